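test_that("origin_nodes returns the parent of every D-to-H branch", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  mk_hist <- function(maps, root_state = "D")
    ploidyshift:::.new_simmap(tr, maps,
                              node_states = integer(7),
                              tip_states = NULL, root_state = root_state)
  # no events
  empty <- lapply(tr$edge.length, function(l) c(D = l))
  expect_length(origin_nodes(mk_hist(empty)), 0)
  # one origin on the branch subtending the (A,B) cherry: that edge's
  # parent node is reported
  maps <- empty
  i <- which(tr$edge[, 2] == 7)  # edge into the cherry's crown node
  maps[[i]] <- c(D = tr$edge.length[i] / 2, H = tr$edge.length[i] / 2)
  expect_equal(origin_nodes(mk_hist(maps)), tr$edge[i, 1])
  # two origins on one branch (with an intervening reversal) count twice
  maps2 <- empty
  maps2[[i]] <- stats::setNames(rep(tr$edge.length[i] / 4, 4),
                                c("D", "H", "D", "H"))
  expect_equal(origin_nodes(mk_hist(maps2)), rep(tr$edge[i, 1], 2))
})

test_that("origin nodes from the generator are ancestors of H clades", {
  cfg <- sim_config(n_tips = 60, seed = 23)
  tr <- simulate_bd_tree(cfg)
  sim <- simulate_joint_traits(tr, cfg)
  skip_if(length(origin_nodes(sim$history)) == 0)
  tu <- ploidyshift:::.tips_under(tr)
  for (nd in origin_nodes(sim$history)) {
    # the parent node subtends at least one haplodiploid descendant
    expect_true(any(sim$systems[tu[[nd]]] == "H"))
  }
})

test_that("the Monte Carlo origin test never touches haplodiploid counts", {
  cfg <- sim_config(n_tips = 60, beta = 0, q_DH0 = 0.08,
                    ploidy_effect = 0, seed = 29)
  tr <- simulate_bd_tree(cfg)
  sim <- simulate_joint_traits(tr, cfg)
  skip_if(length(unique(sim$systems)) < 2)
  res1 <- monte_carlo_origin_test(tr, sim$systems, sim$count_2n,
                                  n_maps = 2, R = 50, seed = 5)
  poisoned <- sim$count_2n
  poisoned[sim$systems == "H"] <- 999L  # must be ignored entirely
  res2 <- monte_carlo_origin_test(tr, sim$systems, poisoned,
                                  n_maps = 2, R = 50, seed = 5)
  expect_identical(res1$table, res2$table)
  expect_identical(res1$nulls, res2$nulls)

  # p-values live in [1/(R+1), 1] and expected mean within the null range
  expect_true(all(res1$table$p_value >= 1 / 51 - 1e-12))
  expect_true(all(res1$table$p_value <= 1))
  for (j in seq_along(res1$nulls))
    expect_true(res1$table$expected_mean[j] >= min(res1$nulls[[j]]) &&
                res1$table$expected_mean[j] <= max(res1$nulls[[j]]))
})

test_that("aggregation pools nulls and passes single results through", {
  fake <- function(obs, nulls) {
    structure(list(table = data.frame(map = 1, observed_mean = obs,
                                      expected_mean = mean(nulls),
                                      p_value = NA, n_origins = 2),
                   nulls = list(nulls), R = length(nulls)),
              class = "origin_test")
  }
  a <- fake(10, c(11, 12, 13, 14))
  agg1 <- aggregate_origin_tests(a)
  expect_equal(agg1$observed_mean, 10)
  expect_equal(agg1$expected_mean, 12.5)
  expect_equal(agg1$p_value, 1 / 5)  # observed below every null
  b <- fake(12.5, c(11, 12, 13, 14))
  agg2 <- aggregate_origin_tests(a, b)
  expect_equal(agg2$expected_mean, 12.5)
  expect_equal(agg2$observed_mean, 11.25)
})

test_that("strong state dependence yields small p-values", {
  cfg <- sim_config(n_tips = 80, beta = 3,
                    q_DH0 = 0.06 * exp(3 * log(18)),
                    ploidy_effect = 0, sigma2 = 0.08, seed = 37)
  tr <- simulate_bd_tree(cfg)
  sim <- simulate_joint_traits(tr, cfg)
  skip_if(length(unique(sim$systems)) < 2 ||
            sum(sim$systems == "D") < 3)
  res <- monte_carlo_origin_test(tr, sim$systems, sim$count_2n,
                                 n_maps = 5, R = 100, seed = 11)
  expect_lt(res$pooled$p_value, 0.2)
  expect_lt(res$pooled$observed_mean, res$pooled$expected_mean)
})

test_that("infraorder comparison matches the Welch formulas", {
  mk_table <- function(means_with, means_without) {
    rows <- list()
    add <- function(io, cnt, sys) rows[[length(rows) + 1]] <<-
      data.frame(infraorder = io, system = sys, count_2n = cnt)
    for (i in seq_along(means_with)) {
      add(paste0("W", i), means_with[i], "diplodiploid")
      add(paste0("W", i), NA, "haplodiploid")
    }
    for (i in seq_along(means_without))
      add(paste0("O", i), means_without[i], "diplodiploid")
    do.call(rbind, rows)
  }
  # textbook Welch case
  w <- c(14, 16, 15); o <- c(19, 21, 20, 18)
  res <- infraorder_test(mk_table(w, o))
  se2 <- stats::var(o) / 4 + stats::var(w) / 3
  t_hand <- (mean(o) - mean(w)) / sqrt(se2)
  df_hand <- se2^2 / ((stats::var(o) / 4)^2 / 3 + (stats::var(w) / 3)^2 / 2)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), df_hand),
               tolerance = 1e-10)
  expect_equal(unname(res$group_means), c(15, 19.5))

  # identical groups: t = 0, p = 1 (degenerate zero-variance case)
  res0 <- infraorder_test(mk_table(c(10, 10), c(10, 10)))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  # too few infraorders in a group
  expect_error(infraorder_test(mk_table(10, c(12, 13))), "at least 2")
})
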