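test_that("binary transition matrix matches its closed forms", {
  expect_equal(binary_transition_matrix(0.7, 0.2, 0),
               diag(2), ignore_attr = TRUE)
  P <- binary_transition_matrix(0.5, 0, 2)
  expect_equal(P["D", "D"], exp(-1))
  expect_equal(P["D", "H"], 1 - exp(-1))
  expect_equal(P["H", "D"], 0)
  expect_error(binary_transition_matrix(0.5, 0.1, -1), "t must be")
})

test_that("transition matrix equals the numerical matrix exponential", {
  skip_if_not_installed("Matrix")
  set.seed(10)
  for (i in 1:50) {
    q <- stats::runif(2, 0, 3)
    t <- stats::runif(1, 0, 5)
    Q <- matrix(c(-q[1], q[1], q[2], -q[2]), 2, 2, byrow = TRUE)
    E <- as.matrix(Matrix::expm(Q * t))
    expect_lt(max(abs(binary_transition_matrix(q[1], q[2], t) - E)),
              1e-10)
  }
})

test_that("pruning log-likelihood has its closed forms and sentinels", {
  # cherry with both tips diplodiploid under the irreversible model:
  # likelihood is just no-transition along both branches
  ch <- ape::read.tree(text = "(A:1.3,B:0.4);")
  st <- c(A = "D", B = "D")
  q <- 0.37
  expect_equal(mk_loglik(ch, st, q, 0, "fixed_D"), -q * (1.3 + 0.4))

  # impossible data: a haplodiploid tip with zero transition rate
  expect_identical(mk_loglik(ch, c(A = "D", B = "H"), 0, 0, "fixed_D"),
                   -Inf)
  # degenerate stationary distribution is refused
  expect_error(mk_loglik(ch, st, 0.3, 0, "stationary"), "degenerate")
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(21)
  for (i in 1:25) {
    tr <- rand_tree(sample(4:6, 1))
    st <- rand_states(tr)
    q <- stats::runif(2, 0.05, 2)
    expect_equal(mk_loglik(tr, st, q[1], q[2], "stationary"),
                 enum_mk_loglik(tr, st, q[1], q[2], "stationary"),
                 tolerance = 1e-12)
    expect_equal(mk_loglik(tr, st, q[1], q[2], "fixed_D"),
                 enum_mk_loglik(tr, st, q[1], q[2], "fixed_D"),
                 tolerance = 1e-12)
  }
})

test_that("likelihood decreases in q_DH for all-diplodiploid data", {
  tr <- ape::rcoal(15)
  st <- stats::setNames(rep("D", 15), tr$tip.label)
  qs <- c(0.01, 0.1, 0.5, 1, 3)
  ll <- vapply(qs, function(q) mk_loglik(tr, st, q, 0, "fixed_D"), 0)
  expect_true(all(diff(ll) < 0))
})

test_that("AICc follows its formula and exceeds AIC", {
  expect_equal(aicc(-10, 1, 109), 22 + 4 / 107)
  expect_gt(aicc(-10, 2, 20), -2 * -10 + 2 * 2)  # AICc > AIC
  expect_equal(aicc(-10, 1, 1e7), 22, tolerance = 1e-5)
  expect_error(aicc(-10, 2, 3), "undefined")
})

test_that("ML fits recover rates and are invariant to tip ordering", {
  set.seed(31)
  tr <- simulate_bd_tree(120, birth_rate = 1)
  st <- simulate_mk_tips(tr, 0.06, 0, seed = 7)
  f <- fit_mk(tr, st, "one_rate")
  expect_lt(f$rates[["q_DH"]], 0.06 * 4)
  expect_gt(f$rates[["q_DH"]], 0.06 / 4)
  expect_equal(f$aicc, aicc(f$loglik, 1, 120))

  # permuting the state vector or rotating the tree leaves the fit alone
  f_perm <- fit_mk(tr, st[sample(names(st))], "one_rate")
  expect_equal(f_perm$loglik, f$loglik, tolerance = 1e-8)
  rot <- ape::rotate(tr, ape::Ntip(tr) + 1L)
  f_rot <- fit_mk(rot, st, "one_rate")
  expect_equal(f_rot$loglik, f$loglik, tolerance = 1e-6)

  # nesting: the two-rate maximized likelihood is never worse
  f2 <- fit_mk(tr, st, "two_rate")
  expect_gte(f2$loglik, f$loglik - 1e-4)
})

test_that("one-rate median rate estimate is within x/1.5 of truth", {
  set.seed(77)
  qhat <- replicate(12, {
    tr <- simulate_bd_tree(150, birth_rate = 1)
    st <- simulate_mk_tips(tr, 0.05, 0)
    if (length(unique(st)) < 2) return(NA)
    fit_mk(tr, st, "one_rate")$rates[["q_DH"]]
  })
  med <- stats::median(qhat, na.rm = TRUE)
  expect_lt(med, 0.05 * 1.5)
  expect_gt(med, 0.05 / 1.5)
})

test_that("monomorphic data give a flagged boundary fit", {
  tr <- ape::rcoal(12)
  st <- stats::setNames(rep("D", 12), tr$tip.label)
  f <- fit_mk(tr, st, "one_rate")
  expect_true(f$boundary)
  expect_lt(f$rates[["q_DH"]], 1e-6)
})

test_that("fits agree with an independent Mk implementation", {
  skip_if_not_installed("phytools")
  set.seed(41)
  tr <- simulate_bd_tree(60, birth_rate = 1)
  st <- simulate_mk_tips(tr, 0.12, 0, seed = 2)
  skip_if(length(unique(st)) < 2)
  f <- fit_mk(tr, st, "one_rate")
  irrev <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  pm <- phytools::fitMk(tr, st, model = irrev, pi = c(1, 0))
  expect_equal(f$loglik, as.numeric(stats::logLik(pm)), tolerance = 1e-4)
  expect_equal(unname(f$rates["q_DH"]), pm$rates[1], tolerance = 0.02)
})

test_that("model comparison reports per-tree and mean AICc differences", {
  set.seed(51)
  tr <- simulate_bd_tree(80, birth_rate = 1)
  st <- simulate_mk_tips(tr, 0.08, 0, seed = 3)
  skip_if(length(unique(st)) < 2)
  cmp <- compare_mk_models(list(tr, tr), st)
  expect_equal(nrow(cmp$table), 2)
  expect_equal(cmp$mean_delta_aicc, mean(cmp$table$delta_aicc))
  expect_equal(cmp$table$delta_aicc[1],
               cmp$table$aicc_two[1] - cmp$table$aicc_one[1])
  expect_identical(cmp$preferred,
                   if (cmp$mean_delta_aicc < 0) "two_rate" else "one_rate")
})

test_that("dropping an uninvolved tip barely moves the comparison", {
  set.seed(61)
  tr <- simulate_bd_tree(70, birth_rate = 1)
  st <- simulate_mk_tips(tr, 0.07, 0, seed = 5)
  skip_if(length(unique(st)) < 2)
  cmp <- compare_mk_models(tr, st)
  # choose a diplodiploid tip whose sister is also diplodiploid
  dd <- names(st)[st == "D"]
  drop <- NULL
  for (lab in dd) {
    i <- which(tr$tip.label == lab)
    sis <- tr$edge[tr$edge[, 1] == tr$edge[tr$edge[, 2] == i, 1], 2]
    sis <- setdiff(sis, i)
    if (length(sis) == 1 && sis <= ape::Ntip(tr) &&
        st[tr$tip.label[sis]] == "D") { drop <- lab; break }
  }
  skip_if(is.null(drop))
  sens <- drop_tip_sensitivity(tr, st, drop)
  expect_lt(abs(sens$mean_delta_aicc - cmp$mean_delta_aicc), 2)
  expect_error(drop_tip_sensitivity(tr, st, "no_such_tip"), "not present")
})
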