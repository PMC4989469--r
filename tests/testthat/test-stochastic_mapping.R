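test_that("marginal posteriors match enumeration and symmetry", {
  tr3 <- ape::read.tree(text = "((A:1,B:2):0.5,C:1.5);")
  st3 <- c(A = "D", B = "H", C = "H")
  mp <- marginal_node_posteriors(tr3, st3, 0.4, 0.3, "stationary")
  expect_equal(unname(rowSums(mp)), rep(1, nrow(mp)))
  for (node in 4:5)
    expect_equal(unname(mp[node, ]),
                 enum_node_posterior(tr3, st3, 0.4, 0.3, "stationary",
                                     node),
                 tolerance = 1e-12)

  # near-zero rates with uniform data pin every node
  trc <- ape::rcoal(8)
  stD <- stats::setNames(rep("D", 8), trc$tip.label)
  mpD <- marginal_node_posteriors(trc, stD, 1e-9, 0, "fixed_D")
  expect_true(all(mpD[, "D"] > 1 - 1e-6))

  # symmetric cherry, symmetric rates, stationary root: 50/50 at root
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  mpc <- marginal_node_posteriors(cherry, c(A = "D", B = "H"),
                                  0.4, 0.4, "stationary")
  expect_equal(unname(mpc[3, ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("sampled histories are consistent with the tips and the rates", {
  tr <- ape::rcoal(10)
  stD <- stats::setNames(rep("D", 10), tr$tip.label)
  for (k in 1:10) {
    h <- sample_history(tr, stD, 1e-8, 0, "fixed_D", seed = k)
    expect_equal(count_origins(h), 0)
  }

  set.seed(71)
  tr2 <- simulate_bd_tree(40, birth_rate = 1)
  st2 <- simulate_mk_tips(tr2, 0.15, 0, seed = 4)
  skip_if(!any(st2 == "H"))
  f <- fit_mk(tr2, st2, "one_rate")
  for (k in 1:15) {
    h <- sample_history(tr2, st2, f$rates["q_DH"], 0, "fixed_D",
                        seed = k)
    # logical necessity: irreversible model with haplodiploid tips
    expect_gte(count_origins(h), 1)
    # tip end states must equal the observations
    ends <- vapply(seq_along(h$maps), function(i) {
      m <- h$maps[[i]]
      names(m)[length(m)]
    }, "")
    tip_edges <- which(tr2$edge[, 2] <= ape::Ntip(tr2))
    expect_identical(unname(ends[tip_edges]),
                     unname(st2[tr2$tip.label[tr2$edge[tip_edges, 2]]]))
    # per-edge durations fill the branch; no self-transitions
    for (i in seq_along(h$maps)) {
      m <- h$maps[[i]]
      expect_equal(sum(m), tr2$edge.length[i], tolerance = 1e-9)
      if (length(m) > 1)
        expect_true(all(names(m)[-1] != names(m)[-length(m)]))
    }
  }
  # seed determinism
  h1 <- sample_history(tr2, st2, f$rates["q_DH"], 0, "fixed_D", seed = 5)
  h2 <- sample_history(tr2, st2, f$rates["q_DH"], 0, "fixed_D", seed = 5)
  expect_identical(h1$maps, h2$maps)
})

test_that("root-state frequency across maps matches the marginal posterior", {
  tr5 <- ape::read.tree(
    text = "((A:0.6,B:0.6):0.9,((C:0.8,D:0.8):0.3,E:1.1):0.4);")
  st5 <- c(A = "H", B = "D", C = "D", D = "H", E = "D")
  q <- c(0.5, 0.35)
  post <- marginal_node_posteriors(tr5, st5, q[1], q[2], "stationary")
  p_true <- post[6, "D"]
  set.seed(81)
  n <- 3000
  hits <- replicate(n,
    sample_history(tr5, st5, q[1], q[2], "stationary")$root_state == "D")
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(mean(hits) - p_true), 3.5 * se)
})

test_that("uniformization bridge honors impossible and forced paths", {
  # irreversible unlike-endpoint bridge has exactly one transition
  for (k in 1:20) {
    ev <- ploidyshift:::.uniformization_bridge(1L, 2L, 1, 0.05, 0)
    expect_length(ev, 1)
    expect_true(ev > 0 && ev < 1)
  }
  # like endpoints under reversible rates: even number of transitions
  set.seed(91)
  for (k in 1:20) {
    ev <- ploidyshift:::.uniformization_bridge(1L, 1L, 2, 0.8, 0.6)
    expect_equal(length(ev) %% 2, 0)
  }
  expect_error(ploidyshift:::.sample_bridge(1L, 2L, 1, 0, 0),
               "impossible")
})

test_that("count_origins counts D-to-H events plus a haplodiploid root", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  mk_hist <- function(maps, root_state)
    ploidyshift:::.new_simmap(tr, maps, node_states = integer(5),
                              tip_states = NULL, root_state = root_state)
  # empty history, root D
  empty <- list(c(D = 1), c(D = 1), c(D = 1), c(D = 2))
  expect_equal(count_origins(mk_hist(empty, "D")), 0)
  expect_equal(count_origins(mk_hist(empty, "H")), 1)
  # two separate origins and one reversal
  maps <- list(c(D = 0.4, H = 0.6), c(D = 1),
               c(D = 0.5, H = 0.3, D = 0.2), c(D = 2))
  names(maps[[3]]) <- c("D", "H", "D")
  expect_equal(count_origins(mk_hist(maps, "D")), 2)
})

test_that("origin counts respect the parsimony lower bound", {
  skip_if_not_installed("phangorn")
  set.seed(101)
  for (k in 1:6) {
    tr <- simulate_bd_tree(30, birth_rate = 1)
    st <- simulate_mk_tips(tr, 0.2, 0, seed = k)
    if (length(unique(st)) < 2) next
    f <- fit_mk(tr, st, "one_rate")
    pd <- phangorn::phyDat(matrix(st[tr$tip.label], ncol = 1,
                                  dimnames = list(tr$tip.label, NULL)),
                           type = "USER", levels = c("D", "H"))
    fitch <- phangorn::parsimony(tr, pd)
    for (j in 1:5) {
      h <- sample_history(tr, st, f$rates["q_DH"], 0, "fixed_D",
                          seed = 100 * k + j)
      expect_gte(count_origins(h), fitch)
    }
  }
})

test_that("summaries pool counts over trees and maps deterministically", {
  set.seed(111)
  tr <- simulate_bd_tree(50, birth_rate = 1)
  st <- simulate_mk_tips(tr, 0.1, 0, seed = 6)
  skip_if(length(unique(st)) < 2)
  s1 <- summarize_origins(tr, st, "one_rate", n_maps = 5, seed = 3)
  s2 <- summarize_origins(tr, st, "one_rate", n_maps = 5, seed = 3)
  expect_identical(s1$counts, s2$counts)
  expect_equal(s1$mean, mean(s1$counts))
  expect_true(s1$mean >= min(s1$counts) && s1$mean <= max(s1$counts))
  # one map, one tree: a single deterministic count
  s3 <- summarize_origins(tr, st, "one_rate", n_maps = 1, seed = 9)
  expect_length(s3$counts, 1)
})

test_that("SIMMAP export writes one annotated newick line per history", {
  set.seed(121)
  tr <- simulate_bd_tree(8, birth_rate = 1)
  st <- simulate_mk_tips(tr, 0.3, 0, seed = 2)
  skip_if(length(unique(st)) < 2)
  f <- fit_mk(tr, st, "one_rate")
  h <- sample_history(tr, st, f$rates["q_DH"], 0, "fixed_D", seed = 1)
  out <- withr::local_tempfile(fileext = ".tre")
  write_simmap(h, out)
  txt <- readLines(out)
  expect_length(txt, 1)
  expect_match(txt, "\\{[DH],")
  expect_match(txt, ";$")
})
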