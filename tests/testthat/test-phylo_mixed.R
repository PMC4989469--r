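test_that("p_mcmc is the doubled smaller tail probability with a floor", {
  expect_equal(p_mcmc(c(rep(-1, 75), rep(1, 25))), 0.5)
  expect_equal(p_mcmc(rep(1, 200)), 2 / 200)      # all-positive floor
  set.seed(151)
  expect_gt(p_mcmc(stats::rnorm(5000)), 0.8)       # symmetric about 0
  expect_error(p_mcmc(stats::rnorm(50)), "at least 100")
})

test_that("the phylogenetic sampler degenerates to OLS on a star tree", {
  set.seed(161)
  n <- 80
  star <- ape::stree(n, type = "star")
  star$edge.length <- rep(1, n)
  z <- stats::setNames(rep(c(0, 1), n / 2), star$tip.label)
  y <- stats::setNames(3 - 0.4 * z + stats::rnorm(n, 0, 0.15),
                       star$tip.label)
  fit <- phylo_lmm(star, y, z, n_iter = 8000, burnin = 2000, seed = 3)
  ols <- stats::coef(stats::lm(y ~ z))[2]
  expect_lt(abs(fit$beta - ols), 0.06)
  expect_true(fit$beta_ci[1] < -0.4 && fit$beta_ci[2] > -0.4 ||
                abs(fit$beta + 0.4) < 0.1)
})

test_that("posterior summaries are deterministic and well-formed", {
  set.seed(171)
  tr <- simulate_bd_tree(60, birth_rate = 1)
  z <- simulate_mk_tips(tr, 1, 1, seed = 2)
  C <- ape::vcv(tr); C <- C / max(C)
  u <- as.vector(t(chol(C)) %*% stats::rnorm(60)) * sqrt(0.18)
  y <- stats::setNames(3 - 0.3 * (z == "H") + u +
                         stats::rnorm(60, 0, sqrt(0.02)), tr$tip.label)
  f1 <- phylo_lmm(tr, y, z, n_iter = 6000, burnin = 1000, seed = 7)
  f2 <- phylo_lmm(tr, y, z, n_iter = 6000, burnin = 1000, seed = 7)
  expect_identical(f1$samples$beta, f2$samples$beta)
  expect_true(all(f1$samples$h2 >= 0 & f1$samples$h2 <= 1))
  expect_lt(f1$beta_ci[1], f1$beta_ci[2])
  expect_true(f1$p_mcmc > 0 && f1$p_mcmc <= 1)

  # doubling the chain barely moves the posterior mean
  f3 <- phylo_lmm(tr, y, z, n_iter = 12000, burnin = 1000, seed = 7)
  expect_lt(abs(f3$beta - f1$beta), 0.05)

  # prior-sensitivity smoke test: doubling the inverse-gamma scale
  # moves beta by well under 10% on informative data
  f4 <- phylo_lmm(tr, y, z, n_iter = 6000, burnin = 1000, seed = 7,
                  prior = list(ig_rate = 0.002))
  expect_lt(abs(f4$beta - f1$beta), 0.1 * max(abs(f1$beta), 0.1))
})

test_that("shuffled ploidy yields an unremarkable fixed effect", {
  set.seed(181)
  tr <- simulate_bd_tree(60, birth_rate = 1)
  C <- ape::vcv(tr); C <- C / max(C)
  u <- as.vector(t(chol(C)) %*% stats::rnorm(60)) * sqrt(0.18)
  y <- stats::setNames(3 + u + stats::rnorm(60, 0, sqrt(0.02)),
                       tr$tip.label)
  z <- stats::setNames(sample(rep(c(0, 1), 30)), tr$tip.label)
  f <- phylo_lmm(tr, y, z, n_iter = 6000, burnin = 1000, seed = 5)
  expect_gt(f$p_mcmc, 0.05)
  expect_true(f$beta_ci[1] < 0 && f$beta_ci[2] > 0)
})

test_that("taxonomic and phylogenetic models agree on nested data", {
  set.seed(191)
  n_gen <- 20; per <- 4
  genus <- rep(paste0("G", seq_len(n_gen)), each = per)
  family <- rep(paste0("F", rep(1:5, each = 4)), each = per)
  gene_eff <- stats::rnorm(n_gen, 0, 0.25)[rep(seq_len(n_gen), each = per)]
  fam_eff <- stats::rnorm(5, 0, 0.2)[rep(rep(1:5, each = 4), each = per)]
  z <- stats::rbinom(n_gen * per, 1, 0.4)
  y <- 3 - 0.3 * z + gene_eff + fam_eff +
    stats::rnorm(n_gen * per, 0, 0.1)
  tab <- data.frame(taxon = paste0("sp", seq_along(y)),
                    infraorder = "I1", family = family, genus = genus,
                    system = ifelse(z == 1, "haplodiploid",
                                    "diplodiploid"),
                    count_2n = round(exp(y)))
  suppressWarnings(
    ft <- taxonomic_lmm(tab, n_iter = 8000, burnin = 2000, seed = 3))
  expect_lt(ft$beta, 0)
  expect_true(ft$beta_ci[1] < -0.3 + 0.2)
  expect_true(all(ft$samples$h2 >= 0 & ft$samples$h2 <= 1))
  # variance is genuinely partitioned away from the residual
  expect_gt(ft$heritability, 0.3)
})

test_that("singleton-only taxonomic levels are absorbed with a warning", {
  tab <- data.frame(taxon = paste0("sp", 1:40),
                    genus = paste0("G", 1:40),  # all singletons
                    family = rep(paste0("F", 1:8), each = 5),
                    system = rep(c("haplodiploid", "diplodiploid"), 20),
                    count_2n = rep(c(12, 18), 20))
  expect_warning(
    fit <- taxonomic_lmm(tab, levels = c("family", "genus"),
                         n_iter = 2000, burnin = 500, seed = 1),
    "singleton")
  expect_identical(fit$levels, "family")
})

test_that("the threshold model detects a deterministic threshold", {
  set.seed(201)
  tr <- simulate_bd_tree(80, birth_rate = 1)
  C <- ape::vcv(tr); C <- C / max(C)
  x <- as.vector(t(chol(C)) %*% stats::rnorm(80)) * 0.45 + 3
  names(x) <- tr$tip.label
  pl <- stats::setNames(ifelse(x < stats::median(x), "H", "D"),
                        tr$tip.label)
  fit <- threshold_model(tr, x, pl, n_iter = 5000, burnin = 1500,
                         seed = 4)
  expect_lt(fit$r, -0.9)
})

test_that("independent traits leave the threshold correlation near zero", {
  set.seed(211)
  tr <- simulate_bd_tree(80, birth_rate = 1)
  C <- ape::vcv(tr); C <- C / max(C)
  L <- t(chol(C))
  x <- as.vector(L %*% stats::rnorm(80)) * 0.45 + 3
  liab <- as.vector(L %*% stats::rnorm(80))
  names(x) <- tr$tip.label
  pl <- stats::setNames(ifelse(liab > 0, "H", "D"), tr$tip.label)
  fit <- threshold_model(tr, x, pl, n_iter = 5000, burnin = 1500,
                         seed = 6)
  expect_true(fit$r_ci[1] < 0 && fit$r_ci[2] > 0)
  expect_lt(abs(fit$r), 0.5)
})
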