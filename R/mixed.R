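# Bayesian mixed models for the ploidy / chromosome-number
# association: a Gaussian phylogenetic "animal model", its taxonomic
# (nested random intercepts) analogue, and Felsenstein's liability
# threshold model. All samplers are plain Gibbs samplers written for
# this model family; priors follow common practice for variance
# components (inverse-gamma on the residual, parameter-expanded
# half-Cauchy on random-effect variances).

#' MCMC significance of a fixed effect
#'
#' Twice the smaller tail posterior probability of the sign of the
#' effect, floored at `2/n` so it is never exactly zero; a Bayesian
#' analogue of a two-sided p-value.
#'
#' @param samples numeric vector of posterior draws (>= 100).
#' @return scalar in (0, 1].
#' @export
p_mcmc <- function(samples) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 100) stop("need at least 100 posterior samples")
  p <- 2 * min(mean(samples < 0), mean(samples > 0))
  min(1, max(p, 2 / n))
}

# inverse-gamma draw (shape a, rate/scale b on the variance)
.rinvgamma <- function(a, b) 1 / stats::rgamma(1L, shape = a, rate = b)

.summarize_lmm <- function(sm, model, extra = list()) {
  ci_b <- .quantile_ci(sm$beta)
  ci_h <- .quantile_ci(sm$h2)
  out <- c(list(
    beta = mean(sm$beta), beta_ci = ci_b,
    p_mcmc = p_mcmc(sm$beta),
    heritability = mean(sm$h2), heritability_ci = ci_h,
    sigma2_random = mean(sm$sp2), sigma2_resid = mean(sm$se2),
    rhat_beta = .split_rhat(sm$beta),
    samples = sm, model = model), extra)
  class(out) <- "ploidy_lmm"
  out
}

#' @export
print.ploidy_lmm <- function(x, digits = 3, ...) {
  cat(sprintf("%s mixed model of log(2n) on ploidy\n",
              if (x$model == "phylo") "Phylogenetic" else "Taxonomic"))
  cat(sprintf("  beta (haplodiploid - diplodiploid) = %.*f  [%.*f, %.*f]\n",
              digits, x$beta, digits, x$beta_ci[1], digits, x$beta_ci[2]))
  cat(sprintf("  P_MCMC = %.*g\n", digits, x$p_mcmc))
  cat(sprintf("  heritability = %.*f  [%.*f, %.*f]\n", digits,
              x$heritability, digits, x$heritability_ci[1], digits,
              x$heritability_ci[2]))
  if (is.finite(x$rhat_beta) && x$rhat_beta > 1.1)
    cat(sprintf("  warning: split-Rhat on beta = %.2f (poor mixing)\n",
                x$rhat_beta))
  invisible(x)
}

# one Gibbs chain for the phylogenetic animal model in the eigenbasis
# of the scaled phylogenetic covariance
.phylo_lmm_chain <- function(d, Ut, y, X, n_iter, burnin, thin, A = 1,
                             ig_shape = 0.001, ig_rate = 0.001) {
  n <- length(y)
  yt <- as.vector(Ut %*% y)
  Xt <- Ut %*% X
  XtXi <- solve(crossprod(Xt))
  cXtXi <- chol(XtXi)
  a <- numeric(n)
  se2 <- stats::var(y) / 2 + 1e-8
  sp2 <- se2
  xi <- 1
  keep <- rep(FALSE, n_iter)
  keep[seq(burnin + 1L, n_iter, by = thin)] <- TRUE
  nk <- sum(keep)
  sm <- list(beta = numeric(nk), sp2 = numeric(nk),
             se2 = numeric(nk), h2 = numeric(nk), mu = numeric(nk))
  ki <- 0L
  for (it in seq_len(n_iter)) {
    # fixed effects | a, se2
    r <- yt - a
    bhat <- XtXi %*% crossprod(Xt, r)
    b <- as.vector(bhat + sqrt(se2) * t(cXtXi) %*% stats::rnorm(ncol(X)))
    # breeding values in the eigenbasis | b, variances
    r <- yt - as.vector(Xt %*% b)
    va <- 1 / (1 / se2 + 1 / (sp2 * d))
    a <- stats::rnorm(n, va * r / se2, sqrt(va))
    # residual variance (inverse-gamma prior)
    ss <- sum((r - a)^2)
    se2 <- .rinvgamma(ig_shape + n / 2, ig_rate + ss / 2)
    # phylogenetic variance (parameter-expanded half-Cauchy prior)
    sa <- sum(a^2 / d)
    sp2 <- .rinvgamma(0.5 + n / 2, 1 / xi + sa / 2)
    xi <- .rinvgamma(1, 1 / A^2 + 1 / sp2)
    if (keep[it]) {
      ki <- ki + 1L
      sm$beta[ki] <- b[2L]; sm$mu[ki] <- b[1L]
      sm$sp2[ki] <- sp2; sm$se2[ki] <- se2
      sm$h2[ki] <- sp2 / (sp2 + se2)
    }
  }
  sm
}

#' Phylogenetic mixed model of log chromosome number on ploidy
#'
#' Gaussian animal model `y = mu + beta * ploidy + u + e` with
#' `u ~ N(0, sigma2_p C)` and `e ~ N(0, sigma2_e I)`, where C is the
#' phylogenetic covariance of the tree scaled to unit height (so
#' variance components are comparable across trees). Ploidy is coded
#' diplodiploid = 0, haplodiploid = 1, so lower counts in
#' haplodiploids correspond to `beta < 0`. Priors: inverse-gamma
#' (0.001, 0.001) on the residual variance, parameter-expanded
#' half-Cauchy(1) on the phylogenetic variance. Sampling is Gibbs in
#' the eigenbasis of C. Phylogenetic heritability is
#' `sigma2_p / (sigma2_p + sigma2_e)`. Passing several trees runs one
#' chain per tree and pools the posteriors (marginalizing the
#' inference over the tree set).
#'
#' @param tree a `phylo`, `multiPhylo` or list of trees.
#' @param log2n named numeric response (log diploid count).
#' @param ploidy named vector: `"D"`/`"H"` labels or 0/1.
#' @param n_iter,burnin,thin chain control (defaults are desk-scale;
#'   increase for publication-grade runs).
#' @param seed integer seed.
#' @param prior hyperparameters: `A` (half-Cauchy scale on the
#'   phylogenetic standard deviation) and `ig_shape`/`ig_rate`
#'   (inverse-gamma on the residual variance).
#' @return object of class `ploidy_lmm` with posterior summaries
#'   (`beta`, CI, `p_mcmc`, `heritability`, variance components,
#'   split-Rhat on beta) and the retained samples.
#' @export
phylo_lmm <- function(tree, log2n, ploidy, n_iter = 50000L,
                      burnin = 10000L, thin = 10L, seed = 1L,
                      prior = list(A = 1, ig_shape = 0.001,
                                   ig_rate = 0.001)) {
  prior <- utils::modifyList(list(A = 1, ig_shape = 0.001,
                                  ig_rate = 0.001), prior)
  trees <- .as_tree_list(tree)
  z <- .ploidy_code(ploidy)
  stopifnot(length(log2n) == length(z))
  if (is.null(names(log2n))) names(log2n) <- names(z)
  seeds <- .derive_seeds(seed, length(trees))
  chains <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    miss <- setdiff(tr$tip.label, names(log2n))
    if (length(miss)) stop("no data for tip(s): ",
                           paste(miss, collapse = ", "))
    C <- ape::vcv(tr)
    C <- C / max(C)  # unit height
    eg <- eigen(C, symmetric = TRUE)
    if (min(eg$values) < 1e-10 * max(eg$values))
      stop("phylogenetic covariance matrix is singular")
    ord <- tr$tip.label
    X <- cbind(1, unname(z[ord]))
    set.seed(seeds[i])
    chains[[i]] <- .phylo_lmm_chain(eg$values, t(eg$vectors),
                                    unname(log2n[ord]), X,
                                    n_iter, burnin, thin,
                                    A = prior$A, ig_shape = prior$ig_shape,
                                    ig_rate = prior$ig_rate)
  }
  sm <- list(beta = unlist(lapply(chains, `[[`, "beta")),
             sp2 = unlist(lapply(chains, `[[`, "sp2")),
             se2 = unlist(lapply(chains, `[[`, "se2")),
             h2 = unlist(lapply(chains, `[[`, "h2")),
             mu = unlist(lapply(chains, `[[`, "mu")))
  out <- .summarize_lmm(sm, "phylo",
                        list(n_trees = length(trees), n_iter = n_iter,
                             burnin = burnin, thin = thin))
  if (is.finite(out$rhat_beta) && out$rhat_beta > 1.1)
    warning(sprintf("split-Rhat on beta = %.2f: chain may not have mixed",
                    out$rhat_beta))
  out
}

.ploidy_code <- function(ploidy) {
  if (is.numeric(ploidy)) {
    stopifnot(all(ploidy %in% 0:1))
    z <- as.numeric(ploidy)
    names(z) <- names(ploidy)
    return(z)
  }
  s <- .norm_system(ploidy)
  stats::setNames(as.numeric(s == "H"), names(ploidy))
}

#' Taxonomic mixed model of log chromosome number on ploidy
#'
#' The same Gaussian model as [phylo_lmm()] with the phylogenetic
#' effect replaced by nested random intercepts for taxonomic levels
#' (by default infraorder, family and genus, whichever are present in
#' the table). Levels in which every group has a single member are
#' inseparable from the residual and are dropped with a warning. The
#' reported "heritability" is the summed taxonomic variance fraction.
#'
#' @param table data frame with columns `count_2n`, `system` and the
#'   taxonomy columns.
#' @param levels taxonomy columns to use as nested random effects.
#' @inheritParams phylo_lmm
#' @return object of class `ploidy_lmm`.
#' @export
taxonomic_lmm <- function(table, levels = c("infraorder", "family", "genus"),
                          n_iter = 50000L, burnin = 10000L, thin = 10L,
                          seed = 1L) {
  stopifnot(all(c("count_2n", "system") %in% names(table)))
  keep <- !is.na(table$count_2n)
  tab <- table[keep, ]
  y <- log(tab$count_2n)
  z <- .ploidy_code(tab$system)
  levels <- intersect(levels, names(tab))
  groups <- list()
  for (lv in levels) {
    g <- as.character(tab[[lv]])
    g[is.na(g) | !nzchar(g)] <- paste0(".none.", seq_len(sum(is.na(g) | !nzchar(g))))
    f <- factor(g)
    if (all(table(f) == 1L)) {
      warning("taxonomic level '", lv,
              "' has only singleton groups; absorbed into the residual")
      next
    }
    groups[[lv]] <- f
  }
  if (!length(groups)) stop("no usable taxonomic levels")
  n <- length(y)
  X <- cbind(1, z)
  XtXi <- solve(crossprod(X))
  cXtXi <- chol(XtXi)
  nl <- length(groups)
  u <- lapply(groups, function(f) numeric(nlevels(f)))
  s2 <- rep(stats::var(y) / (nl + 1), nl)
  xi <- rep(1, nl)
  se2 <- stats::var(y) / 2
  set.seed(.derive_seeds(seed, 1L))
  keep_it <- rep(FALSE, n_iter)
  keep_it[seq(burnin + 1L, n_iter, by = thin)] <- TRUE
  nk <- sum(keep_it)
  sm <- list(beta = numeric(nk), sp2 = numeric(nk),
             se2 = numeric(nk), h2 = numeric(nk), mu = numeric(nk))
  ki <- 0L
  ranef_sum <- function(skip = 0L) {
    tot <- numeric(n)
    for (l in seq_len(nl)) if (l != skip)
      tot <- tot + u[[l]][as.integer(groups[[l]])]
    tot
  }
  for (it in seq_len(n_iter)) {
    r <- y - ranef_sum()
    bhat <- XtXi %*% crossprod(X, r)
    b <- as.vector(bhat + sqrt(se2) * t(cXtXi) %*% stats::rnorm(2L))
    fx <- as.vector(X %*% b)
    for (l in seq_len(nl)) {
      r <- y - fx - ranef_sum(skip = l)
      idx <- as.integer(groups[[l]])
      ng <- tabulate(idx, nlevels(groups[[l]]))
      sg <- as.vector(rowsum(r, idx, reorder = TRUE))
      vg <- 1 / (ng / se2 + 1 / s2[l])
      u[[l]] <- stats::rnorm(length(ng), vg * sg / se2, sqrt(vg))
      ssu <- sum(u[[l]]^2)
      s2[l] <- .rinvgamma(0.5 + length(ng) / 2, 1 / xi[l] + ssu / 2)
      xi[l] <- .rinvgamma(1, 1 + 1 / s2[l])
    }
    resid <- y - fx - ranef_sum()
    se2 <- .rinvgamma(0.001 + n / 2, 0.001 + sum(resid^2) / 2)
    if (keep_it[it]) {
      ki <- ki + 1L
      sm$beta[ki] <- b[2L]; sm$mu[ki] <- b[1L]
      sm$sp2[ki] <- sum(s2); sm$se2[ki] <- se2
      sm$h2[ki] <- sum(s2) / (sum(s2) + se2)
    }
  }
  .summarize_lmm(sm, "taxonomic",
                 list(levels = names(groups), n_iter = n_iter,
                      burnin = burnin, thin = thin))
}

#' Felsenstein's phylogenetic threshold model
#'
#' The binary reproductive system is modeled as the sign of an
#' unobserved liability that evolves jointly with log chromosome
#' number as a bivariate Brownian motion over the tree (both
#' phylogenetic heritabilities fixed at 1; no residual). The 2x2
#' between-trait covariance has the liability variance fixed at 1 for
#' identifiability (rescaled after every covariance update). Data
#' augmentation MCMC: single-site truncated-normal updates of the
#' liabilities, a joint normal update of the two trait means, and an
#' inverse-Wishart update of the covariance. The quantity of interest
#' is the posterior of the liability / log-count correlation r.
#'
#' @param tree a `phylo`.
#' @param log2n named numeric vector (log diploid counts).
#' @param ploidy named `"D"`/`"H"` (or 0/1) vector; H maps to positive
#'   liability.
#' @param n_iter,burnin,thin chain control; the augmented sampler
#'   defaults to shorter chains than [phylo_lmm()] because every
#'   iteration sweeps all liabilities.
#' @param seed integer seed.
#' @return object of class `threshold_fit`: posterior mean and 95% CI
#'   of `r`, retained samples, and mixing diagnostics.
#' @export
threshold_model <- function(tree, log2n, ploidy, n_iter = 15000L,
                            burnin = 5000L, thin = 10L, seed = 1L) {
  .check_tree(tree)
  z <- .ploidy_code(ploidy)
  if (is.null(names(log2n))) names(log2n) <- names(z)
  ord <- tree$tip.label
  y <- unname(log2n[ord]); zz <- unname(z[ord])
  if (anyNA(y) || anyNA(zz)) stop("complete cases required for every tip")
  n <- length(y)
  C <- ape::vcv(tree); C <- C / max(C)
  Ci <- tryCatch(solve(C), error = function(e)
    stop("phylogenetic covariance matrix is singular"))
  s11 <- sum(Ci)
  set.seed(.derive_seeds(seed, 1L))

  ell <- ifelse(zz == 1, 0.5, -0.5)
  mu <- c(0, mean(y))
  V <- diag(c(1, max(stats::var(y), 1e-4)))
  nu0 <- 3
  S0 <- diag(c(1, max(stats::var(y), 1e-4)))
  keep_it <- rep(FALSE, n_iter)
  keep_it[seq(burnin + 1L, n_iter, by = thin)] <- TRUE
  r_s <- numeric(sum(keep_it)); v22_s <- numeric(sum(keep_it))
  ki <- 0L
  diagCi <- diag(Ci)
  for (it in seq_len(n_iter)) {
    W <- solve(V)
    h <- as.vector(Ci %*% (y - mu[2]))
    g <- as.vector(Ci %*% (ell - mu[1]))
    # single-site Gibbs over liabilities (truncated normals)
    for (i in seq_len(n)) {
      prec <- W[1, 1] * diagCi[i]
      gi <- g[i] - diagCi[i] * (ell[i] - mu[1])
      m <- mu[1] - (W[1, 1] * gi + W[1, 2] * h[i]) / prec
      sd <- 1 / sqrt(prec)
      lo <- if (zz[i] == 1) 0 else -Inf
      hi <- if (zz[i] == 1) Inf else 0
      pa <- stats::pnorm(lo, m, sd); pb <- stats::pnorm(hi, m, sd)
      uu <- stats::runif(1L, min(pa, 1 - 1e-12), max(pb, pa + 1e-12))
      new <- m + sd * stats::qnorm(min(max(uu, 1e-12), 1 - 1e-12))
      if (is.finite(new)) {
        g <- g + Ci[, i] * (new - ell[i])
        ell[i] <- new
      }
    }
    # trait means (flat prior)
    t1 <- sum(Ci %*% ell); t2 <- sum(Ci %*% y)
    P <- W * s11
    bm <- solve(P, W %*% c(t1, t2))
    mu <- as.vector(bm + backsolve(chol(P), stats::rnorm(2L)))
    # between-trait covariance (inverse-Wishart), then fix V[1,1] = 1
    Z <- cbind(ell - mu[1], y - mu[2])
    S <- crossprod(Z, Ci %*% Z)
    Wdraw <- stats::rWishart(1L, nu0 + n, solve(S0 + S))[, , 1L]
    V <- solve(Wdraw)
    s <- sqrt(V[1, 1])
    ell <- ell / s; mu[1] <- mu[1] / s
    V <- V / outer(c(s, 1), c(s, 1))
    if (keep_it[it]) {
      ki <- ki + 1L
      r_s[ki] <- V[1, 2] / sqrt(V[1, 1] * V[2, 2])
      v22_s[ki] <- V[2, 2]
    }
  }
  structure(list(r = mean(r_s), r_ci = .quantile_ci(r_s),
                 samples = list(r = r_s, v22 = v22_s),
                 rhat_r = .split_rhat(r_s), n_iter = n_iter,
                 burnin = burnin, thin = thin),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, digits = 3, ...) {
  cat("Phylogenetic threshold model (liability vs log 2n)\n")
  cat(sprintf("  correlation r = %.*f  [%.*f, %.*f]\n", digits, x$r,
              digits, x$r_ci[1], digits, x$r_ci[2]))
  if (is.finite(x$rhat_r) && x$rhat_r > 1.1)
    cat(sprintf("  warning: split-Rhat on r = %.2f (poor mixing)\n",
                x$rhat_r))
  invisible(x)
}
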