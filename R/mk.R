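#' Transition probability matrix of the binary Markov chain
#'
#' Closed-form `expm(Q t)` for the two-state chain with instantaneous
#' rates `q_DH` (D to H) and `q_HD` (H to D):
#' `P_DD(t) = pi_D + pi_H exp(-(q_DH + q_HD) t)` with `pi` the
#' stationary frequencies; for `q_HD = 0` this reduces to
#' `P_DD(t) = exp(-q_DH t)` and `P_HD(t) = 0`.
#'
#' @param q_DH,q_HD non-negative transition rates.
#' @param t elapsed time (>= 0).
#' @return a 2x2 row-stochastic matrix with dimnames `D`/`H`, rows =
#'   starting state.
#' @export
binary_transition_matrix <- function(q_DH, q_HD, t) {
  if (t < 0) stop("t must be >= 0")
  stopifnot(q_DH >= 0, q_HD >= 0)
  P <- .pmat2(q_DH, q_HD, t)
  dimnames(P) <- list(STATES, STATES)
  P
}

.pmat2 <- function(q_DH, q_HD, t) {
  r <- q_DH + q_HD
  if (r == 0 || t == 0) return(diag(2))
  e <- exp(-r * t)
  piD <- q_HD / r
  piH <- q_DH / r
  matrix(c(piD + piH * e, piH - piH * e,
           piD - piD * e, piH + piD * e),
         2L, 2L, byrow = TRUE)
}

.root_freqs <- function(q_DH, q_HD, root_mode) {
  if (root_mode == "fixed_D") return(c(1, 0))
  if (q_HD == 0)
    stop("stationary root frequencies are degenerate when q_HD = 0; ",
         "use root_mode = 'fixed_D'")
  c(q_HD, q_DH) / (q_DH + q_HD)
}

# Cache the traversal-invariant pieces of the pruning algorithm so
# repeated likelihood evaluations (optimization, mapping) do not
# re-derive them.
.mk_prep <- function(tree, tip_states) {
  s <- .states_int(tree, tip_states)
  list(edge = tree$edge, elen = tree$edge.length,
       po = .postorder_idx(tree), s = s,
       nt = ape::Ntip(tree), nnode = tree$Nnode)
}

# Post-order pruning pass: scaled conditional likelihoods for every
# node plus the accumulated log scaling factor. Shared by the
# likelihood, marginal posteriors and stochastic mapping.
.mk_down_prep <- function(prep, q_DH, q_HD) {
  nt <- prep$nt
  L <- matrix(1, nt + prep$nnode, 2L)
  L[seq_len(nt), ] <- 0
  L[cbind(seq_len(nt), prep$s)] <- 1
  edge <- prep$edge; elen <- prep$elen
  logscale <- 0
  r <- q_DH + q_HD
  piD <- if (r > 0) q_HD / r else 1
  piH <- 1 - piD
  for (i in prep$po) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    l1 <- L[ch, 1L]; l2 <- L[ch, 2L]
    m <- if (l1 > l2) l1 else l2
    if (m <= 0) return(list(L = L, logscale = -Inf, po = prep$po))
    l1 <- l1 / m; l2 <- l2 / m
    logscale <- logscale + log(m)
    e <- exp(-r * elen[i])
    # closed-form 2x2 transition probabilities
    v1 <- (piD + piH * e) * l1 + (piH - piH * e) * l2
    v2 <- (piD - piD * e) * l1 + (piH + piD * e) * l2
    L[p, 1L] <- L[p, 1L] * v1
    L[p, 2L] <- L[p, 2L] * v2
    L[ch, 1L] <- l1; L[ch, 2L] <- l2
  }
  list(L = L, logscale = logscale, po = prep$po)
}

.mk_down <- function(tree, s, q_DH, q_HD) {
  prep <- list(edge = tree$edge, elen = tree$edge.length,
               po = .postorder_idx(tree), s = s,
               nt = ape::Ntip(tree), nnode = tree$Nnode)
  .mk_down_prep(prep, q_DH, q_HD)
}

.mk_ll_prep <- function(prep, q_DH, q_HD, root_mode) {
  pi0 <- .root_freqs(q_DH, q_HD, root_mode)
  d <- .mk_down_prep(prep, q_DH, q_HD)
  if (!is.finite(d$logscale)) return(-Inf)
  lik <- sum(pi0 * d$L[prep$nt + 1L, ])
  if (lik <= 0) return(-Inf)
  log(lik) + d$logscale
}

#' Log-likelihood of tip states under the binary Mk model
#'
#' Felsenstein pruning over the tree: the log of the probability of
#' the observed tip states summed over all internal-state assignments,
#' with the root weighted either by the stationary frequencies of the
#' fitted chain (`"stationary"`, the two-rate convention) or by a
#' point mass on diplodiploidy (`"fixed_D"`, required for the
#' irreversible one-rate model, whose stationary distribution is
#' degenerate). Data that are impossible under the rates (for example
#' a haplodiploid tip with `q_DH = 0` under the irreversible model)
#' give `-Inf`, never `NaN`.
#'
#' @param tree a `phylo` with branch lengths.
#' @param tip_states named vector of `"D"`/`"H"` (or synonyms) covering
#'   every tip.
#' @param q_DH,q_HD non-negative rates.
#' @param root_mode `"stationary"` or `"fixed_D"`.
#' @return the log-likelihood (scalar; possibly `-Inf`).
#' @export
mk_loglik <- function(tree, tip_states, q_DH, q_HD,
                      root_mode = c("stationary", "fixed_D")) {
  root_mode <- match.arg(root_mode)
  .check_tree(tree)
  stopifnot(q_DH >= 0, q_HD >= 0)
  prep <- .mk_prep(tree, tip_states)
  .mk_ll_prep(prep, q_DH, q_HD, root_mode)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)` with `n` the number of
#' tips.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n sample size (number of tips).
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined for n <= k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Fixed 5-point Latin-hypercube start grid on [0,1]^d (deterministic:
# stratified midpoints, second axis permuted).
.lh_starts <- function(d, n = 5L) {
  g <- (seq_len(n) - 0.5) / n
  if (d == 1L) matrix(g, ncol = 1L)
  else cbind(g, g[c(3L, 1L, 5L, 2L, 4L)])
}

#' Maximum-likelihood fit of the one- or two-rate Mk model
#'
#' The one-rate model allows only diplodiploid-to-haplodiploid
#' transitions (`q_HD = 0`) with the root state fixed as diplodiploid;
#' the two-rate model estimates both rates with stationary root
#' frequencies. Optimization is quasi-Newton (`L-BFGS-B`) on log rates
#' within `[lower, upper]`, from five Latin-hypercube starting points
#' (likelihood surfaces for rare transitions are flat, so a single
#' start is unreliable). Monomorphic tip data yield a boundary fit
#' flagged in the result rather than an error.
#'
#' @param tree a `phylo` with branch lengths.
#' @param tip_states named `"D"`/`"H"` vector covering every tip.
#' @param model `"one_rate"` or `"two_rate"`.
#' @param lower,upper box bounds on each rate (per unit branch length).
#' @return an object of class `mk_fit`: list with `model`, `rates`
#'   (named `q_DH`, `q_HD`), `loglik`, `k`, `n`, `aic`, `aicc`,
#'   `root_mode`, `boundary`, `convergence`.
#' @export
fit_mk <- function(tree, tip_states, model = c("one_rate", "two_rate"),
                   lower = 1e-8, upper = 1e3) {
  model <- match.arg(model)
  .check_tree(tree)
  s <- .states_int(tree, tip_states)
  nt <- ape::Ntip(tree)
  root_mode <- if (model == "one_rate") "fixed_D" else "stationary"
  k <- if (model == "one_rate") 1L else 2L
  lb <- log(lower); ub <- log(upper)

  prep <- .mk_prep(tree, tip_states)
  nll <- function(lp) {
    q <- exp(lp)
    ll <- if (model == "one_rate")
      .mk_ll_prep(prep, q[1], 0, "fixed_D")
    else
      .mk_ll_prep(prep, q[1], q[2], "stationary")
    if (!is.finite(ll)) 1e10 else -ll
  }

  monomorphic <- length(unique(s)) == 1L
  starts <- lb + .lh_starts(k) * (ub - lb)
  best <- NULL
  for (j in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[j, ], nll, method = "L-BFGS-B",
                   lower = rep(lb, k), upper = rep(ub, k),
                   control = list(factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("Mk optimization failed to converge from all starting points")
  q <- exp(best$par)
  rates <- if (model == "one_rate") c(q_DH = unname(q[1]), q_HD = 0)
           else c(q_DH = unname(q[1]), q_HD = unname(q[2]))
  at_bound <- any(abs(best$par - lb) < 1e-6) || any(abs(best$par - ub) < 1e-6)
  ll <- -best$value
  structure(list(model = model, rates = rates, loglik = ll, k = k, n = nt,
                 aic = -2 * ll + 2 * k, aicc = aicc(ll, k, nt),
                 root_mode = root_mode,
                 boundary = monomorphic || at_bound,
                 convergence = best$convergence),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Binary Mk model (%s), %d tips\n", x$model, x$n))
  cat(sprintf("  q_DH = %.*g  q_HD = %.*g\n", digits, x$rates["q_DH"],
              digits, x$rates["q_HD"]))
  cat(sprintf("  logLik = %.*f  AIC = %.*f  AICc = %.*f\n",
              digits, x$loglik, digits, x$aic, digits, x$aicc))
  if (x$boundary) cat("  note: estimate at parameter boundary\n")
  invisible(x)
}

#' @export
coef.mk_fit <- function(object, ...) object$rates

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' Compare the one- and two-rate models over a tree set
#'
#' Fits both models on every tree and reports per-tree and mean AICc
#' differences. The sign convention is `delta = AICc(two_rate) -
#' AICc(one_rate)`: negative values favor the two-rate (reversible)
#' model, positive values the irreversible one-rate model.
#'
#' @param trees a `phylo`, `multiPhylo` or list of trees sharing the
#'   same taxa.
#' @param tip_states named `"D"`/`"H"` vector.
#' @return an object of class `mk_comparison`: a per-tree table,
#'   `mean_delta_aicc`, `mean_delta_aic` and `preferred`.
#' @export
compare_mk_models <- function(trees, tip_states) {
  trees <- .as_tree_list(trees)
  rows <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    f1 <- fit_mk(trees[[i]], tip_states, "one_rate")
    f2 <- fit_mk(trees[[i]], tip_states, "two_rate")
    rows[[i]] <- data.frame(
      tree_id = i,
      q_DH_one = f1$rates["q_DH"], loglik_one = f1$loglik,
      aicc_one = f1$aicc, aic_one = f1$aic,
      q_DH_two = f2$rates["q_DH"], q_HD_two = f2$rates["q_HD"],
      loglik_two = f2$loglik, aicc_two = f2$aicc, aic_two = f2$aic,
      delta_aicc = f2$aicc - f1$aicc, delta_aic = f2$aic - f1$aic,
      row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  md <- mean(tab$delta_aicc)
  structure(list(table = tab, mean_delta_aicc = md,
                 mean_delta_aic = mean(tab$delta_aic),
                 preferred = if (md < 0) "two_rate" else "one_rate",
                 n_trees = length(trees)),
            class = "mk_comparison")
}

#' @export
print.mk_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Mk model comparison over %d tree(s)\n", x$n_trees))
  cat(sprintf("  mean AICc difference (two_rate - one_rate): %.*f\n",
              digits, x$mean_delta_aicc))
  cat(sprintf("  mean AIC  difference (two_rate - one_rate): %.*f\n",
              digits, x$mean_delta_aic))
  cat("  preferred model:", x$preferred, "\n")
  invisible(x)
}

#' Single-tip sensitivity re-analysis
#'
#' Repeats the full model comparison on trees pruned of one tip, to
#' assess whether a single taxon (for example a diplodiploid tip
#' nested deep inside a haplodiploid clade) drives the support for
#' reversibility.
#'
#' @param trees tree set as for [compare_mk_models()].
#' @param tip_states named state vector.
#' @param drop_label tip to remove (must be present on every tree).
#' @return an `mk_comparison` for the reduced dataset, with the dropped
#'   label recorded.
#' @export
drop_tip_sensitivity <- function(trees, tip_states, drop_label) {
  trees <- .as_tree_list(trees)
  for (tr in trees)
    if (!drop_label %in% tr$tip.label)
      stop("tip '", drop_label, "' not present on every tree")
  pruned <- lapply(trees, function(tr) ape::drop.tip(tr, drop_label))
  st <- tip_states[setdiff(names(tip_states), drop_label)]
  out <- compare_mk_models(pruned, st)
  out$dropped <- drop_label
  out
}
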