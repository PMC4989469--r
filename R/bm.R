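# Maximum-likelihood ancestral reconstruction of a continuous trait
# under Brownian motion, by exact Gaussian message passing on the tree
# (two-pass pruning). Equivalent to the dense GLS solution with the
# full phylogenetic covariance matrix, without forming it.

#' Brownian-motion ancestral state reconstruction
#'
#' Fits the single-rate Brownian-motion model to tip values and
#' returns the ML rate together with the conditional mean and variance
#' of the ancestral value at every internal node given all tips. The
#' rate is the ML estimator (quadratic form divided by n, not n-1,
#' matching a maximum-likelihood rather than REML reconstruction); the
#' root estimate is the phylogenetically weighted (GLS) mean of the
#' tips. Chromosome counts are usually reconstructed on the log scale
#' and back-transformed for reporting; this function is agnostic about
#' the scale of `tip_values`.
#'
#' @param tree a `phylo` with branch lengths (at least 3 tips; zero
#'   terminal branches are tolerated, a tree of height zero is not).
#' @param tip_values named numeric vector covering every tip.
#' @return object of class `bm_fit`: `sigma2`, `root_value`, `ace`
#'   (named vector of internal-node estimates, ape numbering), `var`
#'   (conditional variances on the same nodes, already scaled by
#'   `sigma2`), plus the inputs.
#' @export
bm_ancestral <- function(tree, tip_values) {
  .check_tree(tree)
  nt <- ape::Ntip(tree)
  if (nt < 2) stop("need at least 2 tips")
  height <- .tree_height(tree)
  if (height <= 0) stop("tree has zero height; reconstruction is degenerate")
  if (is.null(names(tip_values))) {
    if (length(tip_values) != nt) stop("tip_values must cover every tip")
    names(tip_values) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(tip_values))
  if (length(miss)) stop("no value for tip(s): ", paste(miss, collapse = ", "))
  x <- tip_values[tree$tip.label]
  if (any(!is.finite(x))) stop("tip values must be finite")

  nn <- tree$Nnode
  edge <- tree$edge; elen <- tree$edge.length
  tiny <- 1e-10 * height  # exact-algebra limit for zero-length branches
  po <- .postorder_idx(tree)
  root <- nt + 1L

  mu <- numeric(nt + nn); v <- numeric(nt + nn)
  mu[seq_len(nt)] <- x
  cm <- numeric(nrow(edge)); cw <- numeric(nrow(edge))
  sumw <- numeric(nt + nn); summu <- numeric(nt + nn)
  for (i in po) {
    ch <- edge[i, 2]
    if (ch > nt) { mu[ch] <- summu[ch] / sumw[ch]; v[ch] <- 1 / sumw[ch] }
    cm[i] <- mu[ch]
    cw[i] <- max(v[ch] + elen[i], tiny)
    p <- edge[i, 1]
    sumw[p] <- sumw[p] + 1 / cw[i]
    summu[p] <- summu[p] + cm[i] / cw[i]
  }
  mu[root] <- summu[root] / sumw[root]
  v[root] <- 1 / sumw[root]

  # sum of squared standardized contrasts = GLS quadratic form
  children_of <- split(seq_len(nrow(edge)), edge[, 1])
  qf <- 0
  for (node in names(children_of)) {
    ce <- children_of[[node]]
    M <- cm[ce[1]]; W <- cw[ce[1]]
    for (i in ce[-1]) {
      qf <- qf + (M - cm[i])^2 / (W + cw[i])
      Wn <- W * cw[i] / (W + cw[i])
      M <- (M / W + cm[i] / cw[i]) * Wn
      W <- Wn
    }
  }
  sigma2 <- qf / nt

  # preorder pass: message from the parent side of every node
  upprec <- numeric(nt + nn); upmu <- numeric(nt + nn)
  est <- numeric(nt + nn); cvar <- numeric(nt + nn)
  est[seq_len(nt)] <- x
  est[root] <- mu[root]; cvar[root] <- v[root]
  for (i in rev(po)) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    prec_ex <- sumw[p] - 1 / cw[i] + upprec[p]
    mean_ex <- (summu[p] - cm[i] / cw[i] + upprec[p] * upmu[p]) /
      max(prec_ex, 1e-300)
    w_to_ch <- 1 / max(prec_ex, 1e-300) + elen[i]
    upprec[ch] <- 1 / max(w_to_ch, tiny)
    upmu[ch] <- mean_ex
    if (ch > nt) {
      est[ch] <- (summu[ch] + upprec[ch] * upmu[ch]) /
        (sumw[ch] + upprec[ch])
      cvar[ch] <- 1 / (sumw[ch] + upprec[ch])
    }
  }

  internal <- root:(nt + nn)
  structure(list(sigma2 = sigma2, root_value = est[root],
                 ace = stats::setNames(est[internal], internal),
                 var = stats::setNames(sigma2 * cvar[internal], internal),
                 n_tips = nt, tree = tree, tip_values = x),
            class = "bm_fit")
}

#' @export
print.bm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Brownian-motion ancestral reconstruction (%d tips)\n",
              x$n_tips))
  cat(sprintf("  sigma^2 (ML) = %.*g per unit time\n", digits, x$sigma2))
  cat(sprintf("  root value   = %.*g (conditional sd %.*g)\n", digits,
              x$root_value, digits, sqrt(x$var[1])))
  invisible(x)
}

#' Ancestral point estimates at selected internal nodes
#'
#' @param fit a `bm_fit` from [bm_ancestral()].
#' @param node_ids internal-node ids (ape numbering, i.e. larger than
#'   the tip count); requesting a tip is an error.
#' @param transform `"none"` returns estimates on the fitted scale;
#'   `"exp"` back-transforms log-scale reconstructions to the raw
#'   chromosome-number scale (no bias correction, a reporting
#'   convention).
#' @return numeric vector of point estimates, one per requested node.
#' @export
node_means_at <- function(fit, node_ids, transform = c("none", "exp")) {
  stopifnot(inherits(fit, "bm_fit"))
  transform <- match.arg(transform)
  node_ids <- as.integer(node_ids)
  if (any(node_ids <= fit$n_tips))
    stop("node ids must be internal nodes, not tips")
  out <- fit$ace[as.character(node_ids)]
  if (anyNA(out)) stop("unknown node id(s)")
  if (transform == "exp") out <- exp(out)
  unname(out)
}
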