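# Stochastic character mapping for the binary reproductive-system
# character: marginal node posteriors, joint sampling of complete
# histories conditional on tip states, and origin counting.

.new_simmap <- function(tree, maps, node_states, tip_states, root_state) {
  structure(list(tree = tree, maps = maps, node_states = node_states,
                 tip_states = tip_states, root_state = root_state),
            class = "simmap_history")
}

#' @export
print.simmap_history <- function(x, ...) {
  nev <- sum(vapply(x$maps, function(m) length(m) - 1L, 1L))
  cat("Stochastic character map on", ape::Ntip(x$tree), "tips:",
      nev, "transition(s), root state", x$root_state, "\n")
  cat("  origins of haplodiploidy (root origin included):",
      count_origins(x), "\n")
  invisible(x)
}

# Per-edge "lift" vectors P(t_i) %*% L[child_i, ] on top of the shared
# pruning pass.
.mk_lifts <- function(tree, down, q_DH, q_HD) {
  lifts <- matrix(0, nrow(tree$edge), 2L)
  for (i in seq_len(nrow(tree$edge))) {
    P <- .pmat2(q_DH, q_HD, tree$edge.length[i])
    lifts[i, ] <- as.vector(P %*% down$L[tree$edge[i, 2], ])
  }
  lifts
}

#' Marginal posterior state probabilities at every node
#'
#' Exact two-pass (post-order then pre-order) computation of each
#' node's marginal posterior over \{D, H\} conditional on all tip
#' states, under fixed transition rates and root weighting. Tip rows
#' are the observed indicators.
#'
#' @inheritParams mk_loglik
#' @return matrix (`Ntip + Nnode` rows, columns `D`, `H`), rows
#'   summing to 1; row order is ape node numbering.
#' @export
marginal_node_posteriors <- function(tree, tip_states, q_DH, q_HD,
                                     root_mode = c("stationary", "fixed_D")) {
  root_mode <- match.arg(root_mode)
  .check_tree(tree)
  pi0 <- .root_freqs(q_DH, q_HD, root_mode)
  s <- .states_int(tree, tip_states)
  down <- .mk_down(tree, s, q_DH, q_HD)
  if (!is.finite(down$logscale))
    stop("tip states have zero likelihood under these rates")
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  lifts <- .mk_lifts(tree, down, q_DH, q_HD)
  U <- matrix(0, nt + tree$Nnode, 2L)
  U[root, ] <- pi0
  children_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (i in rev(down$po)) {  # preorder
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    sibs <- setdiff(children_of[[as.character(p)]], i)
    M <- U[p, ]
    for (j in sibs) M <- M * lifts[j, ]
    P <- .pmat2(q_DH, q_HD, tree$edge.length[i])
    u <- as.vector(crossprod(P, M))
    m <- max(u)
    U[ch, ] <- if (m > 0) u / m else u
  }
  post <- U * down$L
  post <- post / rowSums(post)
  colnames(post) <- STATES
  post
}

# Sample a CTMC bridge on {1,2} from state a to state b over time t.
# Rejection sampling of unconditioned paths, with a uniformization
# fallback once `max_rej` proposals have failed (bridges with unlike
# endpoints can be arbitrarily rare under small rates). Returns the
# ordered event times in (0, t); states alternate starting from `a`.
.sample_bridge <- function(a, b, t, q_DH, q_HD, max_rej = 1e4) {
  rates <- c(q_DH, q_HD)
  if (t <= 0 || all(rates == 0)) {
    if (a != b) stop("impossible endpoint pair under zero rates")
    return(numeric(0))
  }
  for (rep in seq_len(max_rej)) {
    s <- a; tt <- 0; ev <- numeric(0)
    repeat {
      r <- rates[s]
      if (r <= 0) break
      tt <- tt + stats::rexp(1L, r)
      if (tt >= t) break
      ev <- c(ev, tt); s <- 3L - s
    }
    if (s == b) return(ev)
  }
  .uniformization_bridge(a, b, t, q_DH, q_HD)
}

.uniformization_bridge <- function(a, b, t, q_DH, q_HD) {
  Om <- max(q_DH, q_HD)
  if (Om <= 0) {
    if (a != b) stop("impossible endpoint pair under zero rates")
    return(numeric(0))
  }
  Q <- matrix(c(-q_DH, q_DH, q_HD, -q_HD), 2L, 2L, byrow = TRUE)
  R <- diag(2) + Q / Om
  nmax <- max(10L, stats::qpois(1 - 1e-12, Om * t) + 10L)
  Rpow <- vector("list", nmax + 1L)
  Rpow[[1L]] <- diag(2)
  for (n in seq_len(nmax)) Rpow[[n + 1L]] <- Rpow[[n]] %*% R
  w <- vapply(0:nmax, function(n)
    stats::dpois(n, Om * t) * Rpow[[n + 1L]][a, b], 0)
  if (sum(w) <= 0) stop("impossible endpoint pair: P(", STATES[a], " -> ",
                        STATES[b], ") = 0 over t = ", t)
  N <- sample.int(nmax + 1L, 1L, prob = w) - 1L
  if (N == 0L) return(numeric(0))
  states <- integer(N + 1L)
  states[1L] <- a; states[N + 1L] <- b
  if (N > 1L) for (k in 2:N) {
    pr <- R[states[k - 1L], ] * c(Rpow[[N - k + 2L]][1L, b],
                                  Rpow[[N - k + 2L]][2L, b])
    states[k] <- sample.int(2L, 1L, prob = pr)
  }
  times <- sort(stats::runif(N, 0, t))
  keep <- states[-1L] != states[-(N + 1L)]  # drop virtual jumps
  times[keep]
}

#' Sample one complete character history conditional on tip states
#'
#' Draws internal node states jointly (root-to-tip from the exact
#' conditional distributions, not independent marginals) and then
#' samples the path along each branch conditional on its endpoint
#' states. The result is a complete realization of the binary
#' character consistent with the observed tips.
#'
#' @inheritParams mk_loglik
#' @param seed optional integer seed.
#' @return an object of class `simmap_history`: the tree, per-edge
#'   named duration vectors (names `"D"`/`"H"`, in tree edge order),
#'   node states, tip states and the root state.
#' @export
sample_history <- function(tree, tip_states, q_DH, q_HD,
                           root_mode = c("stationary", "fixed_D"),
                           seed = NULL) {
  root_mode <- match.arg(root_mode)
  .check_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  pi0 <- .root_freqs(q_DH, q_HD, root_mode)
  s <- .states_int(tree, tip_states)
  down <- .mk_down(tree, s, q_DH, q_HD)
  if (!is.finite(down$logscale))
    stop("tip states have zero likelihood under these rates")
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  node_state <- integer(nt + tree$Nnode)
  node_state[seq_len(nt)] <- s
  wr <- pi0 * down$L[root, ]
  node_state[root] <- sample.int(2L, 1L, prob = wr)
  for (i in rev(down$po)) {  # preorder
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    P <- .pmat2(q_DH, q_HD, tree$edge.length[i])
    w <- P[node_state[p], ] * down$L[ch, ]
    node_state[ch] <- sample.int(2L, 1L, prob = w)
  }
  maps <- vector("list", nrow(tree$edge))
  for (i in seq_len(nrow(tree$edge))) {
    a <- node_state[tree$edge[i, 1]]; b <- node_state[tree$edge[i, 2]]
    len <- tree$edge.length[i]
    ev <- .sample_bridge(a, b, len, q_DH, q_HD)
    bounds <- c(0, ev, len)
    k <- seq_len(length(ev) + 1L)
    segst <- STATES[ifelse(k %% 2L == 1L, a, 3L - a)]
    maps[[i]] <- stats::setNames(diff(bounds), segst)
  }
  .new_simmap(tree, maps, node_state,
              stats::setNames(STATES[s], tree$tip.label),
              STATES[node_state[root]])
}

#' Count origins of haplodiploidy in a character history
#'
#' The number of D-to-H transition events across all branches, plus
#' one if the root itself is haplodiploid (an origin on the stem,
#' outside the observed tree, is counted as a single origin; this
#' convention is recorded in the summaries that use it).
#'
#' @param history a `simmap_history`.
#' @return non-negative integer origin count.
#' @export
count_origins <- function(history) {
  stopifnot(inherits(history, "simmap_history"))
  n <- 0L
  for (m in history$maps) {
    st <- names(m)
    if (length(st) > 1L)
      n <- n + sum(st[-length(st)] == "D" & st[-1L] == "H")
  }
  n + as.integer(history$root_state == "H")
}

#' Summarize origin counts over trees and stochastic maps
#'
#' Fits the requested Mk model on each tree, samples `n_maps`
#' histories per tree, and pools the per-map origin counts.
#'
#' @param trees a `phylo`, `multiPhylo` or list of trees.
#' @param tip_states named `"D"`/`"H"` vector.
#' @param model `"one_rate"` (irreversible, root fixed diplodiploid)
#'   or `"two_rate"` (reversible, stationary root).
#' @param n_maps maps per tree (>= 1).
#' @param seed integer seed driving all map sampling.
#' @return object of class `origin_summary`: per-map `counts` matrix
#'   (trees x maps), per-tree means, pooled `mean` and `sd`, and the
#'   per-tree fitted rates.
#' @export
summarize_origins <- function(trees, tip_states,
                              model = c("one_rate", "two_rate"),
                              n_maps = 100L, seed = 1L) {
  model <- match.arg(model)
  trees <- .as_tree_list(trees)
  stopifnot(n_maps >= 1)
  seeds <- .derive_seeds(seed, length(trees) * n_maps)
  counts <- matrix(NA_integer_, length(trees), n_maps)
  fits <- vector("list", length(trees))
  root_mode <- if (model == "one_rate") "fixed_D" else "stationary"
  for (i in seq_along(trees)) {
    fit <- fit_mk(trees[[i]], tip_states, model)
    fits[[i]] <- fit
    for (j in seq_len(n_maps)) {
      h <- sample_history(trees[[i]], tip_states,
                          fit$rates["q_DH"], fit$rates["q_HD"],
                          root_mode, seed = seeds[(i - 1L) * n_maps + j])
      counts[i, j] <- count_origins(h)
    }
  }
  structure(list(counts = counts,
                 per_tree_mean = rowMeans(counts),
                 mean = mean(counts), sd = stats::sd(as.vector(counts)),
                 model = model, n_maps = n_maps, fits = fits),
            class = "origin_summary")
}

#' @export
print.origin_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Origins of haplodiploidy (%s model, %d tree(s) x %d map(s))\n",
              x$model, nrow(x$counts), x$n_maps))
  cat(sprintf("  pooled mean %.*f (sd %.*f), per-tree means %s\n",
              digits, x$mean, digits, x$sd,
              paste(round(x$per_tree_mean, digits), collapse = ", ")))
  invisible(x)
}

#' Write histories in SIMMAP-annotated Newick
#'
#' Branches are annotated as `{state,duration:state,duration}` reading
#' from the parent end, the convention used by SIMMAP and phytools.
#'
#' @param history a `simmap_history` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_simmap <- function(history, path) {
  if (inherits(history, "simmap_history")) history <- list(history)
  lines <- vapply(history, .simmap_newick, "")
  writeLines(lines, path)
  invisible(path)
}

.simmap_newick <- function(h) {
  tree <- h$tree
  nt <- ape::Ntip(tree)
  edge_of <- integer(nt + tree$Nnode)
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  ann <- function(i) {
    m <- h$maps[[i]]
    paste0("{", paste(sprintf("%s,%g", names(m), unname(m)),
                      collapse = ":"), "}")
  }
  rec <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    lab <- if (node <= nt) tree$tip.label[node]
           else paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")")
    if (node == nt + 1L) return(paste0(lab, ";"))
    paste0(lab, ":", ann(edge_of[node]))
  }
  rec(nt + 1L)
}
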