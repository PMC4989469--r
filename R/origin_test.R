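# Directionality analyses: does haplodiploidy originate on lineages
# that already have low chromosome numbers?

# tip labels descending from each node (list indexed by node id)
.tips_under <- function(tree) {
  nt <- ape::Ntip(tree)
  out <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) out[[i]] <- tree$tip.label[i]
  for (i in .postorder_idx(tree)) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

#' Nodes subtending origins of haplodiploidy
#'
#' For every D-to-H transition event in a sampled history, returns the
#' parent node of the branch carrying the event: the last
#' reconstructable ancestor still in the diplodiploid state "leading
#' to" the haplodiploid clade. Two origins under one parent yield the
#' node twice. A haplodiploid root state implies an origin on the stem
#' outside the observed tree; it contributes to [count_origins()] but
#' has no reconstructable node and so is not returned here.
#'
#' @param history a `simmap_history`.
#' @return integer vector of node ids (possibly empty, duplicates
#'   kept).
#' @export
origin_nodes <- function(history) {
  stopifnot(inherits(history, "simmap_history"))
  out <- integer(0)
  for (i in seq_along(history$maps)) {
    st <- names(history$maps[[i]])
    if (length(st) > 1L) {
      k <- sum(st[-length(st)] == "D" & st[-1L] == "H")
      if (k > 0L) out <- c(out, rep(history$tree$edge[i, 1], k))
    }
  }
  out
}

# Map a full-tree node onto the pruned tree: the nearest ancestor
# (including the node itself) that survives pruning. A node survives
# when its kept descendants span at least two of its child subtrees;
# otherwise it is suppressed and its image is the pruned-tree parent
# of the MRCA of its kept descendants.
.map_to_pruned <- function(tree, node, keep, pruned, tu = NULL) {
  nt <- ape::Ntip(tree)
  if (is.null(tu)) tu <- .tips_under(tree)
  parent_of <- integer(nt + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  kept_desc <- intersect(tu[[node]], keep)
  while (!length(kept_desc) && node != nt + 1L) {
    node <- parent_of[node]
    kept_desc <- intersect(tu[[node]], keep)
  }
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  spread <- sum(vapply(kids, function(k)
    length(intersect(tu[[k]], keep)) > 0L, TRUE))
  m <- if (length(kept_desc) == 1L)
    which(pruned$tip.label == kept_desc)
  else ape::getMRCA(pruned, kept_desc)
  m <- as.integer(m)
  proot <- ape::Ntip(pruned) + 1L
  if (spread >= 2L && length(kept_desc) >= 2L) return(m)
  if (m == proot) return(proot)
  as.integer(pruned$edge[pruned$edge[, 2] == m, 1])
}

#' Monte Carlo test for low chromosome number at origin nodes
#'
#' For each stochastic map of the reproductive system: (a) identify
#' the k nodes subtending D-to-H origins; (b) prune all haplodiploid
#' tips, so the reconstruction never uses haplodiploid counts; (c)
#' reconstruct (log) diploid chromosome number on the pruned tree
#' under Brownian motion; (d) take the mean reconstructed count at the
#' origin nodes (mapped to their nearest surviving ancestors on the
#' pruned tree); (e) build a null distribution of R replicate means at
#' k internal nodes drawn uniformly without replacement; (f) report
#' the one-sided (low tail) add-one p-value
#' `p = (1 + #\{null <= observed\}) / (R + 1)`, which is bounded below
#' by `1/(R+1)`.
#'
#' @param tree a `phylo`.
#' @param tip_states named `"D"`/`"H"` vector.
#' @param tip_2n named diploid chromosome counts covering every tip
#'   used.
#' @param model `"one_rate"` or `"two_rate"` (fitted by [fit_mk()]).
#' @param n_maps number of stochastic maps.
#' @param R null replicates per map.
#' @param seed integer seed.
#' @param log_scale reconstruct log(2n) (default) or raw counts;
#'   either way `observed`/`expected` means are reported on the raw
#'   2n scale (log reconstructions are back-transformed per node).
#' @return object of class `origin_test`: per-map data frame
#'   (`observed_mean`, `expected_mean`, `p_value`, `n_origins`), the
#'   per-map null distributions, and the pooled summary from
#'   [aggregate_origin_tests()].
#' @export
monte_carlo_origin_test <- function(tree, tip_states, tip_2n,
                                    model = c("one_rate", "two_rate"),
                                    n_maps = 10L, R = 100L, seed = 1L,
                                    log_scale = TRUE) {
  model <- match.arg(model)
  .check_tree(tree)
  s <- .states_int(tree, tip_states)
  if (length(unique(s)) < 2L)
    stop("both reproductive systems must be present among the tips")
  if (is.null(names(tip_2n))) {
    stopifnot(length(tip_2n) == ape::Ntip(tree))
    names(tip_2n) <- tree$tip.label
  }
  keep <- tree$tip.label[s == 1L]
  if (length(keep) < 3L)
    stop("need at least 3 diplodiploid tips to reconstruct counts")
  cnt <- tip_2n[keep]
  if (anyNA(cnt)) stop("missing 2n count for diplodiploid tip(s)")

  fit <- fit_mk(tree, tip_states, model)
  root_mode <- if (model == "one_rate") "fixed_D" else "stationary"
  pruned <- prune_to(tree, keep)
  vals <- if (log_scale) log(cnt) else cnt
  asr <- bm_ancestral(pruned, vals)
  node_est <- if (log_scale) exp(asr$ace) else asr$ace  # raw 2n scale
  internal_ids <- as.integer(names(asr$ace))
  tu <- .tips_under(tree)

  seeds <- .derive_seeds(seed, n_maps + 1L)
  null_seed_rng <- seeds[n_maps + 1L]
  rows <- list(); nulls <- list()
  set.seed(null_seed_rng)
  for (j in seq_len(n_maps)) {
    h <- sample_history(tree, tip_states, fit$rates["q_DH"],
                        fit$rates["q_HD"], root_mode, seed = seeds[j])
    onodes <- origin_nodes(h)
    k <- length(onodes)
    if (k == 0L) {
      warning("map ", j, " has no within-tree origin; skipped")
      next
    }
    if (k > length(internal_ids))
      stop("more origins (", k, ") than internal nodes on the pruned tree")
    mapped <- vapply(onodes, .map_to_pruned, integer(1),
                     tree = tree, keep = keep, pruned = pruned, tu = tu)
    observed <- mean(node_est[as.character(mapped)])
    null_means <- vapply(seq_len(R), function(r)
      mean(node_est[as.character(sample(internal_ids, k))]), 0)
    p <- (1 + sum(null_means <= observed)) / (R + 1)
    rows[[length(rows) + 1L]] <- data.frame(
      map = j, observed_mean = observed, expected_mean = mean(null_means),
      p_value = p, n_origins = k)
    nulls[[length(nulls) + 1L]] <- null_means
  }
  if (!length(rows))
    stop("no map produced a within-tree origin; cannot test")
  tab <- do.call(rbind, rows)
  out <- structure(list(table = tab, nulls = nulls, R = R,
                        model = model, fit = fit, n_maps = n_maps,
                        log_scale = log_scale),
                   class = "origin_test")
  out$pooled <- aggregate_origin_tests(out)
  out
}

#' Pool origin tests over maps (and trees)
#'
#' Pools all per-map results: the pooled observed mean, the pooled
#' expected mean, and a combined p-value obtained by ranking the
#' pooled observed mean within the union of all null replicate means.
#' Pooling (rather than, say, Fisher's method) is used because per-map
#' results share the same data and are not independent.
#'
#' @param ... one or more `origin_test` objects (or a single list of
#'   them).
#' @return a list with `observed_mean`, `expected_mean`, `p_value` and
#'   `n_results`.
#' @export
aggregate_origin_tests <- function(...) {
  args <- list(...)
  if (length(args) == 1L && !inherits(args[[1L]], "origin_test"))
    args <- args[[1L]]
  stopifnot(length(args) >= 1L,
            all(vapply(args, inherits, TRUE, "origin_test")))
  tab <- do.call(rbind, lapply(args, `[[`, "table"))
  nulls <- unlist(lapply(args, function(a) a$nulls))
  obs <- mean(tab$observed_mean)
  p <- (1 + sum(nulls <= obs)) / (length(nulls) + 1)
  list(observed_mean = obs, expected_mean = mean(nulls),
       p_value = p, n_results = nrow(tab))
}

#' @export
print.origin_test <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Origin-node chromosome number test (%s model, %d map(s), R = %d)\n",
    x$model, nrow(x$table), x$R))
  cat(sprintf("  mean origins used: %.1f\n", mean(x$table$n_origins)))
  cat(sprintf("  observed mean 2n at origin nodes: %.*f\n", digits,
              x$pooled$observed_mean))
  cat(sprintf("  expected mean under independence: %.*f\n", digits,
              x$pooled$expected_mean))
  cat(sprintf("  one-sided pooled p-value: %.*g\n", digits,
              x$pooled$p_value))
  invisible(x)
}

#' Infraorder-level comparison of diploid chromosome numbers
#'
#' Computes, for every infraorder, the mean diploid chromosome count
#' over its diplodiploid species, flags infraorders that harbor at
#' least one haplodiploid record, and compares the two groups of
#' infraorder means with Welch's two-sample t-test (the statistic is
#' oriented as mean(without haplodiploids) minus mean(with), so a
#' positive t supports lower counts where haplodiploidy arose).
#'
#' @param table a trait data frame with columns `infraorder`, `system`
#'   and `count_2n`.
#' @return object of class `infraorder_test`: per-infraorder means,
#'   group means, `t`, `df` (Welch-Satterthwaite), `p`.
#' @export
infraorder_test <- function(table) {
  stopifnot(all(c("infraorder", "system", "count_2n") %in% names(table)))
  sys <- .norm_system(table$system)
  ok <- !is.na(table$infraorder) & nzchar(table$infraorder)
  tab <- table[ok, ]
  sys <- sys[ok]
  dip <- tab[sys == "D" & !is.na(tab$count_2n), ]
  if (!nrow(dip)) stop("no diplodiploid records with chromosome counts")
  means <- tapply(dip$count_2n, dip$infraorder, mean)
  has_h <- tapply(sys == "H", tab$infraorder, any)[names(means)]
  with_h <- means[has_h]
  without_h <- means[!has_h]
  if (length(with_h) < 2L || length(without_h) < 2L)
    stop("each group needs at least 2 infraorders (variance undefined)")
  res <- tryCatch(
    stats::t.test(without_h, with_h),
    error = function(e) NULL)
  if (is.null(res)) {  # zero-variance degenerate case
    d <- mean(without_h) - mean(with_h)
    t <- if (d == 0) 0 else sign(d) * Inf
    df <- length(without_h) + length(with_h) - 2
    p <- if (d == 0) 1 else 0
  } else {
    t <- unname(res$statistic); df <- unname(res$parameter)
    p <- res$p.value
  }
  structure(list(infraorder_means = means, has_haplodiploids = has_h,
                 group_means = c(with = mean(with_h),
                                 without = mean(without_h)),
                 t = t, df = df, p = p),
            class = "infraorder_test")
}

#' @export
print.infraorder_test <- function(x, digits = 3, ...) {
  cat("Infraorder comparison of diploid chromosome numbers\n")
  cat(sprintf("  %d infraorders, %d with haplodiploids nested within\n",
              length(x$infraorder_means), sum(x$has_haplodiploids)))
  cat(sprintf("  mean 2n: with = %.*g, without = %.*g\n", digits,
              x$group_means["with"], digits, x$group_means["without"]))
  cat(sprintf("  Welch t(%.*g) = %.*g, P = %.*g\n", digits, x$df,
              digits, x$t, digits, x$p))
  invisible(x)
}
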