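# Internal helpers shared across modules.

STATES <- c("D", "H")  # 1 = diplodiploid, 2 = haplodiploid

# Normalize taxon labels: case-insensitive, "_" treated as space,
# whitespace squeezed.
.norm_label <- function(x) {
  x <- tolower(gsub("_", " ", trimws(as.character(x))))
  gsub("[[:space:]]+", " ", x)
}

.genus_of <- function(x) sub(" .*$", "", .norm_label(x))

# Coerce user-supplied reproductive-system labels to the internal
# two-state coding. Accepts D/H, full words, or the internal codes.
.norm_system <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("d", "dd", "diplodiploid", "diplodiploidy", "diploid")] <- "D"
  out[s %in% c("h", "hd", "haplodiploid", "haplodiploidy")] <- "H"
  if (anyNA(out[!is.na(s) & nzchar(s)])) {
    bad <- unique(s[is.na(out) & !is.na(s) & nzchar(s)])
    stop("unrecognized reproductive system value(s): ",
         paste(bad, collapse = ", "))
  }
  out
}

# Tip states as integer 1/2 in tree tip order. `states` must be a named
# vector covering every tip.
.states_int <- function(tree, states) {
  s <- .norm_system(states)
  names(s) <- names(states)
  if (is.null(names(s))) {
    if (length(s) != ape::Ntip(tree))
      stop("unnamed state vector must have one entry per tip")
    names(s) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(s))
  if (length(miss))
    stop("no reproductive system for tip(s): ", paste(miss, collapse = ", "))
  out <- match(s[tree$tip.label], STATES)
  if (anyNA(out)) stop("missing state for some tips")
  names(out) <- tree$tip.label
  out
}

.check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an object of class 'phylo'")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; all analyses require time-calibrated branches")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  invisible(tree)
}

.as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo")) trees <- unclass(trees)
  lapply(trees, .check_tree)
  trees
}

.tree_height <- function(tree) max(ape::node.depth.edgelength(tree))

# Postorder edge ordering indices for a phylo object (children before
# parents), without mutating the tree.
.postorder_idx <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  key <- function(e) paste(e[, 1], e[, 2])
  match(key(tr$edge), key(tree$edge))
}

# Split-half Rhat for a single chain (or pooled chains given as list).
.split_rhat <- function(x) {
  if (is.list(x)) x <- unlist(x)
  n <- length(x) %/% 2L
  if (n < 10L) return(NA_real_)
  halves <- list(x[seq_len(n)], x[n + seq_len(n)])
  m <- vapply(halves, mean, 0)
  v <- vapply(halves, stats::var, 0)
  W <- mean(v)
  B <- n * stats::var(m)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Derive a stream of well-separated 31-bit seeds from one master seed.
.derive_seeds <- function(seed, n) {
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

.quantile_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE, na.rm = TRUE)
}
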