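#' Read a set of time trees from Newick or Nexus
#'
#' Reads one or more rooted trees with branch lengths. Nexus files
#' (including a TRANSLATE block) are handled by [ape::read.nexus()],
#' Newick by [ape::read.tree()]. Every tree must carry branch lengths:
#' all downstream models are time-calibrated, so trees without branch
#' lengths are an error, never defaulted.
#'
#' @param path path to a tree file.
#' @param format `"auto"` (detect `#NEXUS` header), `"newick"` or
#'   `"nexus"`.
#' @return an object of class `multiPhylo` (a list of `phylo` trees).
#' @seealso [write_tree_set()], [check_ultrametric()]
#' @export
read_tree_set <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "auto") {
    head <- readLines(path, n = 5L, warn = FALSE)
    head <- head[nzchar(trimws(head))]
    format <- if (length(head) && grepl("^#NEXUS", toupper(trimws(head[1]))))
      "nexus" else "newick"
  }
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) stop("could not parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (is.null(trees)) stop("no trees found in ", path)
  if (inherits(trees, "phylo")) trees <- c(ape::as.phylo(trees))
  if (!length(trees)) stop("no trees found in ", path)
  for (i in seq_along(trees)) {
    if (is.null(trees[[i]]$edge.length))
      stop("tree ", i, " in '", path, "' has no branch lengths; ",
           "time-calibrated branch lengths are required")
    .check_tree(trees[[i]])
  }
  class(trees) <- "multiPhylo"
  trees
}

#' Write a set of trees
#'
#' @param trees a `phylo`, `multiPhylo`, or list of `phylo` objects.
#' @param path output file.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_tree_set <- function(trees, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  trees <- .as_tree_list(trees)
  class(trees) <- "multiPhylo"
  if (format == "nexus") ape::write.nexus(trees, file = path)
  else ape::write.tree(trees, file = path)
  invisible(path)
}

#' Read a per-taxon trait table
#'
#' Expects a delimited table with (at least) columns `taxon` and
#' `system`; optional columns `infraorder`, `family`, `genus`,
#' `species`, `count_2n` (diploid chromosome count in females) and
#' `sex_determination` (`XY`/`XO`). The reproductive system is coerced
#' to the two internal states `"D"` (diplodiploid) and `"H"`
#' (haplodiploid).
#'
#' @param path CSV (default) or TSV file; tab separation is assumed for
#'   `.tsv`/`.txt` extensions.
#' @return a `data.frame`, one row per record.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  names(tab) <- tolower(names(tab))
  if (!all(c("taxon", "system") %in% names(tab)))
    stop("trait table must have columns 'taxon' and 'system'")
  tab$system <- .norm_system(tab$system)
  if (!is.null(tab$count_2n)) {
    cn <- suppressWarnings(as.numeric(tab$count_2n))
    bad <- !is.na(cn) & (cn != round(cn) | cn < 2 | cn > 200)
    if (any(bad))
      stop("count_2n must be an integer in [2, 200]; offending rows: ",
           paste(which(bad), collapse = ", "))
    tab$count_2n <- cn
  }
  for (col in c("infraorder", "family", "genus", "species",
                "sex_determination"))
    if (is.null(tab[[col]])) tab[[col]] <- NA_character_
  tab
}

#' Check ultrametricity of a time tree
#'
#' Reports (never enforces) whether all root-to-tip path lengths agree
#' within a relative tolerance.
#'
#' @param tree a `phylo` object.
#' @param tol relative tolerance on root-to-tip depth spread.
#' @return a list with `is_ultrametric`, `max_rel_dev` and the tip
#'   depths.
#' @export
check_ultrametric <- function(tree, tol = 1e-6) {
  .check_tree(tree)
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(d)
  dev <- if (h > 0) (max(d) - min(d)) / h else 0
  list(is_ultrametric = dev <= tol, max_rel_dev = dev, tip_depths = d)
}

#' Prune a tree to a set of tips
#'
#' Induced subtree on `keep_labels`: unsampled tips are removed,
#' degree-two internal nodes are suppressed with their branch lengths
#' summed, so root-to-tip depths and all pairwise patristic distances
#' among kept tips are preserved exactly.
#'
#' @param tree a `phylo` object.
#' @param keep_labels tip labels to retain (at least 2, all present).
#' @return the pruned `phylo`.
#' @export
prune_to <- function(tree, keep_labels) {
  .check_tree(tree)
  keep_labels <- as.character(keep_labels)
  miss <- setdiff(keep_labels, tree$tip.label)
  if (length(miss))
    stop("labels not in tree: ", paste(miss, collapse = ", "))
  if (length(unique(keep_labels)) < 2)
    stop("need at least 2 tips to keep")
  ape::keep.tip(tree, keep_labels)
}

# Collapse a clade (given by its tip labels) to a single tip whose
# branch ends at the clade's original crown-node depth. The stem edge
# is retained; on an ultrametric tree the collapsed tip therefore ends
# *before* the present, preserving the time scale of the stem.
.collapse_clade <- function(tree, tips, new_label) {
  if (length(tips) == 1L) {
    tree$tip.label[tree$tip.label == tips] <- new_label
    return(tree)
  }
  depths <- ape::node.depth.edgelength(tree)
  crown <- ape::getMRCA(tree, tips)
  crown_depth <- depths[crown]
  keep <- tips[1L]
  tree <- ape::drop.tip(tree, setdiff(tips, keep))
  depths2 <- ape::node.depth.edgelength(tree)
  i <- which(tree$tip.label == keep)
  ed <- which(tree$edge[, 2] == i)
  excess <- depths2[i] - crown_depth
  if (excess > tree$edge.length[ed] + 1e-9)
    excess <- tree$edge.length[ed]  # degenerate: do not create negative edges
  tree$edge.length[ed] <- tree$edge.length[ed] - excess
  tree$tip.label[i] <- new_label
  tree
}

#' Match tree tips against a trait table
#'
#' Implements an iterative tip-matching procedure between a phylogeny
#' and a taxon-level trait compilation:
#' \enumerate{
#'   \item exact species matches (labels compared case-insensitively,
#'     with underscores treated as spaces) are kept;
#'   \item each genus on the tree with zero species-level matches is
#'     collapsed to a single tip ending at the genus crown-node depth
#'     and matched against all records of that genus;
#'   \item remaining unmatched tips whose genus can be placed in a
#'     family present in the table (or whose label token is itself a
#'     family name) are collapsed per family and matched against that
#'     family's records;
#'   \item tips that still have no record are pruned.
#' }
#' When several records match one tip, the mean `count_2n` is attached;
#' the discrete reproductive system must agree across the matched
#' records, otherwise an error lists the conflict.
#'
#' @param tree a `phylo` object, or a `matched_dataset` (in which case
#'   re-matching is a no-op up to bookkeeping and the call is
#'   idempotent).
#' @param table a trait `data.frame` as from [read_trait_table()].
#' @return an object of class `matched_dataset`: list with the pruned
#'   `tree`, a `traits` data frame (one row per tip: `taxon`, `system`,
#'   `count_2n`, `match_level`, `n_records`, taxonomy columns) and
#'   `metadata` describing conventions.
#' @export
match_tips <- function(tree, table) {
  if (inherits(tree, "matched_dataset")) {
    if (missing(table)) table <- tree$traits
    tree <- tree$tree
  }
  .check_tree(tree)
  if (!nrow(table)) stop("trait table is empty")
  if (is.null(table$taxon) || is.null(table$system))
    stop("trait table must have columns 'taxon' and 'system'")
  table$system <- .norm_system(table$system)
  if (is.null(table$count_2n)) table$count_2n <- NA_real_
  for (col in c("infraorder", "family", "genus"))
    if (is.null(table[[col]])) table[[col]] <- NA_character_

  tab_taxon <- .norm_label(table$taxon)
  tab_genus <- ifelse(is.na(table$genus) | !nzchar(table$genus),
                      .genus_of(table$taxon), .norm_label(table$genus))
  tab_family <- .norm_label(table$family)

  rec_pool <- function(idx, tip_label) {
    sys <- unique(table$system[idx])
    if (length(sys) > 1)
      stop("conflicting reproductive systems among records matched to tip '",
           tip_label, "': rows ", paste(idx, collapse = ", "),
           " give states {", paste(sys, collapse = ", "), "}")
    cnt <- table$count_2n[idx]
    cnt <- if (all(is.na(cnt))) NA_real_ else mean(cnt, na.rm = TRUE)
    list(system = sys, count_2n = cnt,
         infraorder = {
           v <- unique(stats::na.omit(table$infraorder[idx]))
           if (length(v) == 1) v else NA_character_
         },
         family = {
           v <- unique(stats::na.omit(table$family[idx]))
           if (length(v) == 1) v else NA_character_
         },
         n_records = length(idx))
  }

  rows <- list()
  # --- pass 1: exact species matches -------------------------------
  tip_norm <- .norm_label(tree$tip.label)
  species_hit <- lapply(tip_norm, function(tl) which(tab_taxon == tl))
  matched <- vapply(species_hit, length, 1L) > 0L
  for (i in which(matched)) {
    r <- rec_pool(species_hit[[i]], tree$tip.label[i])
    rows[[tree$tip.label[i]]] <- data.frame(
      taxon = tree$tip.label[i], system = r$system, count_2n = r$count_2n,
      match_level = "species", n_records = r$n_records,
      infraorder = r$infraorder, family = r$family,
      genus = .genus_of(tree$tip.label[i]), stringsAsFactors = FALSE)
  }
  matched_labels <- tree$tip.label[matched]

  # --- pass 2: genus-level collapsing ------------------------------
  tip_genus <- .genus_of(tree$tip.label)
  genus_has_species_match <- unique(tip_genus[matched])
  todo <- setdiff(unique(tip_genus[!matched]), genus_has_species_match)
  for (g in todo) {
    idx <- which(tab_genus == g)
    if (!length(idx)) next
    members <- tree$tip.label[.genus_of(tree$tip.label) == g &
                                !(tree$tip.label %in% matched_labels)]
    new_label <- paste0(tools::toTitleCase(g), "_sp")
    r <- rec_pool(idx, new_label)
    tree <- .collapse_clade(tree, members, new_label)
    rows[[new_label]] <- data.frame(
      taxon = new_label, system = r$system, count_2n = r$count_2n,
      match_level = "genus", n_records = r$n_records,
      infraorder = r$infraorder, family = r$family, genus = g,
      stringsAsFactors = FALSE)
    matched_labels <- c(matched_labels, new_label)
  }

  # --- pass 3: family-level collapsing -----------------------------
  genus2family <- tapply(tab_family, tab_genus, function(f) {
    f <- unique(stats::na.omit(f[nzchar(f)]))
    if (length(f) == 1) f else NA_character_
  })
  unmatched <- setdiff(tree$tip.label, matched_labels)
  if (length(unmatched)) {
    tg <- .genus_of(unmatched)
    fam <- unname(genus2family[tg])
    direct <- tg %in% tab_family[nzchar(tab_family)]
    fam[is.na(fam) & direct] <- tg[is.na(fam) & direct]
    for (f in unique(stats::na.omit(fam))) {
      idx <- which(tab_family == f)
      if (!length(idx)) next
      members <- unmatched[!is.na(fam) & fam == f]
      new_label <- paste0(tools::toTitleCase(f), "_sp")
      r <- rec_pool(idx, new_label)
      tree <- .collapse_clade(tree, members, new_label)
      rows[[new_label]] <- data.frame(
        taxon = new_label, system = r$system, count_2n = r$count_2n,
        match_level = "family", n_records = r$n_records,
        infraorder = r$infraorder, family = f, genus = NA_character_,
        stringsAsFactors = FALSE)
      matched_labels <- c(matched_labels, new_label)
    }
  }

  if (length(matched_labels) < 2)
    stop("fewer than 2 tips could be matched between tree and trait table")
  drop <- setdiff(tree$tip.label, matched_labels)
  if (length(drop)) tree <- ape::drop.tip(tree, drop)

  traits <- do.call(rbind, rows[tree$tip.label])
  rownames(traits) <- NULL
  structure(list(
    tree = tree, traits = traits,
    metadata = list(
      collapsed_tip_convention =
        "collapsed genus/family tips end at the original crown-node depth",
      label_normalization = "case-insensitive, underscore = space")),
    class = "matched_dataset")
}

#' @export
print.matched_dataset <- function(x, ...) {
  lv <- table(x$traits$match_level)
  cat("Matched dataset:", ape::Ntip(x$tree), "tips (",
      paste(sprintf("%s: %d", names(lv), as.integer(lv)), collapse = ", "),
      ")\n")
  cat("  haplodiploid:", sum(x$traits$system == "H"),
      " diplodiploid:", sum(x$traits$system == "D"), "\n")
  um <- check_ultrametric(x$tree)
  cat("  ultrametric:", um$is_ultrametric,
      sprintf("(max relative depth deviation %.2e)\n", um$max_rel_dev))
  invisible(x)
}

# Named state vector ("D"/"H") for a matched dataset.
#' Extract tip states or chromosome counts from a matched dataset
#' @param x a `matched_dataset`.
#' @return `tip_systems()`: named character vector of `"D"`/`"H"`;
#'   `tip_counts()`: named numeric vector of diploid counts.
#' @export
tip_systems <- function(x) {
  stopifnot(inherits(x, "matched_dataset"))
  stats::setNames(x$traits$system, x$traits$taxon)
}

#' @rdname tip_systems
#' @export
tip_counts <- function(x) {
  stopifnot(inherits(x, "matched_dataset"))
  stats::setNames(x$traits$count_2n, x$traits$taxon)
}
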