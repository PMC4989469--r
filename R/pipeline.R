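# End-to-end orchestration: match -> model comparison -> stochastic
# mapping -> origin test -> mixed models, with a reproducible
# manifest. All randomness flows from one master seed through
# per-stage derived seeds.

#' Run the full comparative analysis
#'
#' Executes every stage of the analysis from one configuration:
#' tip matching (or synthetic-data generation), one- vs two-rate
#' model comparison with AICc, optional single-tip sensitivity
#' re-analysis, stochastic mapping with origin counts under both
#' models, the Monte Carlo origin-node chromosome test, the
#' phylogenetic and taxonomic mixed models, and the threshold model.
#' A failed stage is recorded and stages depending on it are skipped;
#' independent stages still run. Results, CSV tables, a JSON report
#' and a manifest (seeds, input hashes, versions) are written to
#' `outdir`.
#'
#' @param config a named list or the path of a YAML file. Recognized
#'   fields: `trees`, `traits` (input paths) or `simulate` (list of
#'   [sim_config()] arguments); `outdir`; `variant` (`"full"` or
#'   `"species_only"`); `drop_tip` (optional label for the
#'   sensitivity re-analysis); `n_trees_use`; `n_maps`; `null_reps`;
#'   `lmm` and `threshold` (lists: `n_iter`, `burnin`, `thin`);
#'   `seed`.
#' @return an object of class `ploidyshift_report` (invisibly the
#'   full results list), written to `outdir` as `report.json`,
#'   `report.md`, `manifest.json` and `tables/*.csv`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(list(
    outdir = tempfile("ploidyshift_run_"), variant = "full",
    drop_tip = NULL, n_trees_use = NULL, n_maps = 10L, null_reps = 100L,
    lmm = list(n_iter = 20000L, burnin = 5000L, thin = 10L),
    threshold = list(n_iter = 8000L, burnin = 3000L, thin = 10L),
    seed = 1L), config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$outdir, "tables"), showWarnings = FALSE)
  seeds <- .derive_seeds(cfg$seed, 8L)
  results <- list(config = cfg)
  errors <- list()
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      message("stage '", name, "' failed: ", conditionMessage(e))
      NULL
    })
    results[[name]] <<- out
    out
  }

  # --- data ---------------------------------------------------------
  input_hashes <- NULL
  if (!is.null(cfg$simulate)) {
    sc <- do.call(sim_config, utils::modifyList(list(seed = seeds[1]),
                                                cfg$simulate))
    nset <- cfg$n_trees_use %||% 1L
    simdat <- simulate_dataset(sc, n_trees = nset)
    trees <- simdat$trees
    table <- simdat$table
    results$simulation_truth <- list(n_origins = simdat$n_origins,
                                     config = unclass(sc))
  } else {
    trees <- read_tree_set(cfg$trees)
    table <- read_trait_table(cfg$traits)
    input_hashes <- as.list(tools::md5sum(c(cfg$trees, cfg$traits)))
    if (!is.null(cfg$n_trees_use))
      trees <- trees[seq_len(min(cfg$n_trees_use, length(trees)))]
  }
  matched <- stage("matched", {
    ms <- lapply(trees, match_tips, table = table)
    ms
  })
  if (is.null(matched)) stop("tip matching failed; cannot continue")
  if (cfg$variant == "species_only") {
    matched <- lapply(matched, function(m) {
      keep <- m$traits$taxon[m$traits$match_level == "species"]
      mm <- m
      mm$tree <- prune_to(m$tree, keep)
      mm$traits <- m$traits[m$traits$taxon %in% keep, ]
      mm
    })
    results$matched <- matched
  }
  mtrees <- lapply(matched, `[[`, "tree")
  traits <- matched[[1L]]$traits
  systems <- tip_systems(matched[[1L]])
  counts <- tip_counts(matched[[1L]])

  # --- Mk model comparison -----------------------------------------
  comparison <- stage("comparison", compare_mk_models(mtrees, systems))
  if (!is.null(cfg$drop_tip))
    stage("sensitivity",
          drop_tip_sensitivity(mtrees, systems, cfg$drop_tip))

  # --- stochastic mapping / origins --------------------------------
  stage("origins_one_rate",
        summarize_origins(mtrees, systems, "one_rate",
                          n_maps = cfg$n_maps, seed = seeds[2]))
  stage("origins_two_rate",
        summarize_origins(mtrees, systems, "two_rate",
                          n_maps = cfg$n_maps, seed = seeds[3]))

  # --- origin-node chromosome test ---------------------------------
  stage("origin_test", {
    per_tree <- lapply(seq_along(mtrees), function(i)
      monte_carlo_origin_test(mtrees[[i]], systems, counts,
                              model = "one_rate", n_maps = cfg$n_maps,
                              R = cfg$null_reps,
                              seed = (seeds[4] %% 1000000000L) + i))
    pooled <- aggregate_origin_tests(per_tree)
    list(per_tree = per_tree, pooled = pooled)
  })

  # --- infraorder comparison ---------------------------------------
  stage("infraorder", infraorder_test(traits))

  # --- mixed models -------------------------------------------------
  ok <- !is.na(counts)
  stage("phylo_lmm", {
    lmm_trees <- if (all(ok)) mtrees else
      lapply(mtrees, function(tr) prune_to(tr, names(counts)[ok]))
    phylo_lmm(lmm_trees, log(counts[ok]), systems[ok],
              n_iter = cfg$lmm$n_iter, burnin = cfg$lmm$burnin,
              thin = cfg$lmm$thin, seed = seeds[5])
  })
  stage("taxonomic_lmm",
        taxonomic_lmm(traits, n_iter = cfg$lmm$n_iter,
                      burnin = cfg$lmm$burnin, thin = cfg$lmm$thin,
                      seed = seeds[6]))
  stage("threshold", {
    tr1 <- if (all(ok)) mtrees[[1L]] else
      prune_to(mtrees[[1L]], names(counts)[ok])
    threshold_model(tr1, log(counts[ok]), systems[ok],
                    n_iter = cfg$threshold$n_iter,
                    burnin = cfg$threshold$burnin,
                    thin = cfg$threshold$thin, seed = seeds[7])
  })

  results$errors <- errors
  report <- .assemble_report(results)
  results$report <- report
  .write_report(results, cfg, seeds, input_hashes)
  class(results) <- "ploidyshift_report"
  invisible(results)
}

.assemble_report <- function(res) {
  rep <- list()
  if (!is.null(res$comparison)) rep$model_comparison <- list(
    mean_delta_aicc = res$comparison$mean_delta_aicc,
    mean_delta_aic = res$comparison$mean_delta_aic,
    preferred = res$comparison$preferred)
  if (!is.null(res$sensitivity)) rep$sensitivity <- list(
    dropped = res$sensitivity$dropped,
    mean_delta_aicc = res$sensitivity$mean_delta_aicc,
    preferred = res$sensitivity$preferred)
  for (m in c("origins_one_rate", "origins_two_rate"))
    if (!is.null(res[[m]])) rep[[m]] <- list(
      mean = res[[m]]$mean, sd = res[[m]]$sd,
      per_tree_mean = res[[m]]$per_tree_mean)
  if (!is.null(res$origin_test)) rep$origin_test <- res$origin_test$pooled
  if (!is.null(res$infraorder)) rep$infraorder <- list(
    t = res$infraorder$t, df = res$infraorder$df, p = res$infraorder$p,
    group_means = as.list(res$infraorder$group_means))
  for (m in c("phylo_lmm", "taxonomic_lmm"))
    if (!is.null(res[[m]])) rep[[m]] <- list(
      beta = res[[m]]$beta, beta_ci = res[[m]]$beta_ci,
      p_mcmc = res[[m]]$p_mcmc,
      heritability = res[[m]]$heritability,
      heritability_ci = res[[m]]$heritability_ci)
  if (!is.null(res$threshold)) rep$threshold <- list(
    r = res$threshold$r, r_ci = res$threshold$r_ci)
  if (!is.null(res$simulation_truth))
    rep$simulation_truth <- res$simulation_truth["n_origins"]
  rep$failed_stages <- names(res$errors)
  rep
}

.write_report <- function(res, cfg, seeds, input_hashes) {
  out <- cfg$outdir
  jsonlite::write_json(res$report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "ploidyshift",
    version = as.character(utils::packageVersion("ploidyshift")),
    r_version = R.version.string,
    master_seed = cfg$seed, stage_seeds = seeds,
    input_hashes = input_hashes,
    variant = cfg$variant,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(res$comparison))
    utils::write.csv(res$comparison$table,
                     file.path(out, "tables", "model_comparison.csv"),
                     row.names = FALSE)
  if (!is.null(res$origin_test))
    utils::write.csv(do.call(rbind, lapply(res$origin_test$per_tree,
                                           `[[`, "table")),
                     file.path(out, "tables", "origin_test.csv"),
                     row.names = FALSE)
  md <- c("# ploidyshift analysis report", "",
          vapply(names(res$report), function(k)
            paste0("- **", k, "**: ",
                   jsonlite::toJSON(res$report[[k]], auto_unbox = TRUE,
                                    digits = 6)), ""))
  writeLines(md, file.path(out, "report.md"))
  invisible(out)
}

#' @export
print.ploidyshift_report <- function(x, ...) {
  cat("ploidyshift pipeline report (outdir:", x$config$outdir, ")\n")
  str(x$report, max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Diagnostic figures for a pipeline run
#'
#' Writes three figures: (1) the first tree painted with per-node
#' posterior probabilities of each reproductive system; (2) a
#' jittered scatterplot of chromosome number by system with group
#' means; (3) the tree colored by the Brownian-motion reconstruction
#' of chromosome number.
#'
#' @param result a `ploidyshift_report` from [run_pipeline()].
#' @param outdir output directory (defaults to `<run outdir>/figures`).
#' @return character vector of the files written.
#' @export
make_figures <- function(result, outdir = NULL) {
  stopifnot(inherits(result, "ploidyshift_report"))
  outdir <- outdir %||% file.path(result$config$outdir, "figures")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  m <- result$matched[[1L]]
  tree <- m$tree
  systems <- tip_systems(m)
  counts <- tip_counts(m)
  files <- character(0)

  fit <- result$comparison
  if (!is.null(fit)) {
    q1 <- fit$table$q_DH_one[1L]
    post <- marginal_node_posteriors(tree, systems, q1, 0, "fixed_D")
    f <- file.path(outdir, "ancestral_system.png")
    grDevices::png(f, 900, 900)
    graphics::par(mar = c(1, 1, 2, 1))
    ape::plot.phylo(tree, cex = 0.6, main = "P(haplodiploid) at nodes")
    nt <- ape::Ntip(tree)
    ape::nodelabels(pie = post[(nt + 1):nrow(post), , drop = FALSE],
                    piecol = c("grey85", "firebrick"), cex = 0.4)
    ape::tiplabels(pch = 19, cex = 0.6,
                   col = ifelse(systems[tree$tip.label] == "H",
                                "firebrick", "grey60"))
    grDevices::dev.off()
    files <- c(files, f)
  }

  ok <- !is.na(counts)
  if (any(ok)) {
    f <- file.path(outdir, "counts_by_system.png")
    grDevices::png(f, 700, 600)
    sys <- factor(ifelse(systems[ok] == "H", "haplodiploid",
                         "diplodiploid"))
    graphics::plot(jitter(as.integer(sys), 0.3), counts[ok],
                   xaxt = "n", xlab = "", ylab = "diploid count (2n)",
                   pch = 19, col = grDevices::adjustcolor("steelblue", 0.6),
                   xlim = c(0.5, 2.5),
                   main = "Chromosome number by reproductive system")
    graphics::axis(1, at = 1:2, labels = levels(sys))
    gm <- tapply(counts[ok], sys, mean)
    graphics::points(1:2, gm, pch = 18, cex = 2.2, col = "black")
    grDevices::dev.off()
    files <- c(files, f)
  }

  if (sum(ok & systems == "D") >= 3) {
    keep <- names(counts)[ok & systems == "D"]
    pr <- prune_to(tree, keep)
    asr <- bm_ancestral(pr, log(counts[keep]))
    f <- file.path(outdir, "ancestral_counts.png")
    grDevices::png(f, 900, 900)
    graphics::par(mar = c(1, 1, 2, 1))
    ape::plot.phylo(pr, cex = 0.6,
                    main = "Reconstructed 2n (diplodiploids)")
    est <- exp(asr$ace)
    pal <- grDevices::hcl.colors(100, "viridis")
    idx <- pmax(1, pmin(100, round(99 * (est - min(est)) /
                                     max(1e-9, diff(range(est)))) + 1))
    ape::nodelabels(round(est), bg = pal[idx], cex = 0.5)
    grDevices::dev.off()
    files <- c(files, f)
  }
  files
}
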