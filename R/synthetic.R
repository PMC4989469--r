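#' Configuration for the synthetic data generator
#'
#' Bundles the parameters of the joint tree/trait simulation. The
#' defaults describe the standard study conditions the package's
#' analyses are exercised under: a 100-tip pure-birth time tree; a
#' nearly irreversible binary reproductive system with a handful
#' (roughly 4-13) of independent origins of haplodiploidy; log diploid
#' chromosome number evolving by Brownian motion around 2n ~ 18 with
#' most tip counts in 4-28; a state-dependent transition hazard under
#' which lineages with fewer chromosomes convert to haplodiploidy more
#' readily; and a modest post-transition drift toward lower counts so
#' haplodiploid tips end up about 5 chromosomes below diplodiploids.
#'
#' @param n_tips number of extant tips (>= 4).
#' @param birth_rate,death_rate per-lineage per-time birth/death rates;
#'   `birth_rate > death_rate >= 0`.
#' @param q_DH0 baseline diplodiploid-to-haplodiploid transition rate
#'   (the hazard at log(2n) = 0; see `beta`).
#' @param q_HD haplodiploid-to-diplodiploid reversal rate (0 for an
#'   irreversible truth).
#' @param beta state-dependence coefficient: the D-to-H hazard at
#'   log-count x is `q_DH0 * exp(-beta * x)`, so `beta > 0` makes
#'   low-chromosome lineages transition faster and `beta = 0` decouples
#'   the traits.
#' @param sigma2 Brownian-motion rate of log(2n) per unit time.
#' @param x_root root value of log(2n).
#' @param ploidy_effect drift (per unit time) added to log(2n) on
#'   haplodiploid lineages; the accumulated shift grows linearly with
#'   time since the transition.
#' @param seed integer seed; every generator consuming the config is
#'   byte-reproducible given the seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_tips = 100L, birth_rate = 1, death_rate = 0,
                       q_DH0 = 4.5, q_HD = 0, beta = 1.5,
                       sigma2 = 0.05, x_root = log(18),
                       ploidy_effect = -0.15, seed = 1L) {
  stopifnot(n_tips >= 4, birth_rate > 0, death_rate >= 0,
            birth_rate > death_rate, q_DH0 >= 0, q_HD >= 0, sigma2 > 0)
  structure(list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
                 death_rate = death_rate, q_DH0 = q_DH0, q_HD = q_HD,
                 beta = beta, sigma2 = sigma2, x_root = x_root,
                 ploidy_effect = ploidy_effect, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-data configuration\n")
  for (f in names(x)) cat(sprintf("  %-13s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Simulate a birth-death time tree conditioned on its tip count
#'
#' Forward Gillespie simulation started from two lineages at the root.
#' The simulation stops at the instant the (n_tips + 1)-th extant
#' lineage would be born; the present is set to that instant, so the
#' final epoch at `n_tips` lineages is a full exponential waiting time.
#' Extinct lineages are pruned; a realization that dies out entirely is
#' retried. For a pure-birth (Yule) tree this construction gives
#' E\[root age\] = sum_{k=2}^{n} 1/(k * birth_rate).
#'
#' @param config a [sim_config()], or `n_tips` when rates are passed
#'   explicitly.
#' @param birth_rate,death_rate,seed override the config values.
#' @param max_retries retries allowed when the clade goes extinct.
#' @return an ultrametric `phylo` with exactly `n_tips` tips.
#' @export
simulate_bd_tree <- function(config, birth_rate = NULL, death_rate = NULL,
                             seed = NULL, max_retries = 100L) {
  if (inherits(config, "sim_config")) {
    n <- config$n_tips
    b <- birth_rate %||% config$birth_rate
    d <- death_rate %||% config$death_rate
    seed <- seed %||% config$seed
  } else {
    n <- as.integer(config)
    b <- birth_rate %||% 1
    d <- death_rate %||% 0
  }
  stopifnot(n >= 2, b > 0, d >= 0, b > d)
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_retries)) {
    tr <- .bd_forward_once(n, b, d)
    if (!is.null(tr)) return(tr)
  }
  stop("birth-death simulation failed to reach ", n,
       " extant tips in ", max_retries, " attempts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One forward realization; NULL on extinction.
.bd_forward_once <- function(n, b, d) {
  # lineage bookkeeping: parent lineage, start time, end time, fate
  cap <- 4L * n + 8L
  parent <- integer(cap); t0 <- numeric(cap); t1 <- numeric(cap)
  fate <- integer(cap)  # 0 alive, 1 split, 2 dead
  parent[1:2] <- 0L; t0[1:2] <- 0; fate[1:2] <- 0L
  m <- 2L               # lineages created
  alive <- c(1L, 2L)
  t <- 0
  repeat {
    k <- length(alive)
    if (k == 0L) return(NULL)
    t <- t + stats::rexp(1L, k * (b + d))
    birth <- stats::runif(1L) < b / (b + d)
    if (birth && k == n) { present <- t; break }
    who <- alive[sample.int(k, 1L)]
    if (birth) {
      if (m + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(t0) <- cap
        length(t1) <- cap; length(fate) <- cap
      }
      t1[who] <- t; fate[who] <- 1L
      kids <- m + 1:2
      parent[kids] <- who; t0[kids] <- t; fate[kids] <- 0L
      m <- m + 2L
      alive <- c(setdiff(alive, who), kids)
    } else {
      t1[who] <- t; fate[who] <- 2L
      alive <- setdiff(alive, who)
    }
  }
  t1[alive] <- present
  idx <- seq_len(m)
  is_leaf <- fate[idx] != 1L
  leaves <- idx[is_leaf]; internals <- idx[!is_leaf]
  ntip <- length(leaves)
  # ape numbering: tips 1..ntip, then a synthetic root node, internals after
  node_id <- integer(m)
  node_id[leaves] <- seq_len(ntip)
  node_id[internals] <- ntip + 1L + seq_along(internals)
  root_id <- ntip + 1L
  edge <- matrix(0L, m, 2); elen <- numeric(m)
  for (i in idx) {
    from <- if (parent[i] == 0L) root_id else node_id[parent[i]]
    edge[i, ] <- c(from, node_id[i])
    elen[i] <- t1[i] - t0[i]
  }
  tr <- list(edge = edge, edge.length = elen,
             tip.label = paste0("t", seq_len(ntip)),
             Nnode = length(internals) + 1L)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  extinct <- which(fate[leaves] == 2L)
  if (length(extinct)) {
    tr <- ape::drop.tip(tr, tr$tip.label[extinct])
    if (is.null(tr) || ape::Ntip(tr) != n) return(NULL)
    tr$tip.label <- paste0("t", seq_len(n))
  }
  tr
}

#' Simulate tip states under a two-state Markov chain
#'
#' Exact Gillespie simulation of the binary reproductive-system chain
#' along every branch, from a fixed root state.
#'
#' @param tree a `phylo` with branch lengths.
#' @param q_DH,q_HD transition rates (per unit time, >= 0).
#' @param root_state `"D"` or `"H"`.
#' @param seed optional integer seed.
#' @return named character vector of tip states (`"D"`/`"H"`).
#' @export
simulate_mk_tips <- function(tree, q_DH, q_HD, root_state = "D",
                             seed = NULL) {
  .check_tree(tree)
  stopifnot(q_DH >= 0, q_HD >= 0)
  if (!is.null(seed)) set.seed(seed)
  root_state <- match(match.arg(root_state, STATES), STATES)
  rates <- c(q_DH, q_HD)
  nt <- ape::Ntip(tree)
  state <- integer(nt + tree$Nnode)
  state[nt + 1L] <- root_state
  po <- .postorder_idx(tree)
  for (i in rev(po)) {  # preorder
    s <- state[tree$edge[i, 1]]
    len <- tree$edge.length[i]
    tt <- 0
    repeat {
      r <- rates[s]
      if (r <= 0) break
      tt <- tt + stats::rexp(1L, r)
      if (tt >= len) break
      s <- 3L - s
    }
    state[tree$edge[i, 2]] <- s
  }
  stats::setNames(STATES[state[seq_len(nt)]], tree$tip.label)
}

#' Jointly simulate reproductive system and chromosome number
#'
#' Log diploid chromosome number x = log(2n) evolves by Brownian motion
#' along every branch (Euler steps no longer than 1/1000 of tree
#' height, refined until hazard * dt <= 0.1). A diplodiploid lineage
#' converts to haplodiploidy with instantaneous hazard
#' `q_DH0 * exp(-beta * x(t))`, so with `beta > 0` low-count lineages
#' convert first; haplodiploid lineages revert with rate `q_HD`
#' (usually 0) and acquire an additional drift of `ploidy_effect` per
#' unit time on x. Tip counts are `round(exp(x))` clamped to >= 4. The
#' complete realized history is returned so downstream inferences can
#' be scored against the truth.
#'
#' @param tree an ultrametric `phylo`.
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list with `systems` (named `"D"`/`"H"`), `count_2n` (named
#'   integer), `tip_x` and `node_x` (log-scale values; `node_x` indexed
#'   by ape node id), `history` (a [simmap_history] holding the true
#'   character history) and `n_origins` (true number of D-to-H events,
#'   root origin included).
#' @export
simulate_joint_traits <- function(tree, config, seed = NULL) {
  .check_tree(tree)
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% config$seed)
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  height <- .tree_height(tree)
  dt0 <- height / 1000
  x <- numeric(nt + nn); s <- integer(nt + nn)
  x[nt + 1L] <- config$x_root; s[nt + 1L] <- 1L
  maps <- vector("list", nrow(tree$edge))
  po <- .postorder_idx(tree)
  for (i in rev(po)) {
    from <- tree$edge[i, 1]; to <- tree$edge[i, 2]
    seg <- .sim_edge_joint(x[from], s[from], tree$edge.length[i],
                           config, dt0)
    x[to] <- seg$x_end; s[to] <- seg$s_end
    maps[[i]] <- seg$map
  }
  tip_x <- x[seq_len(nt)]
  counts <- pmax(4, round(exp(tip_x)))
  systems <- stats::setNames(STATES[s[seq_len(nt)]], tree$tip.label)
  hist <- .new_simmap(tree, maps, node_states = s,
                      tip_states = systems, root_state = STATES[s[nt + 1L]])
  list(systems = systems,
       count_2n = stats::setNames(as.integer(counts), tree$tip.label),
       tip_x = stats::setNames(tip_x, tree$tip.label),
       node_x = x, history = hist, n_origins = count_origins(hist))
}

# Simulate one edge of the joint process. Returns end values and a
# simmap-style named duration vector.
.sim_edge_joint <- function(x0, s0, len, config, dt0) {
  if (len <= 0)
    return(list(x_end = x0, s_end = s0,
                map = stats::setNames(0, STATES[s0])))
  nstep <- max(2L, ceiling(len / dt0))
  cap <- 64L * nstep
  repeat {
    dt <- len / nstep
    xs <- numeric(nstep + 1L); ss <- integer(nstep + 1L)
    xs[1] <- x0; ss[1] <- s0
    ok <- TRUE
    dW <- stats::rnorm(nstep, 0, sqrt(config$sigma2 * dt))
    u <- stats::runif(nstep)
    for (k in seq_len(nstep)) {
      st <- ss[k]
      drift <- if (st == 2L) config$ploidy_effect * dt else 0
      haz <- if (st == 1L) config$q_DH0 * exp(-config$beta * xs[k])
             else config$q_HD
      if (haz * dt > 0.1 && nstep < cap) {
        ok <- FALSE; break
      }
      flip <- u[k] < 1 - exp(-haz * dt)
      ss[k + 1L] <- if (flip) 3L - st else st
      xs[k + 1L] <- xs[k] + drift + dW[k]
    }
    if (ok) break
    nstep <- nstep * 2L
  }
  # compress the step-wise state path into simmap segments
  chg <- which(ss[-1] != ss[-(nstep + 1L)])
  bounds <- c(0, chg * dt, len)
  states <- STATES[ss[c(1L, chg + 1L)]]
  map <- stats::setNames(diff(bounds), states)
  list(x_end = xs[nstep + 1L], s_end = ss[nstep + 1L], map = map)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: simulates a birth-death tree under `config`,
#' then the joint trait process on it, and formats the result as a
#' trait table compatible with [match_tips()] and the analysis
#' functions. Tips are assigned round-robin to synthetic genera,
#' families and infraorders so the taxonomic mixed model has nested
#' levels to work with.
#'
#' @param config a [sim_config()].
#' @param n_trees number of independent replicate trees (the first
#'   carries the focal trait realization; additional trees act as a
#'   stand-in for a posterior tree set and share no trait data).
#' @return list with `tree`, `trees` (list, length `n_trees`),
#'   `systems`, `count_2n`, `table` (trait data frame), `history`,
#'   `n_origins`, `node_x`, and the `config`.
#' @export
simulate_dataset <- function(config = sim_config(), n_trees = 1L) {
  seeds <- .derive_seeds(config$seed, n_trees + 1L)
  trees <- lapply(seq_len(n_trees), function(i)
    simulate_bd_tree(config, seed = seeds[i]))
  tr <- trees[[1L]]
  sim <- simulate_joint_traits(tr, config, seed = seeds[n_trees + 1L])
  nt <- ape::Ntip(tr)
  genus <- paste0("Genus", ((seq_len(nt) - 1L) %/% 2L) + 1L)
  family <- paste0("Family", ((seq_len(nt) - 1L) %/% 6L) + 1L)
  infra <- paste0("Infra", ((seq_len(nt) - 1L) %/% 12L) + 1L)
  table <- data.frame(
    taxon = tr$tip.label, infraorder = infra, family = family,
    genus = genus, species = tr$tip.label,
    system = ifelse(sim$systems == "H", "haplodiploid", "diplodiploid"),
    count_2n = as.numeric(sim$count_2n),
    sex_determination = NA_character_, stringsAsFactors = FALSE)
  c(list(tree = tr, trees = trees, table = table), sim,
    list(config = config))
}
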