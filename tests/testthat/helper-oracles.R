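# Independent oracles and shared fixtures for the test suite. All
# oracles use a different computational route than the implementation
# they check (enumeration, dense linear algebra, closed forms).

# Brute-force Mk likelihood: sum over all internal-state assignments
# of products of closed-form transition probabilities and root
# weights.
enum_mk_loglik <- function(tree, states, q_DH, q_HD, root_mode) {
  nt <- ape::Ntip(tree)
  s <- match(states[tree$tip.label], c("D", "H"))
  nn <- tree$Nnode
  pi0 <- if (root_mode == "fixed_D") c(1, 0)
         else c(q_HD, q_DH) / (q_DH + q_HD)
  Ps <- lapply(tree$edge.length, function(t)
    binary_transition_matrix(q_DH, q_HD, t))
  tot <- 0
  for (assign in 0:(2^nn - 1)) {
    a <- as.integer(intToBits(assign))[seq_len(nn)] + 1L
    full <- c(s, a)
    p <- pi0[full[nt + 1]]
    for (i in seq_len(nrow(tree$edge)))
      p <- p * Ps[[i]][full[tree$edge[i, 1]], full[tree$edge[i, 2]]]
    tot <- tot + p
  }
  log(tot)
}

# Enumeration-based marginal posterior at one node.
enum_node_posterior <- function(tree, states, q_DH, q_HD, root_mode, node) {
  nt <- ape::Ntip(tree)
  s <- match(states[tree$tip.label], c("D", "H"))
  nn <- tree$Nnode
  pi0 <- if (root_mode == "fixed_D") c(1, 0)
         else c(q_HD, q_DH) / (q_DH + q_HD)
  Ps <- lapply(tree$edge.length, function(t)
    binary_transition_matrix(q_DH, q_HD, t))
  num <- c(0, 0); tot <- 0
  for (assign in 0:(2^nn - 1)) {
    a <- as.integer(intToBits(assign))[seq_len(nn)] + 1L
    full <- c(s, a)
    p <- pi0[full[nt + 1]]
    for (i in seq_len(nrow(tree$edge)))
      p <- p * Ps[[i]][full[tree$edge[i, 1]], full[tree$edge[i, 2]]]
    num[full[node]] <- num[full[node]] + p
    tot <- tot + p
  }
  num / tot
}

# Dense-matrix GLS oracle for BM ancestral reconstruction: estimates,
# ML rate and prediction variances from the full node-node covariance.
gls_bm <- function(tree, x) {
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  d <- ape::dist.nodes(tree)
  dep <- d[root, ]
  Call <- (outer(dep, dep, "+") - d) / 2
  ids <- (nt + 1L):(nt + tree$Nnode)
  Ctt <- Call[seq_len(nt), seq_len(nt)]
  Ci <- solve(Ctt)
  xo <- x[tree$tip.label]
  mu <- sum(Ci %*% xo) / sum(Ci)
  sigma2 <- as.numeric(t(xo - mu) %*% Ci %*% (xo - mu)) / nt
  Cnt <- Call[ids, seq_len(nt), drop = FALSE]
  ace <- mu + Cnt %*% Ci %*% (xo - mu)
  h <- 1 - Cnt %*% Ci %*% rep(1, nt)
  V <- sigma2 * (Call[ids, ids] - Cnt %*% Ci %*% t(Cnt) +
                   (h %*% t(h)) / sum(Ci))
  list(ace = stats::setNames(as.vector(ace), ids), sigma2 = sigma2,
       var = stats::setNames(diag(as.matrix(V)), ids), root = mu)
}

# Random non-ultrametric tree for likelihood oracles.
rand_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}

# Random states guaranteeing at least one of each when possible.
rand_states <- function(tree) {
  n <- ape::Ntip(tree)
  s <- sample(c("D", "H"), n, replace = TRUE)
  s[1] <- "D"; s[2] <- "H"
  stats::setNames(s, tree$tip.label)
}

# The nested-diplodiploid-tip fixture: a large haplodiploid clade with
# one diplodiploid tip buried inside it (analogous to a misplaced or
# genuinely reverted family-level record). Returns tree, states and
# the label of the nested tip.
nested_tip_fixture <- function() {
  set.seed(7)
  tr <- ape::rcoal(30)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  nt <- 30L
  cl <- NULL
  for (nd in (nt + 2L):(nt + tr$Nnode)) {
    tips <- ape::extract.clade(tr, nd)$tip.label
    if (length(tips) >= 10 && length(tips) <= 16) { cl <- nd; break }
  }
  tips <- ape::extract.clade(tr, cl)$tip.label
  st <- stats::setNames(rep("D", nt), tr$tip.label)
  st[tips] <- "H"
  nested <- tips[5]
  st[nested] <- "D"
  list(tree = tr, states = st, nested = nested)
}

# A small matched-data fixture: 6-tip ultrametric tree and a trait
# table exercising species, genus and family matching.
matching_fixture <- function() {
  tree <- ape::read.tree(text = paste0(
    "((Aus_primus:1,(Xus_a:0.4,(Xus_b:0.2,Xus_c:0.2):0.2):0.6):1,",
    "(Bus_secundus:1.5,Zus_ignotus:1.5):0.5);"))
  table <- data.frame(
    taxon = c("Aus primus", "Bus secundus", "Xus sp", "Aus primus"),
    infraorder = c("I1", "I2", "I1", "I1"),
    family = c("Aidae", "Bidae", "Xidae", "Aidae"),
    genus = c("Aus", "Bus", "Xus", "Aus"),
    species = c("primus", "secundus", NA, "primus"),
    system = c("diplodiploid", "diplodiploid", "haplodiploid",
               "diplodiploid"),
    count_2n = c(14, 20, 8, 16),
    sex_determination = c("XY", "XO", NA, NA),
    stringsAsFactors = FALSE)
  list(tree = tree, table = table)
}
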