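# Independent oracles and fixture builders used across the suite.

# Brute-force minimum-duplication reconciliation: enumerates every valid
# mapping of gene internal nodes to species nodes (each node maps to an
# ancestor-or-equal of the LCA of its children's mappings) and counts a
# duplication at a node unless its children map into two distinct child
# subtrees of the node's mapping. Exponential; only for tiny trees.
oracle_min_dups <- function(gene_tree, species_tree, leaf_map) {
  sp_n <- ape::Ntip(species_tree) + species_tree$Nnode
  parent <- integer(sp_n)
  parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  root <- ape::Ntip(species_tree) + 1L
  depth <- rep(NA_integer_, sp_n); depth[root] <- 0L
  queue <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    kids <- species_tree$edge[species_tree$edge[, 1] == v, 2]
    depth[kids] <- depth[v] + 1L
    queue <- c(queue, kids)
  }
  lca2 <- function(a, b) {
    while (a != b) {
      if (depth[a] >= depth[b]) a <- parent[a] else b <- parent[b]
    }
    a
  }
  ancestors_incl <- function(v) {
    out <- v
    while (v != root) { v <- parent[v]; out <- c(out, v) }
    out
  }
  g_ntip <- ape::Ntip(gene_tree)
  po <- ape::reorder.phylo(gene_tree, "postorder")
  internal <- unique(po$edge[, 1])          # postorder
  kids_of <- split(po$edge[, 2], po$edge[, 1])
  leafM <- match(unname(leaf_map[gene_tree$tip.label]),
                 species_tree$tip.label)
  best <- Inf
  assign_node <- function(i, M) {
    if (i > length(internal)) {
      dups <- 0L
      for (v in internal) {
        ch <- kids_of[[as.character(v)]]
        l <- lca2(M[ch[1]], M[ch[2]])
        if (M[v] %in% M[ch] || M[v] != l) dups <- dups + 1L
      }
      best <<- min(best, dups)
      return(invisible())
    }
    v <- internal[i]
    ch <- kids_of[[as.character(v)]]
    for (cand in ancestors_incl(lca2(M[ch[1]], M[ch[2]]))) {
      M[v] <- cand
      assign_node(i + 1L, M)
    }
  }
  M0 <- integer(g_ntip + gene_tree$Nnode)
  M0[seq_len(g_ntip)] <- leafM
  assign_node(1L, M0)
  best
}

# naive all-offsets profile scorer (loops, no windowing tricks)
oracle_profile_scores <- function(sequence, profile) {
  s <- strsplit(sequence, "")[[1]]
  L <- profile$length
  n <- length(s) - L + 1L
  if (n < 1) return(numeric(0))
  out <- numeric(n)
  for (i in seq_len(n)) {
    tot <- 0
    for (j in seq_len(L))
      tot <- tot + profile$log_odds[j, s[i + j - 1L]]
    out[i] <- tot
  }
  out
}

# random (gene tree, species tree, leaf map) instance for reconciliation
random_recon_case <- function(seed, max_gene_leaves = 6) {
  set.seed(seed)
  n_sp <- sample(3:5, 1)
  st <- ape::rtree(n_sp, tip.label = LETTERS[seq_len(n_sp)])
  n_g <- sample(3:max_gene_leaves, 1)
  gt <- ape::rtree(n_g, tip.label = paste0("g", seq_len(n_g)))
  lm <- setNames(sample(st$tip.label, n_g, replace = TRUE), gt$tip.label)
  list(gene_tree = gt, species_tree = st, leaf_map = lm)
}

random_aa_seq <- function(n) paste(sample(clcfamily:::AA_ALPHABET, n, replace = TRUE),
                                   collapse = "")

# full-null permutation reference for pairwise mean-difference significance
# at family-wise alpha, using the max studentized-range statistic
perm_pairwise_sig <- function(groups, alpha = 0.05, B = 400) {
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  x <- unlist(groups)
  lab <- rep(seq_len(k), n)
  qstat <- function(vals, lab) {
    m <- tapply(vals, lab, mean)
    nn <- tabulate(lab, k)
    df2 <- length(vals) - k
    mse <- sum((vals - m[lab])^2) / df2
    qm <- matrix(0, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      qm[i, j] <- qm[j, i] <-
        abs(m[i] - m[j]) / sqrt(mse / 2 * (1 / nn[i] + 1 / nn[j]))
    qm
  }
  obs <- qstat(x, lab)
  null_max <- vapply(seq_len(B), function(b)
    max(qstat(x, sample(lab))), numeric(1))
  crit <- stats::quantile(null_max, 1 - alpha, names = FALSE)
  obs > crit & row(obs) != col(obs)
}
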