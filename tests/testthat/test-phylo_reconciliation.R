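test_that("parse_newick/write_newick round-trip topology, labels and lengths", {
  tr <- parse_newick("((A,B),C);")
  expect_equal(ape::Ntip(tr), 3L)
  expect_true(ape::is.rooted(tr))

  set.seed(2)
  for (i in 1:50) {
    t0 <- ape::rtree(sample(4:12, 1))
    back <- parse_newick(write_newick(t0))
    expect_equal(sort(back$tip.label), sort(t0$tip.label))
    expect_equal(phangorn::RF.dist(back, t0), 0)
    expect_equal(ape::cophenetic.phylo(back)[t0$tip.label, t0$tip.label],
                 ape::cophenetic.phylo(t0), tolerance = 1e-8)
  }

  expect_error(parse_newick("((A,B,C);"), ".")
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate")
  expect_warning(tr3 <- parse_newick("(A,B,C,D);"), "resolved")
  expect_true(ape::is.binary(tr3))
})

test_that("conserved_block_filter keeps/drops columns by the stated rules", {
  ident <- alignment(paste0("s", 1:5), rep(strrep("MKTVAAGH", 2), 5))
  out <- conserved_block_filter(ident, 0.5, 0.2, 5)
  expect_equal(out$n_columns, 16L)
  expect_equal(attr(out, "kept_columns"), 1:16)

  gapcol <- alignment(c("a", "b", "c"),
                      c("AAAAA-AAAAA", "AAAAA-AAAAA", "AAAAA-AAAAA"))
  out2 <- conserved_block_filter(gapcol, 0.5, 0.5, 5)
  expect_false(6L %in% attr(out2, "kept_columns"))

  # a 4-column conserved run is dropped at min_block_length 5
  short <- alignment(c("a", "b"), c("AAAAGGGG", "AAAACCCC"))
  out3 <- conserved_block_filter(short, 0.9, 0, 5)
  expect_equal(out3$n_columns, 0L)
  out4 <- conserved_block_filter(short, 0.9, 0, 4)
  expect_equal(attr(out4, "kept_columns"), 1:4)
})

test_that("block filter output is a subset of input columns in order", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(3:8, 1); w <- sample(10:60, 1)
    rows <- vapply(seq_len(n), function(j) {
      s <- sample(c(clcfamily:::AA_ALPHABET, "-"), w, replace = TRUE,
                  prob = c(rep(0.9 / 20, 20), 0.1))
      paste(s, collapse = "")
    }, character(1))
    aln <- alignment(paste0("t", seq_len(n)), rows)
    out <- conserved_block_filter(aln, 0.4, 0.3, 3)
    kc <- attr(out, "kept_columns")
    expect_true(all(diff(kc) > 0))
    expect_true(all(kc %in% seq_len(w)))
  }
})

test_that("distance_matrix computes p and Poisson distances", {
  aln <- alignment(c("a", "b"),
                   c("AAAAAAAAAA", "CCAAAAAAAA"))
  expect_equal(distance_matrix(aln, "p")["a", "b"], 0.2)
  expect_equal(distance_matrix(aln, "poisson")["a", "b"], -log(0.8),
               tolerance = 1e-10)
  same <- alignment(c("a", "b"), c("MKTV", "MKTV"))
  expect_equal(distance_matrix(same)["a", "b"], 0)
  nosites <- alignment(c("a", "b"), c("AA--", "--AA"))
  expect_error(distance_matrix(nosites), "shared")
  allmis <- alignment(c("a", "b"), c("AAAA", "CCCC"))
  expect_error(distance_matrix(allmis, "poisson"), "Poisson")
})

test_that("nj_tree recovers additive topologies and ignores taxon order", {
  # hand-built additive matrix from ((A:1,B:2):1,(C:3,D:4):1)
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  truth <- parse_newick("((A,B),(C,D));")
  nj <- nj_tree(d)
  expect_equal(phangorn::RF.dist(ape::unroot(nj), ape::unroot(truth)), 0)

  perm <- sample(4)
  nj2 <- nj_tree(d[perm, perm])
  expect_equal(phangorn::RF.dist(ape::unroot(nj2), ape::unroot(truth)), 0)

  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")
  expect_equal(ape::Ntip(nj_tree(d[1:3, 1:3])), 3L)
})

test_that("lca_reconcile matches hand-derived duplication/loss counts", {
  st <- parse_newick("(A,B);")
  r1 <- lca_reconcile(parse_newick("((a1,b1),(a2,b2));"), st,
                      c(a1 = "A", b1 = "B", a2 = "A", b2 = "B"))
  expect_equal(r1$total_duplications, 1L)
  expect_equal(r1$total_losses, 0L)

  r2 <- lca_reconcile(parse_newick("(a1,(a2,b2));"), st,
                      c(a1 = "A", a2 = "A", b2 = "B"))
  expect_equal(r2$total_duplications, 1L)
  expect_equal(r2$total_losses, 1L)
  expect_equal(r2$loss_branches, "B")

  st3 <- parse_newick("((A,B),C);")
  r3 <- lca_reconcile(parse_newick("((a,b),c);"), st3,
                      c(a = "A", b = "B", c = "C"))
  expect_equal(r3$total_duplications, 0L)
  expect_equal(r3$total_losses, 0L)
  expect_true(all(r3$events$event == "speciation"))

  expect_error(lca_reconcile(parse_newick("(a,x);"), st, c(a = "A")),
               "unmapped")
})

test_that("duplication events satisfy the child-mapping invariant", {
  set.seed(9)
  for (s in 1:25) {
    cs <- random_recon_case(s)
    rec <- lca_reconcile(cs$gene_tree, cs$species_tree, cs$leaf_map)
    kids_of <- split(cs$gene_tree$edge[, 2], cs$gene_tree$edge[, 1])
    for (i in seq_len(nrow(rec$events))) {
      v <- rec$events$gene_node[i]
      same <- any(rec$mapping[kids_of[[as.character(v)]]] == rec$mapping[v])
      expect_equal(rec$events$event[i] == "duplication", same)
    }
  }
})

test_that("clade_absence_report lists missing taxon groups", {
  st <- default_species_tree()
  gt <- parse_newick("((Punica_granatum_g1,Vitis_vinifera_g1),Oryza_sativa_g1);")
  lm <- setNames(sub("_g\\d+$", "", gt$tip.label), gt$tip.label)
  rep1 <- clade_absence_report(gt, st, lm,
                               list(cladeA = gt$tip.label),
                               default_taxon_groups())
  expect_true(all(c("gymnosperms", "bryophytes") %in% rep1$absent_group))
  expect_false("monocots" %in% rep1$absent_group)

  rep2 <- clade_absence_report(gt, st, lm, list(cladeA = character(0)),
                               default_taxon_groups())
  expect_equal(nrow(rep2), 0L)
})

test_that("assign_ortholog_names follows smallest-clade majority with suffixes", {
  gt <- parse_newick("(((q1,q2),AtC),(q3,AtG));")
  lm <- c(q1 = "Pg", q2 = "Pg", q3 = "Pg", AtC = "At", AtG = "At")
  nm <- assign_ortholog_names(gt, c(AtC = "CLC-C", AtG = "CLC-G"),
                              c("q1", "q2", "q3"), leaf_map = lm)
  expect_equal(unname(nm[c("q1", "q2", "q3")]),
               c("CLC-C1", "CLC-C2", "CLC-G"))

  # equal-name clade -> ambiguous
  gt2 <- parse_newick("((q1,(AtC,AtG)),out);")
  nm2 <- assign_ortholog_names(gt2, c(AtC = "CLC-C", AtG = "CLC-G"), "q1")
  expect_equal(unname(nm2), "ambiguous")
})
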