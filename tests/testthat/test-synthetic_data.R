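test_that("simulate_proteome is deterministic per seed and validates spec", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(simulate_proteome(proteome_spec(seed = 4))$proteins, f1)
  write_fasta(simulate_proteome(proteome_spec(seed = 4))$proteins, f2)
  expect_identical(readLines(f1), readLines(f2))
  write_fasta(simulate_proteome(proteome_spec(seed = 5))$proteins, f2)
  expect_false(identical(readLines(f1), readLines(f2)))

  expect_error(proteome_spec(n_true = -1), ">= 0")
  expect_error(proteome_spec(n_true = 0,
                             labels = data.frame(selectivity_residue = "P",
                                                 gating = TRUE, proton = TRUE)),
               "zero true genes")
  expect_error(proteome_spec(n_true = 3,
                             labels = data.frame(selectivity_residue = "P",
                                                 gating = TRUE, proton = TRUE)),
               "one row per true gene")
})

test_that("empty and decoy-only proteomes yield no candidates", {
  sim <- simulate_proteome(proteome_spec(n_true = 0, n_decoy = 10, seed = 2))
  cand <- identify_candidates(sim$proteins)
  expect_equal(sum(cand$passed), 0L)
  expect_true(all(sim$manifest$kind == "decoy"))
})

test_that("manifest carries one labelled entry per generated protein", {
  sim <- simulate_proteome(proteome_spec(n_true = 4, n_decoy = 6, seed = 9))
  expect_equal(nrow(sim$manifest), 10L)
  expect_setequal(sim$manifest$id, sim$proteins$id)
  truth <- sim$manifest[sim$manifest$kind == "true", ]
  expect_true(all(truth$transport_class %in% c("antiporter", "channel")))
})

test_that("duploss simulator: rate-zero history is congruent to species tree", {
  st <- default_species_tree()
  sim <- simulate_duploss_gene_tree(duploss_spec(st, 0, 0, seed = 1))
  expect_equal(ape::Ntip(sim$gene_tree), ape::Ntip(st))
  relab <- sim$gene_tree
  relab$tip.label <- unname(sim$leaf_map[relab$tip.label])
  expect_equal(phangorn::RF.dist(relab, st), 0)
  expect_equal(sim$manifest$all_duplications, 0L)
  expect_equal(sim$manifest$all_losses, 0L)
  rec <- lca_reconcile(sim$gene_tree, st, sim$leaf_map)
  expect_equal(rec$total_duplications, 0L)
  expect_equal(rec$total_losses, 0L)
})

test_that("a forced root duplication yields the doubled congruent topology", {
  st <- parse_newick("(A:1,B:1);")
  sim <- simulate_duploss_gene_tree(
    duploss_spec(st, 0, 0, n_root_duplications = 1, seed = 3))
  expect_equal(sort(sim$gene_tree$tip.label),
               c("A_g1", "A_g2", "B_g1", "B_g2"))
  expect_equal(sim$manifest$observable_duplications, 1L)
  expect_equal(sim$manifest$observable_losses, 0L)
  rec <- lca_reconcile(sim$gene_tree, st, sim$leaf_map)
  expect_equal(rec$total_duplications, 1L)
  expect_equal(rec$total_losses, 0L)

  st_nolen <- ape::read.tree(text = "(A,B);")
  expect_error(duploss_spec(st_nolen), "branch lengths")
})

test_that("expected gene count under pure duplication matches the branching
           process", {
  st <- parse_newick("(A:1,B:1);")
  d <- 0.4
  counts <- vapply(1:1000, function(s)
    simulate_duploss_gene_tree(duploss_spec(st, d, 0, seed = s))$manifest$n_extant,
    integer(1))
  # Yule growth per branch: E[N] = 2 * exp(d * 1)
  expected <- 2 * exp(d)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se + 1e-9)
})

test_that("duploss simulation is deterministic per seed", {
  a <- simulate_duploss_gene_tree(duploss_spec(seed = 11))
  b <- simulate_duploss_gene_tree(duploss_spec(seed = 11))
  expect_equal(write_newick(a$gene_tree), write_newick(b$gene_tree))
  expect_identical(a$manifest, b$manifest)
})

test_that("simulate_ct_table plants exact folds at zero noise", {
  sim <- simulate_ct_table(expression_spec(genes = "g1", tissues = "leaf",
                                           log2fold = 4, sigma_ct = 0,
                                           seed = 1))
  fc <- ddct_fold_change(sim$ct, "g1", "leaf", 100)
  expect_equal(fc$fold, 16)
  expect_equal(sim$manifest$true_fold[sim$manifest$treatment_mM == 100], 16)

  a <- simulate_ct_table(expression_spec(seed = 8))
  b <- simulate_ct_table(expression_spec(seed = 8))
  expect_identical(a$ct, b$ct)
  expect_error(expression_spec(n_biorep = 0), ">= 1")
  expect_error(expression_spec(sigma_ct = -1), ">= 0")
})

test_that("measurement simulator reproduces the planted trend shapes", {
  sim <- simulate_measurement_table(
    variables = list(NO3 = "hump", Cl = "increasing"),
    tissues = "root", cv = 0.02, seed = 6)
  m <- sim$measurements
  means <- function(v) vapply(c(0, 100, 300), function(tr)
    mean(m$value[m$variable == v & m$treatment_mM == tr]), numeric(1))
  hump <- means("NO3")
  expect_true(hump[1] < hump[2] && hump[2] > hump[3])
  inc <- means("Cl")
  expect_true(all(diff(inc) > 0))

  a <- simulate_measurement_table(seed = 10)
  b <- simulate_measurement_table(seed = 10)
  expect_identical(a$measurements, b$measurements)
  expect_error(simulate_measurement_table(n_rep = 0), ">= 1")
})
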