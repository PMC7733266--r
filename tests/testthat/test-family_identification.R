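test_that("read_fasta joins wrapped lines, case-folds, and validates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "mk", "tv", ">b desc species=Punica_granatum", "MKT"), f)
  ps <- read_fasta(f)
  expect_equal(ps$id, c("a", "b"))
  expect_equal(ps$sequence[1], "MKTV")
  expect_equal(ps$species[2], "Punica_granatum")

  writeLines(c(">a", "MKT", ">a", "MKV"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">a", "MK9T"), f)
  expect_error(read_fasta(f), "non-amino-acid|invalid|parse")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("write_fasta/read_fasta round-trips a protein set", {
  ps <- protein_set(c("p1", "p2"), c(random_aa_seq(150), random_aa_seq(40)),
                    species = "x")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ps, f, width = 60)
  back <- read_fasta(f)
  expect_equal(back$id, ps$id)
  expect_equal(back$sequence, ps$sequence)
})

test_that("parse_domtblout reads envelope coordinates and i-Evalue", {
  row <- paste("P1 - 500 Voltage_CLC PF00654.1 60 1.2e-32 108.0 0.1",
               "1 1 2e-31 1e-30 95.5 0.1 1 60 38 99 40 420 0.98 desc")
  f <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c("# comment", row), f)
  hits <- parse_domtblout(f)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$protein_id, "P1")
  expect_equal(hits$domain, "Voltage_CLC")
  expect_equal(hits$start, 40L)
  expect_equal(hits$end, 420L)
  expect_equal(hits$evalue, 1e-30)

  writeLines("# only comments", f)
  expect_equal(nrow(parse_domtblout(f)), 0L)

  writeLines("P1 - 500 Voltage_CLC PF00654.1 60 1.2e-32", f)
  expect_error(parse_domtblout(f), "columns")

  bad <- sub("40 420", "420 40", row)
  writeLines(bad, f)
  expect_error(parse_domtblout(f), "end < start")
})

test_that("scan_profile finds planted consensus exactly and scores match a
           brute-force scorer", {
  prof <- default_domain_profiles()$Voltage_CLC
  set.seed(11)
  L <- prof$length
  seqs <- paste0(random_aa_seq(100), prof$consensus, random_aa_seq(120))
  hit <- scan_profile(seqs, prof)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 101L)
  expect_equal(hit$end, 100L + L)
  expect_lt(hit$evalue, 1e-10)

  # reported score equals the sum of per-position log-odds at the offset
  for (s in 1:5) {
    set.seed(s)
    x <- paste0(random_aa_seq(60), prof$consensus, random_aa_seq(40))
    sc <- oracle_profile_scores(x, prof)
    h <- scan_profile(x, prof)
    expect_equal(h$bit_score, sc[h$start], tolerance = 1e-10)
  }
})

test_that("residue-shuffled planted proteins never reach the E-value cutoff", {
  prof <- default_domain_profiles()$Voltage_CLC
  set.seed(21)
  base <- strsplit(paste0(random_aa_seq(100), prof$consensus,
                          random_aa_seq(120)), "")[[1]]
  n_below_cutoff <- 0L
  for (i in 1:100) {
    shuf <- paste(sample(base), collapse = "")
    h <- scan_profile(shuf, prof)
    n_below_cutoff <- n_below_cutoff + sum(h$evalue <= 1e-10)
  }
  expect_equal(n_below_cutoff, 0L)
})

test_that("scan_profile reports two non-overlapping CBS copies and handles
           short proteins", {
  prof <- default_domain_profiles()$CBS
  set.seed(31)
  x <- paste0(random_aa_seq(20), prof$consensus, random_aa_seq(50),
              prof$consensus, random_aa_seq(20))
  h <- scan_profile(x, prof)
  expect_equal(nrow(h), 2L)
  expect_true(h$end[1] < h$start[2])
  expect_equal(nrow(scan_profile("MKTV", prof)), 0L)
})

test_that("collapse_isoforms keeps longest per locus with lexicographic ties", {
  ps <- protein_set(c("x.2", "x.1", "y.1"),
                    c(strrep("A", 700), strrep("A", 650), strrep("A", 100)))
  out <- collapse_isoforms(ps, c(x.2 = "x", x.1 = "x", y.1 = "y"))
  expect_equal(out$id, c("x.2", "y.1"))

  out2 <- collapse_isoforms(ps, c(x.2 = "a", x.1 = "b", y.1 = "c"))
  expect_equal(nrow(out2), 3L)

  tie <- protein_set(c("b", "a"), c(strrep("A", 10), strrep("C", 10)))
  out3 <- collapse_isoforms(tie, c(b = "l", a = "l"))
  expect_equal(out3$id, "a")

  expect_error(collapse_isoforms(ps, c(x.2 = "x")), "missing")
})

test_that("filter_candidates applies the Voltage_CLC E-value rule only", {
  ps <- protein_set(c("p1", "p2", "p3"), rep(strrep("A", 50), 3))
  hits <- domain_hits(c("p1", "p2", "p3", "p3"),
                      c("Voltage_CLC", "Voltage_CLC", "CBS", "CBS"),
                      c(1, 1, 1, 30), c(20, 20, 10, 40),
                      c(50, 40, 20, 20), c(1e-11, 1e-9, 1e-40, 1e-40))
  out <- filter_candidates(ps, hits)
  expect_equal(out$passed, c(TRUE, FALSE, FALSE))
  expect_equal(out$n_cbs, c(0L, 0L, 2L))
  expect_equal(out$id, sort(out$id))
})

test_that("identification is invariant to input record order", {
  sim <- simulate_proteome(proteome_spec(n_true = 3, n_decoy = 6, seed = 5))
  cand1 <- identify_candidates(sim$proteins)
  perm <- sim$proteins[rev(seq_len(nrow(sim$proteins))), ]
  class(perm) <- c("protein_set", "data.frame")
  cand2 <- identify_candidates(perm)
  expect_equal(cand1$id, cand2$id)
  expect_equal(cand1$passed, cand2$passed)
  expect_equal(cand1$best_evalue, cand2$best_evalue)
})
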