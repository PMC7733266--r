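make_ct <- function(gene_ct, ref_ct, treatments) {
  # one gene + reference, one tissue, 1 tech rep; gene_ct/ref_ct are
  # lists: treatment -> per-biorep Ct vectors
  rows <- list()
  for (tr in treatments) {
    for (b in seq_along(gene_ct[[as.character(tr)]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = "g", tissue = "leaf", treatment_mM = tr, biorep = b,
        techrep = 1, ct = gene_ct[[as.character(tr)]][b])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = "ref", tissue = "leaf", treatment_mM = tr, biorep = b,
        techrep = 1, ct = ref_ct[[as.character(tr)]][b])
    }
  }
  do.call(rbind, rows)
}

test_that("ddct_fold_change implements 2^-ddCt with cancellation", {
  ct <- make_ct(list(`0` = c(25, 25), `100` = c(22, 22)),
                list(`0` = c(20, 20), `100` = c(20, 20)), c(0, 100))
  fc <- ddct_fold_change(ct, "g", "leaf", 100, reference_gene = "ref")
  expect_equal(fc$ddct, -3)
  expect_equal(fc$fold, 8)

  # ddCt = 0 -> fold 1
  fc0 <- ddct_fold_change(ct, "g", "leaf", 0, reference_gene = "ref")
  expect_equal(fc0$fold, 1)

  # adding a constant to every Ct of both genes leaves fold unchanged
  ct2 <- ct; ct2$ct <- ct2$ct + 1.7
  fc2 <- ddct_fold_change(ct2, "g", "leaf", 100, reference_gene = "ref")
  expect_equal(fc2$fold, fc$fold)

  expect_error(ddct_fold_change(ct, "g", "leaf", 300, reference_gene = "ref"),
               "no Ct rows|no reference")
  expect_error(ddct_fold_change(ct, "nope", "leaf", 100, reference_gene = "ref"),
               "no Ct rows")
})

test_that("technical replicates average before biological statistics", {
  ct <- rbind(
    data.frame(gene = "g", tissue = "leaf", treatment_mM = 0, biorep = 1,
               techrep = 1:3, ct = c(24, 25, 26)),
    data.frame(gene = "g", tissue = "leaf", treatment_mM = 100, biorep = 1,
               techrep = 1:3, ct = c(21, 22, 23)),
    data.frame(gene = "ref", tissue = "leaf", treatment_mM = 0, biorep = 1,
               techrep = 1, ct = 20),
    data.frame(gene = "ref", tissue = "leaf", treatment_mM = 100, biorep = 1,
               techrep = 1, ct = 20))
  fc <- ddct_fold_change(ct, "g", "leaf", 100, reference_gene = "ref")
  expect_equal(fc$ddct, -3)  # tech means 25 vs 22
})

test_that("one_way_anova matches the hand decomposition and identities", {
  av <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(av$F, 3)
  expect_equal(av$df, c(2, 6))
  expect_equal(av$p, stats::pf(3, 2, 6, lower.tail = FALSE))

  same <- one_way_anova(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(same$F, 0)

  # two groups: F equals the squared pooled-variance t statistic
  g1 <- c(1.2, 3.1, 2.5, 0.7); g2 <- c(4.4, 5.0, 3.9)
  av2 <- one_way_anova(list(g1, g2))
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(av2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(av2$p, tt$p.value, tolerance = 1e-10)

  degenerate <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_true(degenerate$below_eps)
  expect_equal(degenerate$p, 0)

  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
  expect_error(one_way_anova(list(c(1, 2), 3)), ">= 2 values")
})

test_that("tukey_hsd flags separation and not noise", {
  tk0 <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_false(tk0$significant["a", "b"])
  tk1 <- tukey_hsd(list(a = c(0, 0.1, -0.1), b = c(100, 100.1, 99.9)))
  expect_true(tk1$significant["a", "b"])
  expect_true(isSymmetric(tk1$p))
})

test_that("tukey_hsd agrees with a permutation reference away from alpha", {
  set.seed(55)
  checked <- 0L
  for (case in 1:20) {
    k <- sample(3:4, 1)
    shift <- sample(c(0, 0, 3), k, replace = TRUE)
    groups <- lapply(shift, function(m) stats::rnorm(5, m))
    names(groups) <- paste0("g", seq_len(k))
    tk <- tukey_hsd(groups)
    pm <- perm_pairwise_sig(groups, B = 400)
    clear <- abs(tk$p - 0.05) > 0.04 & row(tk$p) != col(tk$p)
    expect_true(all(tk$significant[clear] == pm[clear]),
                info = paste("case", case))
    checked <- checked + sum(clear) / 2
  }
  expect_gt(checked, 20)  # the comparison actually exercised many pairs
})

test_that("compact_letter_display produces consistent letters", {
  no_sig <- matrix(FALSE, 3, 3)
  expect_equal(unname(compact_letter_display(no_sig)), c("a", "a", "a"))

  all_sig <- matrix(TRUE, 3, 3); diag(all_sig) <- FALSE
  expect_equal(unname(compact_letter_display(all_sig)), c("a", "b", "c"))

  chain <- matrix(FALSE, 3, 3); chain[1, 3] <- chain[3, 1] <- TRUE
  expect_equal(unname(compact_letter_display(chain)), c("a", "ab", "b"))
})

test_that("letters share iff not significant, exhaustively to 5 groups", {
  share <- function(a, b) any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
  for (k in 2:5) {
    pairs <- which(upper.tri(matrix(0, k, k)))
    for (code in 0:(2^length(pairs) - 1)) {
      sig <- matrix(FALSE, k, k)
      bits <- bitwAnd(bitwShiftR(code, seq_along(pairs) - 1L), 1L) == 1L
      sig[upper.tri(sig)] <- bits
      sig <- sig | t(sig)
      cld <- compact_letter_display(sig)
      for (i in seq_len(k - 1)) for (j in (i + 1):k)
        expect_equal(share(cld[i], cld[j]), !sig[i, j],
                     info = paste("k", k, "code", code, "pair", i, j))
    }
  }
})

test_that("fold_vs_control ratios and conventions", {
  meas <- data.frame(tissue = "root", treatment_mM = rep(c(0, 300), each = 3),
                     rep = rep(1:3, 2), variable = "Cl",
                     value = c(2, 2, 2, 10, 10, 10))
  expect_equal(fold_vs_control(meas, "Cl", "root", 300), 5)
  expect_equal(fold_vs_control(meas, "Cl", "root", 0), 1)
  expect_equal(fold_vs_control(meas, "Cl", "root", 300,
                               times_means_increment = TRUE), 4)
  zero <- meas; zero$value[zero$treatment_mM == 0] <- 0
  expect_error(fold_vs_control(zero, "Cl", "root", 300), "zero")
})

test_that("correlation_matrix computes Pearson r, p and stars", {
  cm <- correlation_matrix(cbind(x = c(1, 2, 3), y = c(1, 2, 4)))
  expect_equal(cm$r["x", "y"], 0.9819805, tolerance = 1e-6)
  expect_equal(cm$r["x", "x"], 1)
  neg <- correlation_matrix(cbind(x = c(1, 2, 3, 5), y = -c(1, 2, 3, 5)))
  expect_equal(neg$r["x", "y"], -1)
  expect_equal(neg$stars["x", "y"], "**")
  expect_error(correlation_matrix(cbind(x = 1:2, y = 1:2)), "3")
})

test_that("correlation is invariant to sample order and affine rescaling", {
  set.seed(77)
  x <- matrix(stats::rnorm(60), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  cm <- correlation_matrix(x)
  perm <- x[sample(nrow(x)), ]
  expect_equal(correlation_matrix(perm)$r, cm$r, tolerance = 1e-12)
  resc <- x; resc[, 2] <- 3.2 * resc[, 2] + 10
  expect_equal(correlation_matrix(resc)$r, cm$r, tolerance = 1e-12)
})

test_that("group_stats ties means, letters and ANOVA together", {
  groups <- list(`0` = c(1, 1.1, 0.9), `100` = c(5, 5.1, 4.9),
                 `300` = c(5.05, 5.15, 4.95))
  gs <- group_stats(groups)
  expect_lt(gs$anova$p, 0.001)
  expect_equal(unname(gs$letters[1]), "a")
  expect_equal(gs$letters[["100"]], gs$letters[["300"]])
  expect_false(grepl(gs$letters[["0"]], gs$letters[["100"]]))
})
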