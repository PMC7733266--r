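# Expression and anion statistics: 2^-ddCt fold changes, one-way ANOVA,
# Tukey HSD with compact letter displays, fold-vs-control ratios, and the
# Pearson correlation matrix.

#' Read a Ct table
#'
#' Delimited text with header
#' `gene,tissue,treatment_mM,biorep,techrep,ct` (separator auto-detected
#' among tab/comma).
#'
#' @param path input path.
#' @return data.frame with those columns.
#' @export
read_ct_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  ct <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("gene", "tissue", "treatment_mM", "biorep", "techrep", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be finite and positive")
  ct
}

#' Read a measurement (anion / dry-weight) table
#'
#' Columns `tissue,treatment_mM,rep,variable,value`.
#' @param path input path.
#' @return data.frame.
#' @export
read_measurement_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  m <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("tissue", "treatment_mM", "rep", "variable", "value")
  if (!all(need %in% names(m)))
    stop("measurement table must have columns: ", paste(need, collapse = ", "))
  m
}

# mean Ct per biological replicate (technical replicates averaged), then
# per-biorep delta-Ct relative to the reference gene
biorep_dct <- function(ct, gene, tissue, treatment, reference_gene) {
  sub <- ct[ct$tissue == tissue & ct$treatment_mM == treatment, , drop = FALSE]
  g <- sub[sub$gene == gene, , drop = FALSE]
  r <- sub[sub$gene == reference_gene, , drop = FALSE]
  if (!nrow(g))
    stop("no Ct rows for gene ", gene, " in (", tissue, ", ", treatment, " mM)")
  if (!nrow(r))
    stop("no reference-gene rows in (", tissue, ", ", treatment, " mM)")
  gm <- tapply(g$ct, g$biorep, mean)
  rm_ <- tapply(r$ct, r$biorep, mean)
  common <- intersect(names(gm), names(rm_))
  if (!length(common))
    stop("no shared biological replicates for gene ", gene,
         " in (", tissue, ", ", treatment, " mM)")
  gm[common] - rm_[common]
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged within each biological replicate;
#' dCt = Ct(gene) - Ct(reference) per biological replicate; ddCt is the
#' mean treated dCt minus the mean calibrator dCt, and the fold change is
#' `2^-ddCt`. Per-replicate folds (each treated replicate against the mean
#' calibrator dCt) are retained for a standard error.
#'
#' @param ct a Ct table (see [read_ct_table()]).
#' @param gene target gene.
#' @param tissue tissue.
#' @param treatment treatment level (mM NaCl).
#' @param reference_gene internal reference gene (constant in expectation).
#' @param calibrator calibrator treatment level (default 0).
#' @return list with `fold`, `ddct`, `replicate_folds`, `se`.
#' @export
ddct_fold_change <- function(ct, gene, tissue, treatment,
                             reference_gene = "PgActin", calibrator = 0) {
  dct_t <- biorep_dct(ct, gene, tissue, treatment, reference_gene)
  dct_c <- biorep_dct(ct, gene, tissue, calibrator, reference_gene)
  ddct <- mean(dct_t) - mean(dct_c)
  rep_folds <- 2^-(dct_t - mean(dct_c))
  list(fold = 2^-ddct, ddct = unname(ddct),
       replicate_folds = unname(rep_folds),
       se = if (length(rep_folds) > 1) stats::sd(rep_folds) / sqrt(length(rep_folds)) else NA_real_)
}

#' Classical one-way ANOVA
#'
#' Between/within sum-of-squares decomposition; p-value from the F
#' distribution. With zero within-group variance and unequal means the
#' statistic is infinite and p is reported as 0 with `below_eps = TRUE`.
#'
#' @param groups list of numeric replicate vectors (>= 2 groups, each >= 2
#'   values).
#' @return list with `F`, `p`, `df` (c(between, within)), `below_eps`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs >= 2 values")
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, p = 1, df = c(df1, df2), below_eps = FALSE))
    return(list(F = Inf, p = 0, df = c(df1, df2), below_eps = TRUE))
  }
  Fstat <- (ssb / df1) / (ssw / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), below_eps = FALSE)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range tests at family-wise level `alpha` using the pooled
#' within-group variance (Tukey-Kramer for unbalanced groups).
#'
#' @param groups named (or unnamed) list of numeric vectors.
#' @param alpha family-wise significance level.
#' @return list with symmetric matrices `p` and `significant`, plus
#'   `means`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2L) stop("need >= 2 groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  n <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  df2 <- sum(n) - k
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df2
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (mse == 0) {
      p[i, j] <- p[j, i] <- if (means[i] == means[j]) 1 else 0
      next
    }
    q <- abs(means[i] - means[j]) / sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
    p[i, j] <- p[j, i] <- stats::ptukey(q, k, df2, lower.tail = FALSE)
  }
  list(p = p, significant = p < alpha & row(p) != col(p), means = means)
}

#' Compact letter display by insert-and-absorb
#'
#' Starts from a single letter covering all groups; for every significant
#' pair each letter containing both members is split; letters that are
#' subsets of others are absorbed. Letters are assigned in group order.
#' Groups share a letter iff they are not significantly different.
#'
#' @param sig symmetric logical matrix of pairwise significance.
#' @param group_order optional character vector ordering the output.
#' @return Named character vector of letter strings per group.
#' @export
compact_letter_display <- function(sig, group_order = NULL) {
  nm <- rownames(sig)
  if (is.null(nm)) nm <- paste0("g", seq_len(nrow(sig)))
  if (is.null(group_order)) group_order <- nm
  k <- nrow(sig)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    for (s in seq_along(sets)) {
      if (all(c(i, j) %in% sets[[s]])) {
        a <- setdiff(sets[[s]], i); b <- setdiff(sets[[s]], j)
        sets[[s]] <- a
        sets <- c(sets, list(b))
      }
    }
    # absorb subsets
    keep <- rep(TRUE, length(sets))
    for (s in seq_along(sets)) for (t in seq_along(sets)) {
      if (s != t && keep[t] && keep[s] &&
          all(sets[[s]] %in% sets[[t]]) && length(sets[[s]]) < length(sets[[t]]))
        keep[s] <- FALSE
      if (s != t && keep[t] && keep[s] && identical(sort(sets[[s]]), sort(sets[[t]])) && s > t)
        keep[s] <- FALSE
    }
    sets <- sets[keep]
  }
  # order letters by first (smallest-index) member for stable output
  ord <- order(vapply(sets, min, integer(1)))
  sets <- sets[ord]
  letters_out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  setNames(letters_out, nm)[group_order]
}

#' Group summary: ANOVA, Tukey HSD and letters for one panel
#'
#' @param groups named list of replicate vectors (one entry per treatment
#'   level, in display order).
#' @param alpha significance level.
#' @return list with `means`, `se`, `anova`, `tukey`, `letters`.
#' @export
group_stats <- function(groups, alpha = 0.05) {
  av <- one_way_anova(groups)
  tk <- tukey_hsd(groups, alpha)
  list(means = vapply(groups, mean, numeric(1)),
       se = vapply(groups, function(g) stats::sd(g) / sqrt(length(g)), numeric(1)),
       anova = av, tukey = tk,
       letters = compact_letter_display(tk$significant))
}

#' Fold change of a measured variable versus control
#'
#' `mean(treatment) / mean(control)`. The phrase "increased N times" is
#' read as ratio = N; set `times_means_increment = TRUE` for the reading
#' ratio = N + 1.
#'
#' @param meas measurement table (see [read_measurement_table()]).
#' @param variable variable name.
#' @param tissue tissue.
#' @param treatment treatment level.
#' @param control control level (default 0).
#' @param times_means_increment convention flag, see above.
#' @return Numeric ratio (or ratio - 1 under the increment convention).
#' @export
fold_vs_control <- function(meas, variable, tissue, treatment, control = 0,
                            times_means_increment = FALSE) {
  pick <- function(tr) meas$value[meas$variable == variable &
                                  meas$tissue == tissue &
                                  meas$treatment_mM == tr]
  mt <- mean(pick(treatment)); mc <- mean(pick(control))
  if (!is.finite(mc) || mc == 0) stop("zero or missing control mean")
  r <- mt / mc
  if (times_means_increment) r - 1 else r
}

#' Pearson correlation matrix with significance stars
#'
#' @param samples data.frame or matrix, one column per variable, rows are
#'   aligned samples (>= 3).
#' @return list with matrices `r`, `p`, `stars` (`**` p<0.01, `*` p<0.05).
#' @export
correlation_matrix <- function(samples) {
  x <- as.matrix(samples)
  if (nrow(x) < 3L) stop("need >= 3 paired samples")
  k <- ncol(x)
  nm <- colnames(x)
  r <- matrix(1, k, k, dimnames = list(nm, nm))
  p <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ct <- stats::cor.test(x[, i], x[, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  stars <- matrix("", k, k, dimnames = list(nm, nm))
  stars[p < 0.05] <- "*"
  stars[p < 0.01] <- "**"
  diag(stars) <- ""
  list(r = r, p = p, stars = stars)
}

#' Write a correlation matrix in square and long forms
#' @param cm output of [correlation_matrix()].
#' @param path_square,path_long output paths (either may be `NULL`).
#' @return invisible `NULL`.
#' @export
write_correlation <- function(cm, path_square = NULL, path_long = NULL) {
  if (!is.null(path_square))
    write.table(round(cm$r, 4), path_square, sep = "\t", quote = FALSE,
                col.names = NA)
  if (!is.null(path_long)) {
    nm <- rownames(cm$r)
    idx <- which(upper.tri(cm$r), arr.ind = TRUE)
    long <- data.frame(var1 = nm[idx[, 1]], var2 = nm[idx[, 2]],
                       r = cm$r[idx], p = cm$p[idx], stars = cm$stars[idx])
    write.table(long, path_long, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
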