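# Physicochemical profiling: molecular weight (average masses), isoelectric
# point (Bjellqvist pKa set, bisection), GRAVY (Kyte-Doolittle), and a
# hydropathy sliding-window transmembrane-segment predictor.

#' Default property tables
#'
#' Fixes the numeric conventions of the property calculators: average
#' residue masses (Da) with the mass of one water, the Bjellqvist pKa set
#' for the termini and ionizable side chains (matching ExPASy ProtParam's
#' pI), and the Kyte-Doolittle hydropathy scale.
#'
#' @return A list with components `mass_table` (named residue masses plus
#'   `water`), `pka_table` (side-chain, N-terminal and C-terminal pKa sets
#'   with charge signs), and `kd_scale`.
#' @export
default_property_tables <- function() {
  mass <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
            C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
            H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
            M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
            T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, E = -3.5,
          Q = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  pka <- list(
    side = c(D = 4.05, E = 4.45, H = 5.98, C = 9.0, Y = 10.0,
             K = 10.0, R = 12.0),
    side_sign = c(D = -1, E = -1, H = +1, C = -1, Y = -1, K = +1, R = +1),
    # N-terminal pKa depends on the first residue (Bjellqvist)
    nterm = c(A = 7.59, E = 7.70, M = 7.00, P = 8.36, S = 6.93,
              T = 6.82, V = 7.44),
    nterm_default = 7.50,
    cterm = c(D = 4.55, E = 4.75),
    cterm_default = 3.55)
  list(mass_table = c(mass, water = 18.01524), pka_table = pka, kd_scale = kd)
}

seq_chars <- function(sequence) strsplit(toupper(sequence), "")[[1]]

#' Protein molecular weight from average residue masses
#'
#' Sum of average residue masses plus one water. The ambiguity code `X` has
#' no mass and is rejected.
#'
#' @param sequence amino-acid string (canonical residues only).
#' @param tables property tables, see [default_property_tables()].
#' @return Mass in Daltons.
#' @export
molecular_weight <- function(sequence, tables = default_property_tables()) {
  s <- seq_chars(sequence)
  if (!length(s)) stop("empty sequence")
  if (any(!(s %in% names(tables$mass_table))))
    stop("molecular weight undefined for residue(s): ",
         paste(unique(s[!(s %in% names(tables$mass_table))]), collapse = ","))
  sum(tables$mass_table[s]) + tables$mass_table[["water"]]
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the two termini and the ionizable side
#' chains (D, E, C, Y negative; K, R, H positive), Bjellqvist pKa values.
#'
#' @param sequence amino-acid string.
#' @param pH pH value (may be a vector).
#' @param tables property tables.
#' @return Net charge (elementary charges), same length as `pH`.
#' @export
net_charge <- function(sequence, pH, tables = default_property_tables()) {
  s <- seq_chars(sequence)
  if (!length(s)) stop("empty sequence")
  pk <- tables$pka_table
  nt_pka <- if (s[1] %in% names(pk$nterm)) pk$nterm[[s[1]]] else pk$nterm_default
  ct_pka <- if (s[length(s)] %in% names(pk$cterm)) pk$cterm[[s[length(s)]]] else pk$cterm_default
  vapply(pH, function(p) {
    pos <- 1 / (1 + 10^(p - nt_pka))        # alpha-amino
    neg <- -1 / (1 + 10^(ct_pka - p))       # alpha-carboxyl
    for (r in names(pk$side)) {
      n <- sum(s == r)
      if (!n) next
      q <- if (pk$side_sign[[r]] > 0) n / (1 + 10^(p - pk$side[[r]]))
           else -n / (1 + 10^(pk$side[[r]] - p))
      pos <- pos + max(q, 0)
      neg <- neg + min(q, 0)
    }
    pos + neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' The pH at which [net_charge()] is zero. Net charge is strictly
#' decreasing in pH, so the root on `[0, 14]` is unique; bisection runs to
#' a pH tolerance of 1e-4.
#'
#' @inheritParams molecular_weight
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, tables = default_property_tables()) {
  lo <- 0; hi <- 14
  if (net_charge(sequence, lo, tables) < 0) return(lo)
  if (net_charge(sequence, hi, tables) > 0) return(hi)
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, tables) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' GRAVY: grand average of hydropathy
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values over all residues;
#' `X` is excluded from the mean.
#'
#' @inheritParams molecular_weight
#' @return Mean hydropathy (dimensionless).
#' @export
gravy <- function(sequence, tables = default_property_tables()) {
  s <- seq_chars(sequence)
  s <- s[s != "X"]
  if (!length(s)) stop("empty sequence (or all-X)")
  mean(tables$kd_scale[s])
}

#' Predict transmembrane segments by hydropathy windowing
#'
#' A deliberately simple hydropathy-plot predictor (NOT a hidden-Markov
#' topology model): window centres whose mean Kyte-Doolittle hydropathy
#' reaches `threshold` are expanded to full window extent and overlapping
#' runs are merged. Counts from this heuristic are descriptive; they are
#' not comparable to TMHMM output.
#'
#' @param sequence amino-acid string.
#' @param tables property tables.
#' @param window odd window width, residues (default 19, the classic
#'   hydropathy-plot setting for membrane helices).
#' @param threshold mean-hydropathy cutoff (default 1.6).
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   zero rows when nothing qualifies or the sequence is shorter than the
#'   window.
#' @export
predict_tmh <- function(sequence, tables = default_property_tables(),
                        window = 19L, threshold = 1.6) {
  if (window %% 2L == 0L) stop("window must be odd")
  s <- seq_chars(sequence)
  n <- length(s)
  if (n < window) return(data.frame(start = integer(0), end = integer(0)))
  kd <- unname(tables$kd_scale[s])
  kd[is.na(kd)] <- 0  # X as neutral
  cs <- c(0, cumsum(kd))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  hot <- which(means >= threshold)  # window start offsets
  if (!length(hot)) return(data.frame(start = integer(0), end = integer(0)))
  starts <- hot
  ends <- hot + window - 1L
  # merge overlapping/adjacent windows
  out_s <- starts[1]; out_e <- ends[1]; res <- NULL
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= out_e + 1L) out_e <- max(out_e, ends[i])
    else { res <- rbind(res, c(out_s, out_e)); out_s <- starts[i]; out_e <- ends[i] }
  }
  res <- rbind(res, c(out_s, out_e))
  data.frame(start = as.integer(res[, 1]), end = as.integer(res[, 2]))
}

#' Physicochemical property table for a candidate set
#'
#' One profile per candidate, in input order: length, molecular weight,
#' isoelectric point, GRAVY and predicted transmembrane segments.
#'
#' @param candidates a `clc_candidates` table or [protein_set()].
#' @param tables property tables.
#' @param window,threshold passed to [predict_tmh()].
#' @return data.frame with columns `id`, `length`, `mw_da`, `mw_kda`
#'   (1 decimal), `pi` (2 decimals), `gravy` (3 decimals), `tmh_count`,
#'   plus a `tmh_segments` list-column of per-protein segment tables.
#' @export
property_table <- function(candidates, tables = default_property_tables(),
                           window = 19L, threshold = 1.6) {
  if (!nrow(candidates))
    return(data.frame(id = character(0), length = integer(0),
                      mw_da = numeric(0), mw_kda = numeric(0),
                      pi = numeric(0), gravy = numeric(0),
                      tmh_count = integer(0)))
  segs <- lapply(candidates$sequence, predict_tmh, tables = tables,
                 window = window, threshold = threshold)
  out <- data.frame(
    id = candidates$id,
    length = nchar(candidates$sequence),
    mw_da = vapply(candidates$sequence, molecular_weight, numeric(1),
                   tables = tables),
    stringsAsFactors = FALSE)
  out$mw_kda <- round(out$mw_da / 1000, 1)
  out$pi <- round(vapply(candidates$sequence, isoelectric_point, numeric(1),
                         tables = tables), 2)
  out$gravy <- round(vapply(candidates$sequence, gravy, numeric(1),
                            tables = tables), 3)
  out$tmh_count <- vapply(segs, nrow, integer(1))
  out$tmh_segments <- segs
  rownames(out) <- NULL
  out
}

#' Write a property table (without the segment list-column)
#' @param props output of [property_table()].
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_property_table <- function(props, path) {
  cols <- c("id", "length", "mw_kda", "pi", "gravy", "tmh_count")
  write.table(props[, intersect(cols, names(props))], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
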