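# Domain identification: profile construction, window scanning, HMMER3
# domtblout ingestion, isoform collapse and the E-value candidate filter.

# Synthetic stand-in consensus strings for the two CLC-associated domains.
# These are fixed package data used by the profile scanner and the proteome
# simulator; they are NOT the Pfam seed consensi (no external profiles are
# bundled), just fixed sequences with CLC-like composition.
VOLTAGE_CLC_CONSENSUS <- paste0(
  "LAVVGAACGLSAGFNAPLAGTMFAIEEMRWQFRYNLISIKAVFTGVIMSSIMAHAFNGEQ")
CBS_CONSENSUS <- "VVDEIMTKDVITVSPDTTLSEAKELMHEHG"

#' Default E-value cutoff for CLC candidacy
#'
#' Candidates require at least one Voltage_CLC domain hit at or below this
#' expectation value.
#' @export
E_CUTOFF_DEFAULT <- 1e-10

#' Build a log-odds domain profile from a consensus sequence
#'
#' The profile assigns each position a per-residue log2-odds score of a
#' match distribution (probability `match_prob` on the consensus residue,
#' remainder spread uniformly) against uniform background frequencies.
#' `X` always scores 0 (background). E-value parameters are a Gumbel
#' location/scale fitted by the method of moments to per-window scores of
#' `null_n` random background sequences generated from `seed`.
#'
#' @param name domain name (e.g. `"Voltage_CLC"`, `"CBS"`).
#' @param consensus consensus amino-acid string.
#' @param bit_threshold minimum reported window score, bits.
#' @param match_prob probability mass on the consensus residue per position.
#' @param background named numeric vector of background residue frequencies
#'   (default uniform over the 20 canonical residues).
#' @param null_n number of random null windows used for the Gumbel fit.
#' @param seed RNG seed for the null calibration (stored in the profile).
#' @return An object of class `domain_profile`.
#' @export
build_domain_profile <- function(name, consensus, bit_threshold = 30,
                                 match_prob = 0.6, background = NULL,
                                 null_n = 500L, seed = 101L) {
  consensus <- toupper(consensus)
  res <- strsplit(consensus, "")[[1]]
  if (!all(res %in% AA_ALPHABET))
    stop("consensus must use the 20 canonical residues")
  if (is.null(background))
    background <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  stopifnot(abs(sum(background) - 1) < 1e-8, is.finite(bit_threshold))
  L <- length(res)
  lo <- matrix(0, nrow = L, ncol = 21,
               dimnames = list(NULL, c(AA_ALPHABET, "X")))
  for (i in seq_len(L)) {
    p <- setNames(rep((1 - match_prob) / 19, 20), AA_ALPHABET)
    p[res[i]] <- match_prob
    lo[i, AA_ALPHABET] <- log2(p / background[AA_ALPHABET])
  }
  prof <- structure(list(name = name, length = L, log_odds = lo,
                         bit_threshold = bit_threshold,
                         consensus = consensus, background = background,
                         seed = seed),
                    class = "domain_profile")
  # Gumbel null: per-window scores of random background sequences
  null_scores <- withr_seed(seed, {
    vapply(seq_len(null_n), function(i) {
      s <- sample(AA_ALPHABET, L, replace = TRUE, prob = background)
      sum(lo[cbind(seq_len(L), match(s, colnames(lo)))])
    }, numeric(1))
  })
  beta <- stats::sd(null_scores) * sqrt(6) / pi
  mu <- mean(null_scores) - 0.5772156649 * beta
  prof$evalue_params <- c(location = mu, scale = beta)
  prof
}

# run code under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Default packaged domain profiles
#'
#' Profiles for the CLC-defining `Voltage_CLC` domain and the C-terminal
#' regulatory `CBS` domain, built from the fixed packaged consensus strings.
#' @return Named list of `domain_profile` objects.
#' @export
default_domain_profiles <- function() {
  list(Voltage_CLC = build_domain_profile("Voltage_CLC", VOLTAGE_CLC_CONSENSUS),
       CBS = build_domain_profile("CBS", CBS_CONSENSUS))
}

# score every window of seq against profile; returns numeric vector, one per
# start offset (empty when the sequence is shorter than the profile)
window_scores <- function(sequence, profile) {
  s <- strsplit(sequence, "")[[1]]
  L <- profile$length
  n <- length(s) - L + 1L
  if (n < 1L) return(numeric(0))
  idx <- match(s, colnames(profile$log_odds))
  vapply(seq_len(n), function(i)
    sum(profile$log_odds[cbind(seq_len(L), idx[i:(i + L - 1L)])]),
    numeric(1))
}

#' Scan a protein with a domain profile
#'
#' Slides the profile over every offset, reports windows with score at or
#' above the profile's bit threshold, greedily selecting non-overlapping
#' hits in decreasing score order. E-values are the Gumbel upper-tail
#' probability of the window score times the number of windows scanned.
#'
#' @param protein a single-row [protein_set()] or an amino-acid string.
#' @param profile a `domain_profile`.
#' @return A data.frame of domain hits (`protein_id`, `domain`, `start`,
#'   `end`, `bit_score`, `evalue`); zero rows when the protein is shorter
#'   than the profile or nothing reaches the threshold.
#' @export
scan_profile <- function(protein, profile) {
  if (inherits(protein, "protein_set")) {
    stopifnot(nrow(protein) == 1L)
    id <- protein$id
    seqs <- protein$sequence
  } else {
    id <- "query"
    seqs <- toupper(protein)
  }
  sc <- window_scores(seqs, profile)
  empty <- domain_hits(character(0), character(0), integer(0), integer(0),
                       numeric(0), numeric(0))
  if (!length(sc)) return(empty)
  keep <- which(sc >= profile$bit_threshold)
  if (!length(keep)) return(empty)
  keep <- keep[order(sc[keep], keep, decreasing = c(TRUE, FALSE), method = "radix")]
  chosen <- integer(0)
  for (k in keep) {
    if (!any(abs(k - chosen) < profile$length)) chosen <- c(chosen, k)
  }
  chosen <- sort(chosen)
  mu <- profile$evalue_params[["location"]]
  beta <- profile$evalue_params[["scale"]]
  pval <- -expm1(-exp(-(sc[chosen] - mu) / beta))  # P(S >= s), Gumbel
  domain_hits(rep(id, length(chosen)), rep(profile$name, length(chosen)),
              chosen, chosen + profile$length - 1L,
              sc[chosen], pmax(pval * length(sc), 1e-300))
}

#' Construct a domain-hit table
#'
#' Coordinates are 1-based inclusive residue positions.
#' @param protein_id,domain,start,end,bit_score,evalue parallel vectors.
#' @return data.frame of class `domain_hits`.
#' @export
domain_hits <- function(protein_id, domain, start, end, bit_score, evalue) {
  if (any(evalue < 0)) stop("negative E-value")
  if (any(end < start)) stop("domain hit with end < start")
  if (any(start < 1L)) stop("domain hit with start < 1")
  out <- data.frame(protein_id = as.character(protein_id),
                    domain = as.character(domain),
                    start = as.integer(start), end = as.integer(end),
                    bit_score = as.numeric(bit_score),
                    evalue = as.numeric(evalue), stringsAsFactors = FALSE)
  class(out) <- c("domain_hits", "data.frame")
  out
}

#' Parse a HMMER3 per-domain table (domtblout)
#'
#' Reads the whitespace-delimited per-domain hits table written by
#' `hmmsearch --domtblout`. One hit per row, using the envelope coordinates
#' and the independent (i-)E-value; target name is the protein, query name
#' the domain/profile.
#'
#' @param path path to the table; lines starting with `#` are ignored.
#' @return A `domain_hits` data.frame (possibly zero rows).
#' @export
parse_domtblout <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(body))
    return(domain_hits(character(0), character(0), integer(0), integer(0),
                       numeric(0), numeric(0)))
  rows <- lapply(body, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22L)
      stop("domtblout line ", i, ": expected >= 22 columns, got ", length(f))
    f
  })
  m <- do.call(rbind, rows)
  suppressWarnings({
    ev <- as.numeric(m[, 13])
    sc <- as.numeric(m[, 14])
    from <- as.integer(m[, 20])
    to <- as.integer(m[, 21])
  })
  if (anyNA(ev) || anyNA(from) || anyNA(to))
    stop("domtblout: non-numeric coordinate or E-value field")
  domain_hits(m[, 1], m[, 4], from, to, sc, ev)
}

#' Collapse isoforms to one representative per locus
#'
#' Keeps the longest sequence per locus; equal lengths break ties toward the
#' lexicographically smaller id.
#'
#' @param proteins a [protein_set()].
#' @param locus_of named character vector mapping record id to locus.
#' @return A [protein_set()] with one row per locus, in order of first
#'   appearance of each locus.
#' @export
collapse_isoforms <- function(proteins, locus_of) {
  stopifnot(inherits(proteins, "protein_set"))
  missing <- setdiff(proteins$id, names(locus_of))
  if (length(missing))
    stop("id(s) missing from locus map: ", paste(missing, collapse = ", "))
  loci <- unname(locus_of[proteins$id])
  keep <- integer(0)
  for (lc in unique(loci)) {
    rows <- which(loci == lc)
    len <- nchar(proteins$sequence[rows])
    best <- rows[order(-len, proteins$id[rows], method = "radix")][1]
    keep <- c(keep, best)
  }
  out <- proteins[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Filter CLC candidates by Voltage_CLC domain E-value
#'
#' A protein passes iff it carries at least one `Voltage_CLC` hit with
#' E-value at or below `e_cutoff` (default 1e-10). CBS hits are recorded
#' but never required: the defining screen is the Voltage_CLC domain alone,
#' and the canonical pair of C-terminal CBS domains is treated as an
#' observed property of true CLCs rather than a gate.
#'
#' @param proteins a [protein_set()].
#' @param hits a `domain_hits` table over those proteins.
#' @param e_cutoff E-value cutoff, > 0.
#' @return A `clc_candidates` data.frame sorted by protein id, with columns
#'   `id`, `species`, `sequence`, `n_voltage_clc`, `n_cbs`, `best_evalue`,
#'   `passed`, and the full hit table in `attr(, "hits")`.
#' @export
filter_candidates <- function(proteins, hits, e_cutoff = E_CUTOFF_DEFAULT) {
  stopifnot(inherits(proteins, "protein_set"), e_cutoff > 0)
  ord <- order(proteins$id, method = "radix")
  proteins <- proteins[ord, , drop = FALSE]
  vc <- hits[hits$domain == "Voltage_CLC", , drop = FALSE]
  cbs <- hits[hits$domain == "CBS", , drop = FALSE]
  n_vc <- vapply(proteins$id, function(i) sum(vc$protein_id == i), integer(1))
  n_cbs <- vapply(proteins$id, function(i) sum(cbs$protein_id == i), integer(1))
  best <- vapply(proteins$id, function(i) {
    e <- vc$evalue[vc$protein_id == i]
    if (length(e)) min(e) else NA_real_
  }, numeric(1))
  out <- data.frame(id = proteins$id, species = proteins$species,
                    sequence = proteins$sequence,
                    n_voltage_clc = n_vc, n_cbs = n_cbs,
                    best_evalue = best,
                    passed = !is.na(best) & best <= e_cutoff,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "hits") <- hits
  class(out) <- c("clc_candidates", "data.frame")
  out
}

#' Run the identification stage on a protein set
#'
#' Scans every protein with the packaged (or supplied) profiles, or uses a
#' precomputed domain-hit table, then applies [filter_candidates()].
#'
#' @param proteins a [protein_set()].
#' @param hits optional precomputed `domain_hits` (e.g. from
#'   [parse_domtblout()]); when `NULL`, the built-in profile scanner runs.
#' @param profiles named list of `domain_profile`s (default packaged pair).
#' @param e_cutoff candidacy E-value cutoff.
#' @return A `clc_candidates` table (see [filter_candidates()]).
#' @export
identify_candidates <- function(proteins, hits = NULL, profiles = NULL,
                                e_cutoff = E_CUTOFF_DEFAULT) {
  stopifnot(inherits(proteins, "protein_set"))
  if (is.null(hits)) {
    if (is.null(profiles)) profiles <- default_domain_profiles()
    hit_list <- lapply(seq_len(nrow(proteins)), function(i) {
      do.call(rbind, lapply(profiles, function(p)
        scan_profile(proteins[i, , drop = FALSE], p)))
    })
    hits <- do.call(rbind, hit_list)
    rownames(hits) <- NULL
    class(hits) <- c("domain_hits", "data.frame")
  }
  filter_candidates(proteins, hits, e_cutoff)
}

#' Write the candidate table (1-based inclusive coordinates upstream)
#' @param candidates a `clc_candidates` table.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  cols <- c("id", "species", "n_voltage_clc", "n_cbs", "best_evalue", "passed")
  write.table(candidates[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
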