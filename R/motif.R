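# Conserved-region location and residue-rule classification.
#
# Three short regions diagnose function across the CLC family:
#   I   GxGIPE   - the wildcard is the selectivity residue (P -> NO3-,
#                  S -> Cl-)
#   II  GKxGPxxH - the first wildcard is the gating glutamate position
#   III PxxGxLF  - the proton glutamate sits four residues past the match
# Antiporters carry both glutamates; substitution of either one marks a
# passive channel. Proteins lacking the regions (the prokaryote-like clade)
# stay unclassified.

#' Conserved-region patterns and diagnostic offsets
#'
#' @return A list of three `region_pattern` objects (`I`, `II`, `III`),
#'   each with fields `region_id`, `pattern` (with `x` wildcards),
#'   `key_offset` (1-based position of the diagnostic residue within the
#'   match; `NA` for region III) and `downstream_offset` (residues past the
#'   match end where the proton glutamate is read; region III only).
#' @export
region_patterns <- function() {
  mk <- function(id, pattern, key_offset = NA_integer_,
                 downstream_offset = NA_integer_) {
    structure(list(region_id = id, pattern = pattern,
                   key_offset = key_offset,
                   downstream_offset = downstream_offset),
              class = "region_pattern")
  }
  list(I = mk("I", "GxGIPE", key_offset = 2L),
       II = mk("II", "GKxGPxxH", key_offset = 3L),
       III = mk("III", "PxxGxLF", downstream_offset = 4L))
}

# wildcard 'x' matches any canonical residue but never the ambiguity code X
pattern_regex <- function(pattern) {
  chartr_src <- strsplit(pattern, "")[[1]]
  paste(ifelse(chartr_src == "x",
               paste0("[", paste(AA_ALPHABET, collapse = ""), "]"),
               chartr_src), collapse = "")
}

#' Locate a conserved region in a protein
#'
#' Plain per-sequence pattern search; when a domain hit is supplied the
#' search is restricted to its span and the leftmost match inside the span
#' wins. Returns `NULL` (a typed no-match) when the pattern is absent.
#'
#' @param protein single-row [protein_set()] or amino-acid string.
#' @param pattern a `region_pattern` from [region_patterns()].
#' @param domain_span optional single-row `domain_hits` restricting the
#'   search.
#' @return A `region_match` list (`protein_id`, `region_id`, `start`,
#'   `end`, `matched_text`, `key_residue`) or `NULL`.
#' @export
find_region <- function(protein, pattern, domain_span = NULL) {
  if (inherits(protein, "protein_set")) {
    stopifnot(nrow(protein) == 1L)
    id <- protein$id; s <- protein$sequence
  } else { id <- "query"; s <- toupper(protein) }
  offset <- 0L
  search <- s
  if (!is.null(domain_span)) {
    offset <- domain_span$start[1] - 1L
    search <- substr(s, domain_span$start[1], domain_span$end[1])
  }
  m <- regexpr(pattern_regex(pattern$pattern), search)
  if (m == -1L) return(NULL)
  start <- as.integer(m) + offset
  end <- start + attr(m, "match.length") - 1L
  text <- substr(s, start, end)
  key <- if (!is.na(pattern$key_offset))
    substr(text, pattern$key_offset, pattern$key_offset) else NA_character_
  structure(list(protein_id = id, region_id = pattern$region_id,
                 start = start, end = end, matched_text = text,
                 key_residue = key),
            class = "region_match")
}

#' Anion selectivity from the region I wildcard
#'
#' Proline at the wildcard marks nitrate preference, serine chloride
#' preference; any other residue (or a missing region I) is `unknown`.
#'
#' @param match_I a `region_match` for region I, or `NULL`.
#' @return `"NO3-"`, `"Cl-"` or `"unknown"`.
#' @export
call_selectivity <- function(match_I) {
  if (is.null(match_I)) return("unknown")
  switch(match_I$key_residue, P = "NO3-", S = "Cl-", "unknown")
}

#' Gating glutamate from region II
#'
#' @param match_II a `region_match` for region II, or `NULL`.
#' @return `"present"` (first wildcard is E), `"absent"`, or
#'   `"undetermined"` when region II is unmatched.
#' @export
detect_gating_glutamate <- function(match_II) {
  if (is.null(match_II)) return("undetermined")
  if (match_II$key_residue == "E") "present" else "absent"
}

#' Proton glutamate downstream of region III
#'
#' Reads the residue `offset` positions past the region III match end
#' (default 4, i.e. the fourth residue after the match).
#'
#' @param protein single-row [protein_set()] or amino-acid string.
#' @param match_III a `region_match` for region III, or `NULL`.
#' @param offset residues past the match end.
#' @return `"present"`, `"absent"`, or `"undetermined"` (no match, or the
#'   offset runs past the end of the sequence).
#' @export
detect_proton_glutamate <- function(protein, match_III, offset = 4L) {
  if (is.null(match_III)) return("undetermined")
  s <- if (inherits(protein, "protein_set")) protein$sequence else toupper(protein)
  pos <- match_III$end + offset
  if (pos > nchar(s)) return("undetermined")
  if (substr(s, pos, pos) == "E") "present" else "absent"
}

#' Classify a CLC protein as antiporter or channel
#'
#' Locates the three conserved regions and applies the residue rules:
#' antiporter iff gating and proton glutamates are both present; channel
#' if at least one is determined absent; unclassified when either flag is
#' undetermined (e.g. the prokaryote-like clade lacking the regions).
#' Selectivity (region I) is an independent axis and is reported whatever
#' the transport class.
#'
#' @param protein single-row [protein_set()] or amino-acid string.
#' @param patterns region patterns, see [region_patterns()].
#' @param domain_span optional `domain_hits` row restricting region search.
#' @param proton_offset offset for [detect_proton_glutamate()].
#' @return A `clc_classification` list: `protein_id`, region matches,
#'   `selectivity_residue`, `selectivity`, `gating_glutamate`,
#'   `proton_glutamate`, `transport_class`.
#' @export
classify_transport <- function(protein, patterns = region_patterns(),
                               domain_span = NULL, proton_offset = 4L) {
  id <- if (inherits(protein, "protein_set")) protein$id else "query"
  mI <- find_region(protein, patterns$I, domain_span)
  mII <- find_region(protein, patterns$II, domain_span)
  mIII <- find_region(protein, patterns$III, domain_span)
  gating <- detect_gating_glutamate(mII)
  proton <- detect_proton_glutamate(protein, mIII, proton_offset)
  cls <- if (gating == "present" && proton == "present") "antiporter"
         else if (gating == "absent" || proton == "absent") "channel"
         else "unclassified"
  structure(list(protein_id = id,
                 match_I = mI, match_II = mII, match_III = mIII,
                 selectivity_residue = if (is.null(mI)) NA_character_ else mI$key_residue,
                 selectivity = call_selectivity(mI),
                 gating_glutamate = gating, proton_glutamate = proton,
                 transport_class = cls),
            class = "clc_classification")
}

#' Classify every protein in a set
#'
#' @param proteins a [protein_set()] or `clc_candidates` table.
#' @param ... passed to [classify_transport()].
#' @return data.frame with one row per protein: id, region spans, the
#'   selectivity residue and call, both glutamate flags and the transport
#'   class.
#' @export
classify_proteins <- function(proteins, ...) {
  span_str <- function(m) if (is.null(m)) NA_character_ else paste0(m$start, "-", m$end)
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    p <- proteins[i, , drop = FALSE]
    if (!inherits(p, "protein_set")) class(p) <- c("protein_set", "data.frame")
    cl <- classify_transport(p, ...)
    data.frame(id = proteins$id[i],
               region_I = span_str(cl$match_I),
               region_II = span_str(cl$match_II),
               region_III = span_str(cl$match_III),
               selectivity_residue = cl$selectivity_residue,
               selectivity = cl$selectivity,
               gating_glutamate = cl$gating_glutamate,
               proton_glutamate = cl$proton_glutamate,
               transport_class = cl$transport_class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a classification table
#' @param classification output of [classify_proteins()].
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_classification_table <- function(classification, path) {
  write.table(classification, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
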