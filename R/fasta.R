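#' @importFrom stats setNames sd quantile rnorm runif rbinom pf ptukey pt cor
#' @importFrom utils read.delim write.table head tail
NULL

# Canonical residue alphabet. 'X' is tolerated as an ambiguity code; '*' is
# accepted in input as a stop and stripped.
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y")

#' Construct a set of protein records
#'
#' A protein set is the package's container for amino-acid sequences: a
#' `data.frame` with columns `id`, `species` and `sequence`, one row per
#' protein. Sequences are stored uppercase using the 20 canonical one-letter
#' codes plus `X` for ambiguity.
#'
#' @param id character vector of unique identifiers (locus tags, accessions).
#' @param sequence character vector of amino-acid strings.
#' @param species optional character vector of species labels.
#' @return A `protein_set` data.frame.
#' @export
protein_set <- function(id, sequence, species = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(gsub("\\s", "", as.character(sequence)))
  sequence <- gsub("\\*$", "", sequence)
  if (length(id) != length(sequence))
    stop("id and sequence must have equal length")
  if (anyDuplicated(id))
    stop("duplicate protein id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  bad <- vapply(sequence, function(s)
    grepl(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")), s), logical(1))
  if (any(bad))
    stop("non-amino-acid characters in record(s): ",
         paste(id[bad], collapse = ", "))
  out <- data.frame(id = id, species = rep_len(as.character(species), length(id)),
                    sequence = sequence, stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' Wrapped lines are joined and sequences are case-folded to uppercase. The
#' record id is the first whitespace-delimited token of the header; a
#' `species=<name>` tag anywhere in the header populates the species column.
#'
#' @param path path to a FASTA file.
#' @return A [protein_set()] with one row per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("non-amino-acid characters in FASTA file: ", path, call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  species <- ifelse(grepl("species=", headers),
                    sub(".*species=(\\S+).*", "\\1", headers), NA_character_)
  protein_set(ids, as.character(aa), species)
}

#' Write a protein set to FASTA
#'
#' @param proteins a [protein_set()].
#' @param path output path.
#' @param width line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 70L) {
  stopifnot(inherits(proteins, "protein_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    hdr <- proteins$id[i]
    if (!is.na(proteins$species[i]))
      hdr <- paste0(hdr, " species=", proteins$species[i])
    writeLines(paste0(">", hdr), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
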