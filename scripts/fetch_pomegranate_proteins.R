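#!/usr/bin/env Rscript
# One-time, network-requiring helper: fetches the seven published
# pomegranate CLC protein sequences by locus tag from NCBI and stores them
# as inst/extdata/pomegranate_pgclc.fasta, enabling the two accession-based
# acceptance tests. Not run during normal test execution (no network is
# assumed there).

loci <- c("CDL15_Pgr005627", "CDL15_Pgr027626", "CDL15_Pgr013895",
          "CDL15_Pgr008552", "CDL15_Pgr019810", "CDL15_Pgr012201",
          "CDL15_Pgr015371")

eutils <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"
out <- file.path("inst", "extdata", "pomegranate_pgclc.fasta")
dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)

fetch_one <- function(locus) {
  search <- sprintf("%s/esearch.fcgi?db=protein&term=%s", eutils, locus)
  doc <- readLines(search, warn = FALSE)
  id <- regmatches(doc, regexpr("<Id>[0-9]+</Id>", doc))
  id <- gsub("</?Id>", "", id[1])
  if (!length(id) || is.na(id)) stop("no protein record found for ", locus)
  fa <- readLines(sprintf(
    "%s/efetch.fcgi?db=protein&id=%s&rettype=fasta&retmode=text", eutils, id),
    warn = FALSE)
  # normalise the header to the locus tag so tests address records directly
  fa[1] <- paste0(">", locus)
  Sys.sleep(0.4)  # NCBI rate limit
  fa[nzchar(fa)]
}

writeLines(unlist(lapply(loci, fetch_one)), out)
message("wrote ", out)
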