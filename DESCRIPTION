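Package: clcfamily
Title: Identification, Classification and Expression Analysis of the CLC
    Anion Channel/Transporter Gene Family
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for genome-wide analysis of the CLC
    (chloride channel/transporter) gene family. Identifies CLC candidates in
    a proteome by log-odds profile scanning or by ingesting HMMER3 domain
    tables, computes physicochemical profiles (molecular weight, isoelectric
    point, GRAVY, hydropathy-based transmembrane segments), classifies each
    protein as antiporter or channel and as nitrate- or chloride-selective
    from the conserved-region residues (selectivity residue in GxGIPE, gating
    glutamate in GKxGPxxH, proton glutamate downstream of PxxGxLF), infers
    duplication and loss events by LCA gene-tree/species-tree reconciliation,
    and runs the downstream expression and anion statistics (2^-ddCt fold
    changes, one-way ANOVA with Tukey HSD compact letter displays, Pearson
    correlation matrices). Ships seedable synthetic-data generators with
    ground-truth manifests so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
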