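---
title: "Methods: CLC gene-family identification, classification and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CLC gene-family identification, classification and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clcfamily)
```

## The scientific problem

CLC proteins conduct Cl⁻, NO₃⁻, HCO₃⁻ and I⁻ across plant membranes and
are central to how plants redistribute anions under salt stress. The
family has a well-conserved architecture — one voltage-gated chloride
channel (Voltage_CLC) domain plus a pair of C-terminal regulatory CBS
domains — and, remarkably, a handful of single residues determine
function:

* the wildcard residue of the conserved region **GxGIPE** (region I) sets
  anion preference: proline → NO₃⁻, serine → Cl⁻;
* the first wildcard of **GKxGPxxH** (region II) is the *gating
  glutamate*;
* the fourth residue past a **PxxGxLF** match (region III) is the *proton
  glutamate*.

Proteins carrying both glutamates couple anion flow to proton
antiport (active transport); substitution of either one leaves a passive
channel. `clcfamily` turns this whole analysis — candidate discovery in a
proteome, physicochemical profiling, residue-rule classification,
duplication/loss inference against a species tree, and the downstream
qPCR and anion statistics — into one testable, scriptable pipeline.

## Identification model

Candidates are defined by the Voltage_CLC domain alone: a protein passes
iff it has at least one Voltage_CLC hit with E ≤ 10⁻¹⁰ (`e_cutoff`,
the field-standard screen threshold). CBS hits are recorded but **not**
required: the canonical "two CBS domains" is an observed property of true
CLCs and gating on it would silently drop genuine hits with degenerate
CBS copies.

Two ingestion routes exist:

1. **HMMER3 tables** (`parse_domtblout()`): the per-domain tabular layout
   of `hmmsearch --domtblout`, using envelope coordinates and the
   independent E-value. This is the route for production scans with real
   Pfam profiles.
2. **Built-in profile scanning** (`scan_profile()`): a position-specific
   log-odds window scanner so the pipeline runs with no external binaries
   or downloaded profiles. A profile assigns each position log₂-odds of a
   match distribution (mass `match_prob = 0.6` on the consensus residue)
   against uniform background; the ambiguity code X scores 0. Window
   scores at or above `bit_threshold` (30 bits) are greedily selected
   without overlap. E-values come from a Gumbel location/scale fitted by
   the method of moments to per-window scores of 500 seeded random
   background sequences — HMMER's own calibration is unavailable, and the
   Gumbel is the standard null family for ungapped local scores. The
   packaged consensus strings are *synthetic stand-ins* with CLC-like
   composition, not the Pfam seed consensi; with `match_prob = 0.6` a
   planted 60-residue consensus scores ≈ 200 bits against a null mean of
   ≈ −60 (sd ≈ 8), so planted/background separation is essentially
   deterministic while shuffled sequences stay orders of magnitude above
   the E-cutoff (verified on 100 seeded shuffles).

Isoform collapse keeps the longest sequence per locus (ties: smaller id),
a reproducible stand-in for the study-style manual curation.

## Physicochemical profile

All conventions are fixed in `default_property_tables()` and swappable:

* **Molecular weight**: average residue masses + one water (matching
  ProtParam). X is rejected — an unknown residue has no mass.
* **Isoelectric point**: bisection on [0, 14] to 10⁻⁴ pH of the
  Henderson–Hasselbalch net charge with the Bjellqvist pKa set
  (ProtParam's), including the residue-specific terminal pKa values. Net
  charge is strictly decreasing in pH, so the root is unique; the suite
  checks |net_charge(s, pI)| < 10⁻³ on random sequences.
* **GRAVY**: mean Kyte–Doolittle hydropathy, X excluded.
* **Transmembrane segments** (`predict_tmh()`): maximal runs of
  19-residue windows with mean hydropathy ≥ 1.6, merged after expansion
  to window extent. Window 19 / threshold 1.6 is the classic
  hydropathy-plot convention for membrane helices. This is a documented
  heuristic, *not* an HMM topology model: counts are descriptive output
  and are deliberately never compared against published TMHMM counts.

Report rounding mirrors the usual table precision: Mw 1 decimal (kDa),
pI 2 decimals, GRAVY 3 decimals.

## Residue-rule classification

Region search is per-sequence pattern matching (wildcards match any
canonical residue, never X; leftmost match wins, optionally restricted to
a domain span). Classification composes three independent reads:

| gating \\ proton | present | absent | undetermined |
|---|---|---|---|
| **present** | antiporter | channel | unclassified |
| **absent** | channel | channel | channel |
| **undetermined** | unclassified | channel | unclassified |

Selectivity (region I) is an *independent axis*: a serine-bearing protein
can still be a channel (the CLC-G pattern), so selectivity is always
reported regardless of transport class. Proteins lacking the regions —
the prokaryote-like clade II — stay unclassified rather than being
forced into a call. The proton glutamate is read at `match_end + 4`; the
offset is a parameter (`proton_offset`) because "the next fourth residue"
admits an off-by-one reading.

When a curated alignment is available, `classify_from_alignment()` reads
the diagnostic residues at the alignment columns anchored by one
reference row, which tolerates pattern-breaking substitutions in
individual sequences.

## Trees and reconciliation

Published trees are first-class inputs (Newick, with supports stored as
node labels). For desk-scale self-containment the package includes a
simplified conserved-block filter (keep a column iff its majority non-gap
residue fraction ≥ `min_ident_fraction` and gap fraction ≤
`max_gap_fraction`; drop kept runs shorter than `min_block_length`;
defaults 0.5 / 0.2 / 5), p- and Poisson-corrected distances, and
neighbor-joining with midpoint rooting. The block filter is a
three-parameter simplification and is not claimed column-identical to
Gblocks; maximum-likelihood inference is out of scope by design.

`lca_reconcile()` maps each gene-tree node to the species-tree LCA of its
descendants' species; a node is a duplication iff its mapping equals a
child's mapping; losses follow the path-depth rule (one loss per skipped
sibling branch, the topmost step exempt at speciations). This yields the
minimum duplication-loss reconciliation for the given rooting — the suite
verifies minimality against an exhaustive search over all valid mappings
on 200 seeded random instances. Unrooted input is midpoint-rooted;
`try_all_rootings = TRUE` selects the duplication-minimizing rooting.
Multifurcations are resolved left-associatively with a warning.

Ortholog naming follows the smallest clade containing the query and at
least one named reference: majority name wins, exact ties are
"ambiguous", and same-species queries sharing a name get numeric suffixes
in tree order (C1, C2) — mirroring how family members are conventionally
named after their *Arabidopsis* homologs.

## Expression and anion statistics

`ddct_fold_change()` implements the 2^−ΔΔCT method. Technical replicates
are averaged within each biological replicate *before* any statistics
(the convention when a protocol is silent); ΔCT = Ct(gene) − Ct(reference)
per biological replicate; ΔΔCT subtracts the mean calibrator ΔCT; the
standard error is taken over biological replicates. Amplification
efficiency correction is out of scope — the method is the pure 2^−ΔΔCT.

ANOVA is the classical one-way between/within decomposition (no Welch
correction, matching common practice in SPSS-based studies); zero
within-group variance with unequal means is reported as p = 0 with a
below-machine-epsilon flag. Tukey HSD uses the studentized range with the
Tukey–Kramer unbalanced correction; letters come from insert-and-absorb,
which guarantees both directions of the letter contract (groups share a
letter iff not significantly different) — the suite proves this
exhaustively over every significance relation on up to five groups.
Each (variable, tissue) panel is tested independently, matching per-panel
letter displays. "Increased N times" is read as ratio = N
(`times_means_increment` flips to N + 1). Correlations are Pearson with
two-sided p-values and 0.05/0.01 stars.

## What the synthetic generators emulate — and what they do not

* `simulate_proteome()` plants the full CLC signature (domain consensus,
  two CBS copies, regions I–III with labelled key residues, hydrophobic
  21-mers) in background sequence; decoys carry at most partial signals.
  A rejection step regenerates any sequence whose leftmost region match
  is not the planted one, so manifest labels are exact by construction.
  The default labels are four antiporters (one nitrate-selective) and
  three channels — the composition reported for pomegranate. The
  generator does **not** emulate homologous sequence divergence, so a
  green identification test establishes correct scanning/filtering logic,
  not sensitivity to remote homologs.
* `simulate_duploss_gene_tree()` runs a Poisson birth–death process along
  a species tree (default: a 15-taxon tree mirroring 8 core eudicots,
  2 monocots, 2 gymnosperms, 3 bryophytes, unit branch lengths). The
  manifest records the complete history, the *observable* history after
  pruning extinct lineages, and an identifiability flag. The flag exists
  because exact recovery is information-theoretically impossible when a
  duplication's surviving copies lose complementary clades: no
  reconciliation can see such events, and parsimony returns a strictly
  more economical history. Empirically (dup 0.1, loss 0.05 per unit
  length) ~98% of histories are identifiable, and on those LCA
  reconciliation recovers the observable (duplication, loss) counts
  exactly. Sequence evolution along the gene tree is not simulated —
  reconciliation is tested on topologies, as specified.
* `simulate_ct_table()` adds independent Gaussian noise on the Ct scale
  (the standard qPCR assumption; σ_Ct = 0.2 cycles default, three
  biological × three technical replicates as in the emulated protocol),
  with a constant-in-expectation reference gene. The planted default of
  log₂ fold 4 reflects the ">16-fold" headline inductions.
  `simulate_measurement_table()` supports increasing / hump (peak at the
  second level, i.e. 100 mM) / decreasing / flat profiles with constant
  coefficient of variation (8%), matching the qualitative anion trends;
  absolute concentrations are arbitrary units since the figure units are
  not recoverable.

## Numerical and degenerate-input choices

* Bisection tolerance 10⁻⁴ pH; Gumbel fit by method of moments on 500
  null windows; E-values floored at 10⁻³⁰⁰ to avoid exact zeros.
* Proteins shorter than a profile or window return empty results, not
  errors; empty sequences error.
* Zero shared ungapped sites between two alignment rows is an error, as
  is p ≥ 1 under the Poisson correction.
* NJ negative branch lengths are clamped to zero before midpoint rooting.
* All generators restore the caller's RNG state; determinism is
  per-(spec, seed) and byte-exact.

## Known limitations

* The built-in scanner is a fixed-emission log-odds window model, not a
  profile HMM: no position-specific gaps, no local/glocal alignment. It
  is calibrated for planted-signal fixtures and desk-scale screens, not
  for sensitive remote-homolog discovery — use real HMMER output via
  `parse_domtblout()` for that.
* TMH counts are hydropathy heuristics and not comparable to TMHMM.
* Reconciliation assumes rooted binary trees and one species tree;
  incomplete lineage sorting and horizontal transfer are out of scope.
* The accession-based acceptance checks (published property table and
  headline classification) require a one-time network fetch of the seven
  published sequences (`scripts/fetch_pomegranate_proteins.R`); without
  that file the corresponding tests fail by design rather than being
  silently skipped.
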