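# Synthetic-data generators. Every generator is a pure function of
# (spec, seed) and returns a ground-truth manifest sufficient to score the
# downstream stage without re-deriving the truth.

#' Default 15-taxon species tree for fixtures
#'
#' Eight core eudicots, two monocots, two gymnosperms and three
#' bryophytes-sensu-lato, with unit branch lengths (the simulators need
#' lengths; the absolute scale is arbitrary).
#'
#' @return ape `phylo` with 15 leaves.
#' @export
default_species_tree <- function() {
  nwk <- paste0(
    "((Sphagnum_fallax,(Marchantia_polymorpha,Selaginella_moellendorffii)),",
    "((Ginkgo_biloba,Pinus_taeda),((Oryza_sativa,Zostera_marina),",
    "(((Arabidopsis_thaliana,Eutrema_salsugineum),(Citrus_sinensis,",
    "(Populus_euphratica,Glycine_max))),((Punica_granatum,",
    "Eucalyptus_grandis),Vitis_vinifera)))));")
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

#' Taxon groups of the default species tree
#' @return Named list of species-label vectors.
#' @export
default_taxon_groups <- function() {
  list(core_eudicots = c("Arabidopsis_thaliana", "Eutrema_salsugineum",
                         "Citrus_sinensis", "Populus_euphratica",
                         "Glycine_max", "Punica_granatum",
                         "Eucalyptus_grandis", "Vitis_vinifera"),
       monocots = c("Oryza_sativa", "Zostera_marina"),
       gymnosperms = c("Ginkgo_biloba", "Pinus_taeda"),
       bryophytes = c("Sphagnum_fallax", "Marchantia_polymorpha",
                      "Selaginella_moellendorffii"))
}

#' Specification for a synthetic proteome
#'
#' @param n_true number of planted CLC proteins.
#' @param n_decoy number of decoys carrying at most partial signals.
#' @param labels data.frame with `n_true` rows and columns
#'   `selectivity_residue` (single letters, wildcard of region I),
#'   `gating` and `proton` (logical: glutamate present). Default: a mix of
#'   four antiporters (one nitrate-selective) and alternating channels,
#'   recycled to `n_true` rows.
#' @param n_tm transmembrane blocks planted per true gene.
#' @param seed RNG seed.
#' @return A `proteome_spec` list.
#' @export
proteome_spec <- function(n_true = 7L, n_decoy = 20L, labels = NULL,
                          n_tm = 4L, seed = 1L) {
  if (n_true < 0 || n_decoy < 0) stop("counts must be >= 0")
  if (is.null(labels) && n_true > 0) {
    base <- data.frame(
      selectivity_residue = c("P", "S", "S", "S", "A", "A", "S"),
      gating = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
      proton = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE)
    labels <- base[rep_len(seq_len(7L), n_true), , drop = FALSE]
    rownames(labels) <- NULL
  }
  if (n_true > 0 && (is.null(labels) || nrow(labels) != n_true))
    stop("labels must have one row per true gene")
  if (n_true == 0 && !is.null(labels) && nrow(labels) > 0)
    stop("labels given for zero true genes")
  structure(list(n_true = as.integer(n_true), n_decoy = as.integer(n_decoy),
                 labels = labels, n_tm = as.integer(n_tm),
                 seed = as.integer(seed)),
            class = "proteome_spec")
}

rand_bg <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")

# hydrophobic 21-mer for a planted membrane-spanning block
rand_tm <- function() paste(sample(c("I", "L", "V", "F", "A"), 21,
                                   replace = TRUE,
                                   prob = c(.3, .3, .2, .1, .1)), collapse = "")

planted_true_gene <- function(label, n_tm) {
  sel <- label$selectivity_residue
  gat <- if (label$gating) "E" else "T"
  pro <- if (label$proton) "E" else "Q"
  for (attempt in 1:100) {
    tm <- paste(vapply(seq_len(n_tm), function(i)
      paste0(rand_tm(), rand_bg(12)), character(1)), collapse = "")
    s <- paste0(rand_bg(sample(30:60, 1)), tm,
                VOLTAGE_CLC_CONSENSUS, rand_bg(10),
                "G", sel, "GIPE", rand_bg(12),
                "GK", gat, "GPAVH", rand_bg(12),
                "PLRGGLF", rand_bg(3), pro, rand_bg(15),
                CBS_CONSENSUS, rand_bg(8), CBS_CONSENSUS, rand_bg(20))
    # accept only when the leftmost match of every region pattern is the
    # planted copy (spurious earlier matches would corrupt the labels)
    pats <- region_patterns()
    okI <- regexpr(pattern_regex(pats$I$pattern), s)[1] ==
      regexpr(paste0("G", sel, "GIPE"), s, fixed = TRUE)[1]
    okII <- regexpr(pattern_regex(pats$II$pattern), s)[1] ==
      regexpr(paste0("GK", gat, "GPAVH"), s, fixed = TRUE)[1]
    okIII <- regexpr(pattern_regex(pats$III$pattern), s)[1] ==
      regexpr("PLRGGLF", s, fixed = TRUE)[1]
    if (okI && okII && okIII) return(s)
  }
  stop("could not plant an unambiguous true gene in 100 attempts")
}

#' Simulate a proteome with planted CLC genes among decoys
#'
#' True genes carry the packaged Voltage_CLC consensus, two CBS consensus
#' copies, the three conserved regions with the labelled key residues and
#' `n_tm` hydrophobic blocks. Decoys carry at most partial signals (CBS
#' only, a single conserved region, or plain background). Reproducible per
#' seed.
#'
#' @param spec a [proteome_spec()].
#' @return list with `proteins` (a [protein_set()]) and `manifest`
#'   (data.frame of per-protein truth: kind, selectivity, glutamate flags,
#'   transport class).
#' @export
simulate_proteome <- function(spec = proteome_spec()) {
  stopifnot(inherits(spec, "proteome_spec"))
  withr_seed(spec$seed, {
    ids <- character(0); seqs <- character(0); man <- NULL
    if (spec$n_true > 0) {
      for (i in seq_len(spec$n_true)) {
        lab <- spec$labels[i, , drop = FALSE]
        ids <- c(ids, sprintf("TRUE%03d", i))
        seqs <- c(seqs, planted_true_gene(lab, spec$n_tm))
        sel <- switch(lab$selectivity_residue, P = "NO3-", S = "Cl-", "unknown")
        cls <- if (lab$gating && lab$proton) "antiporter" else "channel"
        man <- rbind(man, data.frame(
          id = sprintf("TRUE%03d", i), kind = "true",
          selectivity_residue = lab$selectivity_residue, selectivity = sel,
          gating_glutamate = ifelse(lab$gating, "present", "absent"),
          proton_glutamate = ifelse(lab$proton, "present", "absent"),
          transport_class = cls, stringsAsFactors = FALSE))
      }
    }
    if (spec$n_decoy > 0) {
      for (i in seq_len(spec$n_decoy)) {
        kind <- c("cbs_only", "single_region", "background")[1 + (i %% 3)]
        s <- switch(kind,
          cbs_only = paste0(rand_bg(150), CBS_CONSENSUS, rand_bg(8),
                            CBS_CONSENSUS, rand_bg(60)),
          single_region = paste0(rand_bg(120), "GSGIPE", rand_bg(160)),
          background = rand_bg(sample(250:500, 1)))
        ids <- c(ids, sprintf("DECOY%03d", i))
        seqs <- c(seqs, s)
        man <- rbind(man, data.frame(
          id = sprintf("DECOY%03d", i), kind = "decoy",
          selectivity_residue = NA_character_, selectivity = NA_character_,
          gating_glutamate = NA_character_, proton_glutamate = NA_character_,
          transport_class = NA_character_, stringsAsFactors = FALSE))
      }
    }
    list(proteins = protein_set(ids, seqs, species = "synthetic"),
         manifest = man)
  })
}

# ---- duplication-loss gene-tree simulator ----------------------------------

#' Specification for a duplication-loss gene-tree simulation
#'
#' @param species_tree rooted binary ape `phylo` WITH branch lengths.
#' @param dup_rate,loss_rate events per branch-length unit, >= 0.
#' @param n_root_duplications duplications forced at the species root
#'   before evolution starts (e.g. 1 plants one ancestral duplication).
#' @param seed RNG seed.
#' @return A `duploss_spec` list.
#' @export
duploss_spec <- function(species_tree = default_species_tree(),
                         dup_rate = 0.1, loss_rate = 0.05,
                         n_root_duplications = 0L, seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"),
            dup_rate >= 0, loss_rate >= 0, n_root_duplications >= 0)
  if (is.null(species_tree$edge.length))
    stop("species tree must have branch lengths (rates are per unit length)")
  structure(list(species_tree = species_tree, dup_rate = dup_rate,
                 loss_rate = loss_rate,
                 n_root_duplications = as.integer(n_root_duplications),
                 seed = as.integer(seed)),
            class = "duploss_spec")
}

#' Simulate gene-family evolution by duplication and loss
#'
#' A birth-death process along the species tree: each gene lineage on a
#' branch experiences Poisson duplication/loss events at the given rates;
#' lineages surviving to a species leaf become extant genes. The manifest
#' records both the full event history and the OBSERVABLE history (events
#' recoverable from the pruned gene tree): a duplication is observable iff
#' both copies leave extant descendants; a loss is observable iff it roots
#' a maximal extinct subtree whose sister lineage at the branching point
#' survives and the branching is a speciation.
#'
#' @param spec a [duploss_spec()].
#' @return list with `gene_tree` (rooted binary ape `phylo`, `NULL` when
#'   fewer than 2 genes survive), `leaf_map`, and `manifest` (list with
#'   `all_duplications`, `all_losses`, `observable_duplications`,
#'   `observable_losses`, `identifiable` -- whether parsimony can recover
#'   the observable history exactly -- and `n_extant`).
#' @export
simulate_duploss_gene_tree <- function(spec = duploss_spec()) {
  stopifnot(inherits(spec, "duploss_spec"))
  st <- spec$species_tree
  ntip <- ape::Ntip(st)
  kids <- function(v) st$edge[st$edge[, 1] == v, 2]
  blen <- function(v) st$edge.length[st$edge[, 2] == v]
  counter <- new.env()
  counter$extant <- 0L; counter$dups <- 0L; counter$losses <- 0L

  withr_seed(spec$seed, {
    # evolve a lineage from the TOP of the branch leading into species
    # node v (t = remaining length); returns a node list or NULL (extinct)
    evolve_branch <- function(v, t) {
      total <- spec$dup_rate + spec$loss_rate
      while (TRUE) {
        w <- if (total > 0) stats::rexp(1, total) else Inf
        if (w >= t) break
        t <- t - w
        if (stats::runif(1) < spec$dup_rate / total) {
          counter$dups <- counter$dups + 1L
          a <- evolve_branch(v, t)
          b <- evolve_branch(v, t)
          return(list(type = "dup", loc = v, children = list(a, b)))
        } else {
          counter$losses <- counter$losses + 1L
          return(NULL)  # extinct lineage: unobservable by construction
        }
      }
      at_node(v)
    }
    # lineage sitting AT species node v (leaf -> extant; else speciation)
    at_node <- function(v) {
      if (v <= ntip) {
        counter$extant <- counter$extant + 1L
        return(list(type = "tip", loc = v, species = st$tip.label[v]))
      }
      ch <- kids(v)
      list(type = "spec", loc = v,
           children = list(evolve_branch(ch[1], blen(ch[1])),
                           evolve_branch(ch[2], blen(ch[2]))))
    }
    root <- ntip + 1L
    lineages <- list(at_node(root))
    if (spec$n_root_duplications > 0) {
      for (i in seq_len(spec$n_root_duplications)) {
        counter$dups <- counter$dups + 1L
        lineages <- c(lineages, list(at_node(root)))
      }
    }
    tree0 <- if (length(lineages) == 1L) lineages[[1]]
             else Reduce(function(a, b)
               list(type = "dup", loc = root, children = list(a, b)),
               lineages)

    # Prune extinct subtrees and count OBSERVABLE events. A suppressed
    # speciation (one side extinct) yields a candidate loss, but it only
    # becomes observable once a binary node survives below it in the
    # pruned tree ("pending" losses above the final root are invisible to
    # reconciliation and are dropped). Suppressed duplications leave no
    # trace at all.
    obs <- new.env(); obs$dups <- 0L; obs$losses <- 0L
    prune <- function(node) {
      # returns list(node = pruned subtree or NULL, pending = losses on
      # the unifurcating chain above the returned subtree)
      if (is.null(node)) return(list(node = NULL, pending = 0L))
      if (node$type == "tip") return(list(node = node, pending = 0L))
      a <- prune(node$children[[1]])
      b <- prune(node$children[[2]])
      if (is.null(a$node) && is.null(b$node))
        return(list(node = NULL, pending = 0L))
      if (is.null(a$node) || is.null(b$node)) {
        kept <- if (is.null(a$node)) b else a
        pend <- kept$pending + if (node$type == "spec") 1L else 0L
        return(list(node = kept$node, pending = pend))
      }
      # binary node survives: pending losses below it become observable
      obs$losses <- obs$losses + a$pending + b$pending
      if (node$type == "dup") obs$dups <- obs$dups + 1L
      list(node = list(type = node$type, loc = node$loc,
                       children = list(a$node, b$node)),
           pending = 0L)
    }
    pruned <- prune(tree0)$node

    # Identifiability: reconciliation can recover the observable history
    # exactly iff every surviving duplication keeps at least one copy
    # whose descendant-species LCA still equals the duplication's true
    # species location. Copies that lose complementary clades pull the
    # parsimony mapping below the true location and hide events.
    sp_parent <- tree_parents(st); sp_depth <- tree_depths(st)
    identifiable <- TRUE
    lca_map <- function(node) {
      if (node$type == "tip") return(node$loc)
      ms <- vapply(node$children, lca_map, integer(1))
      if (node$type == "dup" && !any(ms == node$loc)) identifiable <<- FALSE
      tree_lca(sp_parent, sp_depth, ms)
    }
    if (!is.null(pruned) && pruned$type != "tip") invisible(lca_map(pruned))

    # convert to Newick with per-species copy numbering in tree order
    copy_n <- new.env()
    to_newick <- function(node) {
      if (node$type == "tip") {
        k <- (if (is.null(copy_n[[node$species]])) 0L else copy_n[[node$species]]) + 1L
        copy_n[[node$species]] <- k
        return(paste0(node$species, "_g", k))
      }
      paste0("(", to_newick(node$children[[1]]), ",",
             to_newick(node$children[[2]]), ")")
    }
    gene_tree <- NULL; leaf_map <- character(0)
    if (!is.null(pruned) && counter$extant >= 2L && pruned$type != "tip") {
      gene_tree <- ape::read.tree(text = paste0(to_newick(pruned), ";"))
      leaf_map <- setNames(sub("_g\\d+$", "", gene_tree$tip.label),
                           gene_tree$tip.label)
    }
    list(gene_tree = gene_tree, leaf_map = leaf_map,
         manifest = list(all_duplications = counter$dups,
                         all_losses = counter$losses,
                         observable_duplications = obs$dups,
                         observable_losses = obs$losses,
                         identifiable = identifiable,
                         n_extant = counter$extant))
  })
}

# ---- expression / measurement simulators -----------------------------------

#' Specification for a synthetic qPCR Ct table
#'
#' @param genes target gene names.
#' @param tissues tissue names.
#' @param treatments treatment levels (mM NaCl); the first is the
#'   calibrator.
#' @param log2fold array/vector of true log2 fold changes vs calibrator,
#'   indexed `[gene, tissue, treatment]`; a single number plants that fold
#'   for every non-calibrator cell.
#' @param reference_gene reference gene name (constant in expectation).
#' @param base_ct expected target-gene calibrator Ct.
#' @param ref_ct expected reference-gene Ct.
#' @param sigma_ct per-well Gaussian noise SD on the Ct scale (cycles).
#' @param n_biorep,n_techrep replicate counts (>= 1).
#' @param seed RNG seed.
#' @return An `expression_spec` list.
#' @export
expression_spec <- function(genes = paste0("PgCLC-", c("B", "C1", "C2", "D", "E", "F", "G")),
                            tissues = c("root", "leaf"),
                            treatments = c(0, 100, 200, 300),
                            log2fold = 2, reference_gene = "PgActin",
                            base_ct = 24, ref_ct = 20, sigma_ct = 0.2,
                            n_biorep = 3L, n_techrep = 3L, seed = 1L) {
  if (n_biorep < 1 || n_techrep < 1) stop("replicate counts must be >= 1")
  if (sigma_ct < 0) stop("sigma_ct must be >= 0")
  lf <- array(0, dim = c(length(genes), length(tissues), length(treatments)),
              dimnames = list(genes, tissues, treatments))
  if (length(log2fold) == 1L) {
    lf[, , -1] <- log2fold
  } else lf[] <- log2fold
  lf[, , 1] <- 0  # calibrator defines the baseline
  structure(list(genes = genes, tissues = tissues, treatments = treatments,
                 log2fold = lf, reference_gene = reference_gene,
                 base_ct = base_ct, ref_ct = ref_ct, sigma_ct = sigma_ct,
                 n_biorep = as.integer(n_biorep),
                 n_techrep = as.integer(n_techrep), seed = as.integer(seed)),
            class = "expression_spec")
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Target Ct = `base_ct` - log2fold + biological noise; the reference gene
#' sits at `ref_ct` in expectation. Noise is Gaussian on the Ct scale,
#' independent per well.
#'
#' @param spec an [expression_spec()].
#' @return list with `ct` (a Ct table data.frame) and `manifest`
#'   (data.frame of true fold changes per gene x tissue x treatment).
#' @export
simulate_ct_table <- function(spec = expression_spec()) {
  stopifnot(inherits(spec, "expression_spec"))
  withr_seed(spec$seed, {
    rows <- list(); man <- list(); k <- 0L
    for (ti in seq_along(spec$tissues)) for (tr in seq_along(spec$treatments)) {
      for (g in c(spec$genes, spec$reference_gene)) {
        is_ref <- g == spec$reference_gene
        mu <- if (is_ref) spec$ref_ct
              else spec$base_ct - spec$log2fold[g, ti, tr]
        for (b in seq_len(spec$n_biorep)) for (tech in seq_len(spec$n_techrep)) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            gene = g, tissue = spec$tissues[ti],
            treatment_mM = spec$treatments[tr], biorep = b, techrep = tech,
            ct = stats::rnorm(1, mu, spec$sigma_ct), stringsAsFactors = FALSE)
        }
        if (!is_ref)
          man[[length(man) + 1L]] <- data.frame(
            gene = g, tissue = spec$tissues[ti],
            treatment_mM = spec$treatments[tr],
            true_log2fold = spec$log2fold[g, ti, tr],
            true_fold = 2^spec$log2fold[g, ti, tr], stringsAsFactors = FALSE)
      }
    }
    list(ct = do.call(rbind, rows), manifest = do.call(rbind, man))
  })
}

#' Simulate an anion/measurement table with stated trend shapes
#'
#' Supported per-variable-by-tissue profiles: `increasing` (monotone rise
#' with treatment), `hump` (peak at the second level, mirroring anions
#' that peak at 100 mM), `decreasing`, and `flat`. Values are Gaussian
#' around the profile means with a constant coefficient of variation.
#'
#' @param variables named list: variable -> named character vector of
#'   profiles per tissue (recycled over tissues when a single string).
#' @param tissues tissue names.
#' @param treatments treatment levels, first = control.
#' @param base_mean control-level mean (measurement units, e.g. mg/g DW).
#' @param cv coefficient of variation of the noise.
#' @param n_rep replicates per cell.
#' @param seed RNG seed.
#' @return list with `measurements` (data.frame) and `manifest` (true cell
#'   means).
#' @export
simulate_measurement_table <- function(
    variables = list("Cl" = "increasing", "NO3" = "hump",
                     "H2PO4" = "increasing", "SO4" = "hump"),
    tissues = c("root", "stem", "leaf"),
    treatments = c(0, 100, 200, 300),
    base_mean = 10, cv = 0.08, n_rep = 3L, seed = 1L) {
  if (n_rep < 1) stop("n_rep must be >= 1")
  prof_mult <- list(increasing = c(1, 2.5, 4.5, 6.2),
                    hump = c(1, 1.8, 1.3, 0.7),
                    decreasing = c(1, 0.8, 0.55, 0.35),
                    flat = c(1, 1, 1, 1))
  withr_seed(seed, {
    rows <- list(); man <- list()
    for (v in names(variables)) {
      profs <- rep_len(variables[[v]], length(tissues))
      for (ti in seq_along(tissues)) {
        mult <- rep_len(prof_mult[[profs[ti]]], length(treatments))
        for (tr in seq_along(treatments)) {
          mu <- base_mean * mult[tr]
          vals <- stats::rnorm(n_rep, mu, cv * mu)
          rows[[length(rows) + 1L]] <- data.frame(
            tissue = tissues[ti], treatment_mM = treatments[tr],
            rep = seq_len(n_rep), variable = v, value = vals,
            stringsAsFactors = FALSE)
          man[[length(man) + 1L]] <- data.frame(
            tissue = tissues[ti], treatment_mM = treatments[tr],
            variable = v, profile = profs[ti], true_mean = mu,
            stringsAsFactors = FALSE)
        }
      }
    }
    list(measurements = do.call(rbind, rows), manifest = do.call(rbind, man))
  })
}
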