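# Pipeline orchestration: structured config, validation, staged execution
# with logging, and a consolidated plain-text report.

#' Read a pipeline configuration file
#'
#' Flat `key: value` text (Debian-control layout, one record). Unknown
#' keys are kept; [validate_config()] checks the known ones.
#'
#' @param path config file path.
#' @return A named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  m <- read.dcf(path)
  cfg <- as.list(m[1, ])
  numeric_keys <- c("e_cutoff", "alpha", "proton_offset", "seed",
                    "min_ident_fraction", "max_gap_fraction",
                    "min_block_length")
  for (k in intersect(names(cfg), numeric_keys))
    cfg[[k]] <- as.numeric(cfg[[k]])
  logical_keys <- c("times_means_increment", "try_all_rootings")
  for (k in intersect(names(cfg), logical_keys))
    cfg[[k]] <- toupper(cfg[[k]]) %in% c("TRUE", "YES", "1")
  structure(cfg, class = "pipeline_config")
}

#' Build a pipeline configuration in code
#' @param ... config entries (see [validate_config()] for the known keys).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  structure(list(...), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Collects every problem rather than stopping at the first; an empty
#' return means the config is runnable.
#'
#' @param config a `pipeline_config`.
#' @return Character vector of problems (length 0 when valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  if (is.null(config$fasta))
    problems <- c(problems, "missing required key: fasta")
  for (k in c("fasta", "domtbl", "gene_tree", "species_tree", "leaf_map",
              "ct_table", "measurement_table", "alignment")) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      problems <- c(problems, paste0(k, ": file not found: ", config[[k]]))
  }
  if (!is.null(config$e_cutoff) &&
      (!is.finite(config$e_cutoff) || config$e_cutoff <= 0))
    problems <- c(problems, "e_cutoff must be > 0")
  if (!is.null(config$alpha) &&
      (!is.finite(config$alpha) || config$alpha <= 0 || config$alpha >= 1))
    problems <- c(problems, "alpha must be in (0, 1)")
  if (!is.null(config$proton_offset) &&
      (config$proton_offset < 1 || config$proton_offset != round(config$proton_offset)))
    problems <- c(problems, "proton_offset must be a positive integer")
  if (is.null(config$out_dir))
    problems <- c(problems, "missing required key: out_dir")
  problems
}

pipeline_log <- function(level, config, ...) {
  levels <- c(debug = 1, info = 2, warn = 3)
  want <- config$log_level
  if (is.null(want)) want <- "info"
  if (levels[[level]] >= levels[[want]])
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: identify, properties, classify, then
#' (when their inputs are configured) reconciliation, expression
#' statistics, anion statistics and the correlation matrix. Stages with
#' missing optional inputs are skipped with a logged notice. All tables
#' are written as tab-delimited text under `out_dir`, together with a
#' provenance block recording every parameter, the seed and input
#' checksums. Identical config and seed give identical reports.
#'
#' @param config a `pipeline_config` (validated first; any problem
#'   aborts).
#' @return A `pipeline_report` list with the computed tables.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  e_cutoff <- if (is.null(config$e_cutoff)) E_CUTOFF_DEFAULT else config$e_cutoff
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  proton_offset <- if (is.null(config$proton_offset)) 4L else as.integer(config$proton_offset)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  report <- list()

  # -- identification --------------------------------------------------------
  pipeline_log("info", config, "stage identify: ", config$fasta)
  proteins <- tryCatch(read_fasta(config$fasta),
                       error = function(e) stop("stage identify: ", conditionMessage(e)))
  hits <- NULL
  if (!is.null(config$domtbl)) hits <- parse_domtblout(config$domtbl)
  candidates <- identify_candidates(proteins, hits = hits, e_cutoff = e_cutoff)
  write_candidate_table(candidates, file.path(out_dir, "candidates.tsv"))
  report$candidates <- candidates
  passed <- candidates[candidates$passed, , drop = FALSE]

  # -- properties ------------------------------------------------------------
  pipeline_log("info", config, "stage properties: ", nrow(passed), " candidates")
  report$properties <- property_table(passed)
  write_property_table(report$properties, file.path(out_dir, "properties.tsv"))

  # -- classification --------------------------------------------------------
  pipeline_log("info", config, "stage classify")
  report$classification <- classify_proteins(passed, proton_offset = proton_offset)
  write_classification_table(report$classification,
                             file.path(out_dir, "classification.tsv"))

  # -- reconciliation --------------------------------------------------------
  if (!is.null(config$gene_tree) && !is.null(config$species_tree) &&
      !is.null(config$leaf_map)) {
    pipeline_log("info", config, "stage reconcile")
    gt <- parse_newick(readLines(config$gene_tree, warn = FALSE)[1])
    st <- parse_newick(readLines(config$species_tree, warn = FALSE)[1])
    lm <- read.delim(config$leaf_map, header = FALSE,
                     col.names = c("gene", "species"),
                     stringsAsFactors = FALSE)
    rec <- lca_reconcile(gt, st, setNames(lm$species, lm$gene),
                         try_all_rootings = isTRUE(config$try_all_rootings))
    report$reconciliation <- rec
    write.table(rec$events, file.path(out_dir, "reconciliation_events.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(paste("total_duplications", rec$total_duplications, sep = "\t"),
                 paste("total_losses", rec$total_losses, sep = "\t")),
               file.path(out_dir, "reconciliation_totals.tsv"))
  } else pipeline_log("info", config, "stage reconcile skipped (no trees configured)")

  # -- expression statistics -------------------------------------------------
  if (!is.null(config$ct_table)) {
    pipeline_log("info", config, "stage expression")
    ct <- read_ct_table(config$ct_table)
    ref <- if (is.null(config$reference_gene)) "PgActin" else config$reference_gene
    genes <- setdiff(unique(ct$gene), ref)
    cells <- unique(ct[, c("tissue", "treatment_mM")])
    rows <- list()
    for (g in genes) for (i in seq_len(nrow(cells))) {
      fc <- ddct_fold_change(ct, g, cells$tissue[i], cells$treatment_mM[i],
                             reference_gene = ref)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, tissue = cells$tissue[i],
        treatment_mM = cells$treatment_mM[i],
        fold = fc$fold, se = fc$se, stringsAsFactors = FALSE)
    }
    expr <- do.call(rbind, rows)
    # per-panel (gene x tissue) ANOVA + letters over treatment levels
    letters_rows <- list()
    for (g in genes) for (ti in unique(expr$tissue)) {
      lv <- sort(unique(ct$treatment_mM))
      grp <- lapply(lv, function(tr)
        ddct_fold_change(ct, g, ti, tr, reference_gene = ref)$replicate_folds)
      names(grp) <- lv
      gs <- group_stats(grp, alpha)
      letters_rows[[length(letters_rows) + 1L]] <- data.frame(
        gene = g, tissue = ti, treatment_mM = lv,
        mean_fold = unname(gs$means), letter = unname(gs$letters),
        p_anova = gs$anova$p, stringsAsFactors = FALSE)
    }
    report$expression <- expr
    report$expression_letters <- do.call(rbind, letters_rows)
    write.table(expr, file.path(out_dir, "expression_folds.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(report$expression_letters,
                file.path(out_dir, "expression_letters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else pipeline_log("info", config, "stage expression skipped (no ct_table)")

  # -- anion statistics ------------------------------------------------------
  if (!is.null(config$measurement_table)) {
    pipeline_log("info", config, "stage anion stats")
    meas <- read_measurement_table(config$measurement_table)
    rows <- list()
    for (v in unique(meas$variable)) for (ti in unique(meas$tissue)) {
      sub <- meas[meas$variable == v & meas$tissue == ti, , drop = FALSE]
      lv <- sort(unique(sub$treatment_mM))
      grp <- lapply(lv, function(tr) sub$value[sub$treatment_mM == tr])
      names(grp) <- lv
      gs <- group_stats(grp, alpha)
      ctrl <- lv[1]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, tissue = ti, treatment_mM = lv,
        mean = unname(gs$means), se = unname(gs$se),
        letter = unname(gs$letters),
        fold_vs_control = vapply(lv, function(tr)
          fold_vs_control(meas, v, ti, tr, control = ctrl,
                          times_means_increment = isTRUE(config$times_means_increment)),
          numeric(1)),
        p_anova = gs$anova$p, stringsAsFactors = FALSE)
    }
    report$anion_stats <- do.call(rbind, rows)
    write.table(report$anion_stats, file.path(out_dir, "anion_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    # correlation across aligned (tissue, treatment, rep) samples
    wide <- stats::reshape(meas, direction = "wide",
                           idvar = c("tissue", "treatment_mM", "rep"),
                           timevar = "variable")
    value_cols <- grep("^value\\.", names(wide))
    names(wide)[value_cols] <- sub("^value\\.", "", names(wide)[value_cols])
    mat <- wide[, -(1:3), drop = FALSE]
    if (ncol(mat) >= 2 && nrow(mat) >= 3) {
      report$correlation <- correlation_matrix(mat)
      write_correlation(report$correlation,
                        file.path(out_dir, "correlation_square.tsv"),
                        file.path(out_dir, "correlation_long.tsv"))
    }
  } else pipeline_log("info", config, "stage anion stats skipped (no measurement_table)")

  # -- provenance ------------------------------------------------------------
  inputs <- unlist(config[c("fasta", "domtbl", "gene_tree", "species_tree",
                            "leaf_map", "ct_table", "measurement_table")])
  prov <- c(
    paste0("package_version\t", as.character(utils::packageVersion("clcfamily"))),
    paste0("seed\t", seed),
    paste0("e_cutoff\t", format(e_cutoff)),
    paste0("alpha\t", alpha),
    paste0("proton_offset\t", proton_offset),
    paste0("times_means_increment\t", isTRUE(config$times_means_increment)),
    vapply(names(inputs), function(k)
      paste0("md5_", k, "\t", unname(tools::md5sum(inputs[[k]]))), character(1)))
  writeLines(prov, file.path(out_dir, "provenance.tsv"))
  report$provenance <- prov
  class(report) <- "pipeline_report"
  pipeline_log("info", config, "pipeline complete: ", out_dir)
  invisible(report)
}

# ---- command-line interface ------------------------------------------------

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- sub("^--", "", args[i])
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        out[[gsub("-", "_", key)]] <- args[i + 1L]; i <- i + 2L
      } else { out[[gsub("-", "_", key)]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands. Run via
#' `Rscript -e 'clcfamily::clc_cli()' <subcommand> --flag value ...`.
#' Subcommands: `identify`, `properties`, `classify`, `blockfilter`,
#' `reconcile`, `expression`, `anova`, `correlate`, `simulate`, `run`.
#'
#' @param args character vector of arguments (default: the command line).
#' @return invisibly, the subcommand's main result.
#' @export
clc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: clc_cli <subcommand> [--flag value ...]")
  cmd <- args[1]
  opt <- cli_args_to_list(args[-1])
  outdir <- function() { d <- opt$out; if (is.null(d)) d <- "."; dir.create(d, showWarnings = FALSE, recursive = TRUE); d }
  res <- switch(cmd,
    identify = {
      pr <- read_fasta(opt$fasta)
      hits <- if (!is.null(opt$domtbl)) parse_domtblout(opt$domtbl) else NULL
      ec <- if (!is.null(opt$e_cutoff)) as.numeric(opt$e_cutoff) else E_CUTOFF_DEFAULT
      cand <- identify_candidates(pr, hits = hits, e_cutoff = ec)
      write_candidate_table(cand, file.path(outdir(), "candidates.tsv"))
      cand
    },
    properties = {
      pr <- read_fasta(opt$fasta)
      tab <- property_table(pr)
      write_property_table(tab, if (!is.null(opt$out)) opt$out else "properties.tsv")
      tab
    },
    classify = {
      pr <- read_fasta(opt$fasta)
      tab <- classify_proteins(pr)
      write_classification_table(tab, if (!is.null(opt$out)) opt$out else "classification.tsv")
      tab
    },
    blockfilter = {
      aln <- read_alignment(opt$aln)
      flt <- conserved_block_filter(aln)
      con <- file(if (!is.null(opt$out)) opt$out else "filtered.fasta", "w")
      for (i in seq_along(flt$ids))
        writeLines(c(paste0(">", flt$ids[i]), flt$seqs[i]), con)
      close(con)
      flt
    },
    reconcile = {
      gt <- parse_newick(readLines(opt$gene_tree, warn = FALSE)[1])
      st <- parse_newick(readLines(opt$species_tree, warn = FALSE)[1])
      lm <- read.delim(opt$map, header = FALSE,
                       col.names = c("gene", "species"), stringsAsFactors = FALSE)
      rec <- lca_reconcile(gt, st, setNames(lm$species, lm$gene))
      write.table(rec$events, file.path(outdir(), "reconciliation_events.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      rec
    },
    expression = {
      ct <- read_ct_table(opt$ct)
      ref <- if (!is.null(opt$ref)) opt$ref else "PgActin"
      cfg <- pipeline_config(fasta = NULL, ct_table = opt$ct,
                             reference_gene = ref, out_dir = outdir())
      genes <- setdiff(unique(ct$gene), ref)
      rows <- list()
      for (g in genes) for (ti in unique(ct$tissue))
        for (tr in unique(ct$treatment_mM)) {
          fc <- ddct_fold_change(ct, g, ti, tr, reference_gene = ref)
          rows[[length(rows) + 1L]] <- data.frame(gene = g, tissue = ti,
            treatment_mM = tr, fold = fc$fold, se = fc$se)
        }
      tab <- do.call(rbind, rows)
      write.table(tab, file.path(outdir(), "expression_folds.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    },
    anova = {
      meas <- read_measurement_table(opt$table)
      rows <- list()
      for (v in unique(meas$variable)) for (ti in unique(meas$tissue)) {
        sub <- meas[meas$variable == v & meas$tissue == ti, ]
        grp <- split(sub$value, sub$treatment_mM)
        gs <- group_stats(grp)
        rows[[length(rows) + 1L]] <- data.frame(variable = v, tissue = ti,
          treatment_mM = names(grp), mean = unname(gs$means),
          letter = unname(gs$letters), p_anova = gs$anova$p)
      }
      tab <- do.call(rbind, rows)
      write.table(tab, file.path(outdir(), "anova_letters.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    },
    correlate = {
      meas <- read_measurement_table(opt$table)
      wide <- stats::reshape(meas, direction = "wide",
                             idvar = c("tissue", "treatment_mM", "rep"),
                             timevar = "variable")
      names(wide) <- sub("^value\\.", "", names(wide))
      cm <- correlation_matrix(wide[, -(1:3), drop = FALSE])
      write_correlation(cm, file.path(outdir(), "correlation_square.tsv"),
                        file.path(outdir(), "correlation_long.tsv"))
      cm
    },
    simulate = {
      what <- args[2]
      seed <- if (!is.null(opt$seed)) as.integer(opt$seed) else 1L
      if (what == "proteome") {
        sim <- simulate_proteome(proteome_spec(seed = seed))
        write_fasta(sim$proteins, file.path(outdir(), "proteome.fasta"))
        write.table(sim$manifest, file.path(outdir(), "manifest.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        sim
      } else if (what == "genetree") {
        sim <- simulate_duploss_gene_tree(duploss_spec(seed = seed))
        if (!is.null(sim$gene_tree))
          write_newick(sim$gene_tree, file.path(outdir(), "gene_tree.nwk"))
        writeLines(paste(names(unlist(sim$manifest)), unlist(sim$manifest),
                         sep = "\t"), file.path(outdir(), "manifest.tsv"))
        sim
      } else if (what == "expression") {
        sim <- simulate_ct_table(expression_spec(seed = seed))
        write.table(sim$ct, file.path(outdir(), "ct_table.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(sim$manifest, file.path(outdir(), "manifest.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        sim
      } else stop("unknown simulate target: ", what)
    },
    run = {
      cfg <- read_pipeline_config(opt$config)
      run_pipeline(cfg)
    },
    stop("unknown subcommand: ", cmd))
  invisible(res)
}
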