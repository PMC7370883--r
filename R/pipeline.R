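#' Pipeline configuration
#'
#' Collects every tunable threshold of the caller with its default. A
#' configuration is echoed verbatim (as YAML) into every output directory so
#' a run can be reproduced from its outputs alone.
#'
#' @param counts,gene_map,cell_meta,allele_counts input file paths (allele
#'   counts may be `NULL` for expression-only runs).
#' @param fdr_level nominal FDR at each tree level; default 0.01.
#' @param effect_threshold dosage effect-size gate; default 0.2.
#' @param cell_depth_quantile depth QC quantile; default 0.10.
#' @param min_median_cpm per-stratum gene filter; default 50 CPM.
#' @param min_genes minimum retained genes per stratum; default 2000.
#' @param min_genes_per_chrom minimum genes per chromosome score; default 25.
#' @param min_reads,min_snps allelic coverage floors; defaults 20 and 5.
#' @param meiotic_cutoff,meiotic_criterion origin-classification rule;
#'   defaults 0.75 and `"fraction_75"`.
#' @param seed integer seed.
#' @return list of class `mosaiscan_config`.
#' @export
pipeline_config <- function(counts = NULL, gene_map = NULL, cell_meta = NULL,
                            allele_counts = NULL, fdr_level = 0.01,
                            effect_threshold = 0.2,
                            cell_depth_quantile = 0.10, min_median_cpm = 50,
                            min_genes = 2000, min_genes_per_chrom = 25,
                            min_reads = 20, min_snps = 5,
                            meiotic_cutoff = 0.75,
                            meiotic_criterion = "fraction_75", seed = 1L) {
  stopifnot(fdr_level > 0, fdr_level < 1, effect_threshold >= 0,
            cell_depth_quantile > 0, cell_depth_quantile <= 0.5,
            meiotic_cutoff > 0, meiotic_cutoff <= 1,
            meiotic_criterion %in% c("fraction_75", "lt2_normal"))
  structure(as.list(environment()), class = "mosaiscan_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @return a `mosaiscan_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full calling pipeline on input files
#'
#' QC, expression and allelic signals, effect-size gating, Fisher
#' combination, hierarchical FDR selection, monosomy/trisomy labeling and
#' meiotic/mitotic origin classification, with all intermediate tables
#' written to `out_dir` as TSV, a JSON selection report, the echoed config
#' as YAML, and a timestamped log.
#'
#' @param config a `mosaiscan_config` with input paths set, or a path to a
#'   YAML file readable by [read_pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with `qc`, `signals`, `selection`, `calls`,
#'   `classification`, `summary`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "mosaiscan_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(stage, msg) {
    cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " [", stage, "] ", msg,
        "\n", sep = "", file = logf, append = TRUE)
  }
  set.seed(config$seed)
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))],
                   file.path(out_dir, "config.yaml"))

  inp <- read_counts(config$counts, config$gene_map, config$cell_meta)
  log_line("input", paste(nrow(inp$counts), "genes,",
                          ncol(inp$counts), "cells read"))
  qc <- run_qc(inp$counts, inp$gene_map, inp$meta,
               depth_quantile = config$cell_depth_quantile,
               min_median_cpm = config$min_median_cpm,
               min_genes = config$min_genes)
  log_line("qc", paste(nrow(qc$meta), "cells retained;",
                       sum(qc$strata$pass), "of", nrow(qc$strata),
                       "strata pass"))
  write_tsv(qc$strata, file.path(out_dir, "qc_strata.tsv"))
  write_tsv(data.frame(cell_id = qc$meta$cell_id),
            file.path(out_dir, "retained_cells.tsv"))

  expr <- expression_signal(qc, config$min_genes_per_chrom)
  log_line("expression", paste(nrow(expr), "cell-chromosome scores"))
  ai <- NULL
  if (!is.null(config$allele_counts)) {
    ai <- allelic_signal(read_allele_counts(config$allele_counts),
                         config$min_reads, config$min_snps)
    log_line("allelic", paste(nrow(ai), "cell-chromosome ratios"))
  } else {
    log_line("allelic", "no allele counts supplied: expression-only mode")
  }

  leaves <- omnibus_table(qc$meta, expr, ai, config$effect_threshold)
  sel <- treebh_select(leaves, config$fdr_level)
  log_line("select", paste(sum(sel$leaves$rejected_leaf), "of",
                           nrow(sel$leaves), "leaves rejected"))
  calls <- assign_ploidy_type(
    sel$leaves[sel$leaves$rejected_leaf, , drop = FALSE])
  out_leaves <- sel$leaves
  if (is.null(ai)) # expression-only: allelic columns are absent, not NA
    out_leaves <- out_leaves[, setdiff(names(out_leaves),
                                       c("ai_ratio", "z_ai", "p_ai"))]
  write_tsv(out_leaves, file.path(out_dir, "signals.tsv"))
  write_tsv(calls, file.path(out_dir, "calls.tsv"))

  cls <- classify_embryo_errors(calls, qc$meta,
                                cutoff = config$meiotic_cutoff,
                                criterion = config$meiotic_criterion)
  write_tsv(cls$embryos, file.path(out_dir, "classifications.tsv"))
  if (!is.null(cls$events))
    write_tsv(cls$events, file.path(out_dir, "events.tsv"))
  log_line("classify", paste(sum(cls$embryos$category != "euploid"),
                             "non-euploid embryos"))

  summary <- list(
    q = config$fdr_level,
    n_embryos = nrow(sel$embryos),
    n_embryos_aneuploid = sum(sel$embryos$rejected),
    n_cells = nrow(sel$cells),
    n_cells_aneuploid = sum(sel$cells$rejected),
    n_leaves = nrow(sel$leaves),
    n_leaves_aneuploid = sum(sel$leaves$rejected_leaf),
    embryo_categories = as.list(table(cls$embryos$category))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line("done", "pipeline complete")
  invisible(list(qc = qc, signals = leaves, selection = sel, calls = calls,
                 classification = cls, summary = summary))
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Counts as MatrixMarket with `genes.tsv`/`cells.tsv` sidecars, allele
#' counts as ASEReadCounter-style TSV, cell metadata and the truth table as
#' TSV, and the generating config as YAML.
#'
#' @param sim a `mosaiscan_sim` from [simulate_cohort()].
#' @param out_dir output directory.
#' @return (invisibly) named list of written paths.
#' @export
write_sim_inputs <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    counts = file.path(out_dir, "counts.mtx"),
    genes = file.path(out_dir, "genes.tsv"),
    cells = file.path(out_dir, "cells.tsv"),
    gene_map = file.path(out_dir, "gene_map.tsv"),
    cell_meta = file.path(out_dir, "cell_meta.tsv"),
    allele_counts = file.path(out_dir, "allele_counts.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    config = file.path(out_dir, "sim_config.yaml")
  )
  Matrix::writeMM(Matrix::Matrix(sim$counts, sparse = TRUE), paths$counts)
  writeLines(rownames(sim$counts), paths$genes)
  writeLines(colnames(sim$counts), paths$cells)
  write_tsv(sim$gene_map, paths$gene_map)
  write_tsv(sim$meta, paths$cell_meta)
  ase <- data.frame(
    cell_id = sim$allelic$cell_id, contig = sim$allelic$chromosome,
    position = sim$allelic$position, variantID = ".",
    refAllele = "A", altAllele = "G",
    refCount = sim$allelic$ref_count, altCount = sim$allelic$alt_count,
    totalCount = sim$allelic$ref_count + sim$allelic$alt_count
  )
  write_tsv(ase, paths$allele_counts)
  write_tsv(sim$truth, paths$truth)
  cfg <- unclass(sim$config)
  cfg$beta_params <- lapply(cfg$beta_params, as.list)
  yaml::write_yaml(cfg, paths$config)
  invisible(paths)
}
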