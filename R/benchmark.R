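#' Run the aneuploidy caller on a simulated cohort
#'
#' All cells form a single stratum (simulated cohorts share one stage and
#' cell type). The full caller is run: CPM normalization, per-stratum gene
#' filtering, dosage scores and expression p-values, allelic-imbalance
#' signal, effect-size gating, Fisher combination, hierarchical FDR
#' selection and monosomy/trisomy labeling.
#'
#' @param sim a `mosaiscan_sim` from [simulate_cohort()], or any list with
#'   `counts`, `gene_map`, `meta` and (for combined mode) `allelic`.
#' @param mode `"combined"` (default) or `"expression_only"` (the leaf
#'   p-value is the gated expression p alone).
#' @param fdr nominal FDR at each tree level; default 0.01.
#' @param effect_threshold dosage effect-size gate; default 0.2.
#' @param min_median_cpm,min_genes_per_chrom,min_reads,min_snps signal
#'   thresholds (see the signal modules).
#' @return list of class `mosaiscan_callset`: `leaves` (omnibus table with
#'   rejection flags), `calls` (rejected leaves with monosomy/trisomy
#'   labels), `selection` (the `mosaiscan_treebh` object), `mode`, `fdr`.
#' @export
run_caller <- function(sim, mode = c("combined", "expression_only"),
                       fdr = 0.01, effect_threshold = 0.2,
                       min_median_cpm = 50, min_genes_per_chrom = 25,
                       min_reads = 20, min_snps = 5) {
  mode <- match.arg(mode)
  cpm <- cpm_normalize(sim$counts)
  genes <- filter_genes_in_stratum(cpm, sim$meta$cell_id, min_median_cpm)
  expr <- dosage_scores(cpm, sim$meta$cell_id, sim$gene_map, genes = genes,
                        min_genes_per_chrom = min_genes_per_chrom)
  expr <- expression_pvalues(expr)
  ai <- NULL
  if (mode == "combined")
    ai <- allelic_signal(sim$allelic, min_reads, min_snps)
  leaves <- omnibus_table(sim$meta, expr, ai, effect_threshold)
  sel <- treebh_select(leaves, fdr)
  calls <- assign_ploidy_type(
    sel$leaves[sel$leaves$rejected_leaf, , drop = FALSE])
  structure(list(leaves = sel$leaves, calls = calls, selection = sel,
                 mode = mode, fdr = fdr), class = "mosaiscan_callset")
}

#' Score calls against the simulated truth
#'
#' Leaf-level confusion counts plus realized false discovery proportions at
#' all three tree levels. A rejected embryo/cell is a false discovery when
#' no chromosome of that embryo/cell is truly aneuploid.
#'
#' @param callset a `mosaiscan_callset` from [run_caller()].
#' @param truth truth table from [simulate_ploidy_states()].
#' @return one-row data.frame: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `precision`, `fdp_leaf`, `fdp_cell`, `fdp_embryo`
#'   (sensitivity is `NA` when no aneuploidy was planted).
#' @export
score_calls <- function(callset, truth) {
  leaves <- callset$leaves
  key <- paste(leaves$cell_id, leaves$chromosome)
  tkey <- paste(truth$cell_id, truth$chromosome)
  aneu <- truth$copy_number[match(key, tkey)] != 2L
  rej <- leaves$rejected_leaf
  tp <- sum(rej & aneu); fp <- sum(rej & !aneu)
  fn <- sum(!rej & aneu); tn <- sum(!rej & !aneu)

  fdp <- function(rejected, is_null) {
    if (sum(rejected) == 0) return(0)
    sum(rejected & is_null) / sum(rejected)
  }
  cell_aneu <- tapply(aneu, leaves$cell_id, any)
  sel <- callset$selection
  cell_null <- !cell_aneu[sel$cells$cell_id]
  emb_aneu <- tapply(aneu, leaves$embryo_id, any)
  emb_null <- !emb_aneu[sel$embryos$embryo_id]

  data.frame(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    fdp_leaf = fdp(rej, !aneu),
    fdp_cell = fdp(sel$cells$rejected, cell_null),
    fdp_embryo = fdp(sel$embryos$rejected, emb_null)
  )
}

#' Benchmark the caller over overdispersion factors and replicates
#'
#' For each overdispersion factor and replicate, a cohort is simulated and
#' the caller run in both modes at the same nominal FDR; discoveries are
#' scored against the planted truth at the leaf, cell and embryo levels.
#' Replicate seeds are derived deterministically from the config seed.
#'
#' @param config a `mosaiscan_sim_config`.
#' @param overdispersions variance scaling factors; default `c(0.3, 1, 5)`.
#' @param n_replicates replicates per factor; default 100.
#' @param modes caller modes to run; default both.
#' @param fdr nominal FDR; default 0.01.
#' @return object of class `mosaiscan_benchmark`: list with `replicates`
#'   (per-replicate scores) and `summary` (means per condition and mode).
#' @export
run_benchmark <- function(config = sim_config(),
                          overdispersions = c(0.3, 1, 5),
                          n_replicates = 100,
                          modes = c("combined", "expression_only"),
                          fdr = 0.01) {
  rows <- list()
  for (oi in seq_along(overdispersions)) {
    od <- overdispersions[oi]
    for (rep_i in seq_len(n_replicates)) {
      seed <- (config$seed + 7919L * oi + rep_i) %% .Machine$integer.max
      sim <- simulate_cohort(config, overdispersion = od, seed = seed)
      for (mode in modes) {
        cs <- run_caller(sim, mode = mode, fdr = fdr)
        sc <- score_calls(cs, sim$truth)
        sc$overdispersion <- od
        sc$replicate <- rep_i
        sc$mode <- mode
        rows[[length(rows) + 1L]] <- sc
      }
    }
  }
  reps <- do.call(rbind, rows)
  agg <- stats::aggregate(
    reps[, c("sensitivity", "specificity", "precision",
             "fdp_leaf", "fdp_cell", "fdp_embryo")],
    by = list(overdispersion = reps$overdispersion, mode = reps$mode),
    FUN = function(x) mean(x, na.rm = TRUE))
  structure(list(replicates = reps, summary = agg, fdr = fdr,
                 n_replicates = n_replicates),
            class = "mosaiscan_benchmark")
}

#' @export
print.mosaiscan_benchmark <- function(x, ...) {
  cat("caller benchmark (", x$n_replicates, " replicates, FDR ",
      x$fdr, "):\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}
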