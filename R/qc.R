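#' Filter cells on sequencing depth
#'
#' Removes the union of cells lying strictly below the `quantile`-quantile of
#' mapped reads and of percent mapped reads. The quantile is computed with
#' the linear-interpolation convention (type 7); both the strictness of the
#' inequality and the quantile type are exposed because source descriptions
#' of this filter rarely state them.
#'
#' @param meta cell metadata data.frame (see [read_cell_meta()]).
#' @param quantile depth quantile in (0, 0.5]; default 0.10.
#' @param strict logical; drop cells strictly below the cutoff (default) or
#'   at-or-below it.
#' @param type quantile type passed to [stats::quantile()].
#' @return list with `keep` and `removed` character vectors of cell IDs.
#' @export
filter_cells_by_depth <- function(meta, quantile = 0.10, strict = TRUE,
                                  type = 7) {
  if (quantile <= 0 || quantile > 0.5)
    stop("quantile must lie in (0, 0.5]")
  if (any(is.na(meta$mapped_reads)) || any(is.na(meta$pct_mapped)))
    stop("mapped_reads and pct_mapped must be non-missing for all cells")
  q_reads <- stats::quantile(meta$mapped_reads, quantile, type = type,
                             names = FALSE)
  q_pct <- stats::quantile(meta$pct_mapped, quantile, type = type,
                           names = FALSE)
  below <- if (strict) {
    meta$mapped_reads < q_reads | meta$pct_mapped < q_pct
  } else {
    meta$mapped_reads <= q_reads | meta$pct_mapped <= q_pct
  }
  list(keep = meta$cell_id[!below], removed = meta$cell_id[below])
}

#' Counts-per-million normalization
#'
#' @param counts gene-by-cell matrix of raw counts.
#' @return matrix of the same shape whose columns each sum to 1e6.
#' @export
cpm_normalize <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("cell(s) with zero total counts: ",
         paste(utils::head(colnames(counts)[tot == 0], 3), collapse = ", "))
  sweep(counts, 2, tot, "/") * 1e6
}

#' Per-stratum gene filter on median CPM
#'
#' @param cpm gene-by-cell CPM matrix (library-size normalization is done on
#'   the full retained-autosome gene set, before any stratum subsetting).
#' @param stratum_cells cell IDs of the stratum.
#' @param min_median_cpm retain genes whose median CPM across the stratum's
#'   cells is at least this value; default 50.
#' @return character vector of retained gene IDs, or `NULL` when the stratum
#'   has fewer than 2 cells (stratum fails).
#' @export
filter_genes_in_stratum <- function(cpm, stratum_cells, min_median_cpm = 50) {
  stratum_cells <- intersect(stratum_cells, colnames(cpm))
  if (length(stratum_cells) < 2) return(NULL)
  med <- apply(cpm[, stratum_cells, drop = FALSE], 1, stats::median)
  rownames(cpm)[med >= min_median_cpm]
}

#' Define analysis strata from stage and cell type
#'
#' Strata partition retained cells: expression baselines are only comparable
#' among cells of the same embryonic stage and annotated cell type.
#'
#' @param meta cell metadata restricted to retained cells.
#' @return named list mapping `stratum_id` (`"<stage>.<cell_type>"`) to the
#'   stratum's cell IDs.
#' @export
define_strata <- function(meta) {
  if (any(is.na(meta$stage)) || any(is.na(meta$cell_type)))
    stop("stage and cell_type must be non-missing for retained cells")
  split(meta$cell_id, paste(meta$stage, meta$cell_type, sep = "."))
}

#' Run all quality control steps
#'
#' Applies the depth filter, defines (stage x cell type) strata, filters
#' genes per stratum on median CPM, and fails strata with too few retained
#' genes. Cells of embryos left with fewer than 2 retained cells stay in the
#' analysis but are flagged: chromosome-level calls are still made for them,
#' while embryo-level origin classification requires at least 2 cells.
#'
#' @param counts gene-by-cell raw count matrix (autosomal genes).
#' @param gene_map gene map data.frame.
#' @param meta cell metadata data.frame.
#' @param depth_quantile,min_median_cpm,min_genes QC thresholds; defaults
#'   0.10, 50 CPM and 2000 genes.
#' @return object of class `mosaiscan_qc`: a list with the filtered `counts`,
#'   `cpm`, `meta`, `gene_map`, the `strata` table (one row per stratum with
#'   `n_cells`, `n_genes`, `pass`), per-stratum `stratum_cells` /
#'   `stratum_genes` lists, and `removed_cells`.
#' @export
run_qc <- function(counts, gene_map, meta, depth_quantile = 0.10,
                   min_median_cpm = 50, min_genes = 2000) {
  depth <- filter_cells_by_depth(meta, depth_quantile)
  meta <- meta[meta$cell_id %in% depth$keep, ]
  counts <- counts[, meta$cell_id, drop = FALSE]
  cpm <- cpm_normalize(counts)

  stratum_cells <- define_strata(meta)
  stratum_genes <- lapply(stratum_cells, function(cells)
    filter_genes_in_stratum(cpm, cells, min_median_cpm))
  strata <- data.frame(
    stratum_id = names(stratum_cells),
    n_cells = vapply(stratum_cells, length, integer(1)),
    n_genes = vapply(stratum_genes, function(g)
      if (is.null(g)) 0L else length(g), integer(1)),
    stringsAsFactors = FALSE
  )
  strata <- qc_strata(strata, min_genes)
  rownames(strata) <- NULL

  small_embryo <- names(which(table(meta$embryo_id) < 2))
  meta$flag_small_embryo <- meta$embryo_id %in% small_embryo

  structure(list(
    counts = counts, cpm = cpm, meta = meta, gene_map = gene_map,
    strata = strata, stratum_cells = stratum_cells,
    stratum_genes = stratum_genes, removed_cells = depth$removed
  ), class = "mosaiscan_qc")
}

#' Flag strata with too few sufficiently expressed genes
#'
#' @param strata data.frame with columns `stratum_id`, `n_cells`, `n_genes`.
#' @param min_genes strata with fewer retained genes fail and contribute no
#'   calls downstream.
#' @return `strata` with a logical `pass` column.
#' @export
qc_strata <- function(strata, min_genes) {
  strata$pass <- strata$n_genes >= min_genes & strata$n_cells >= 2
  n_fail <- sum(!strata$pass)
  if (n_fail > 0)
    message(n_fail, " stratum/strata failed QC (fewer than ", min_genes,
            " retained genes or fewer than 2 cells)")
  strata
}

#' @export
print.mosaiscan_qc <- function(x, ...) {
  cat("mosaiscan QC result\n")
  cat("  cells retained:", nrow(x$meta),
      "(removed:", length(x$removed_cells), ")\n")
  cat("  genes:", nrow(x$counts), "\n")
  cat("  strata passing QC:", sum(x$strata$pass), "of", nrow(x$strata), "\n")
  invisible(x)
}
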