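#' Read a gene-to-chromosome map
#'
#' @param path TSV with header columns `gene_id`, `chromosome` and optionally
#'   `is_protein_coding` (logical or 0/1; defaults to `TRUE` when absent).
#' @return data.frame with columns `gene_id`, `chromosome` (bare autosome
#'   labels; non-autosomal genes are dropped), `is_protein_coding`.
#' @export
read_gene_map <- function(path) {
  gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "chromosome")
  if (!all(req %in% names(gm)))
    stop("gene map must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(gm$gene_id))
    stop("duplicate gene ID in gene map: ",
         gm$gene_id[duplicated(gm$gene_id)][1])
  gm$chromosome <- normalize_chrom(gm$chromosome)
  if (!"is_protein_coding" %in% names(gm)) gm$is_protein_coding <- TRUE
  gm$is_protein_coding <- as.logical(gm$is_protein_coding)
  gm <- gm[!is.na(gm$chromosome), c("gene_id", "chromosome", "is_protein_coding")]
  rownames(gm) <- NULL
  gm
}

#' Read per-cell metadata
#'
#' @param path TSV with header columns `cell_id`, `embryo_id`, `stage`,
#'   `cell_type`, `mapped_reads`, `pct_mapped` (fraction in \[0,1\]).
#' @return validated data.frame.
#' @export
read_cell_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "embryo_id", "stage", "cell_type",
           "mapped_reads", "pct_mapped")
  if (!all(req %in% names(meta)))
    stop("cell metadata must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(meta$cell_id))
    stop("duplicate cell ID in metadata: ",
         meta$cell_id[duplicated(meta$cell_id)][1])
  if (any(meta$pct_mapped < 0 | meta$pct_mapped > 1))
    stop("pct_mapped must lie in [0, 1]")
  meta[, req]
}

#' Read a gene-by-cell raw count matrix
#'
#' Accepts either a MatrixMarket triplet (`.mtx`, with sidecar `genes.tsv` and
#' `cells.tsv` of IDs, one per line, in the same directory unless given
#' explicitly) or a wide TSV whose header row holds cell IDs and whose first
#' column holds gene IDs. Genes absent from the gene map, or mapped to
#' non-autosomes, are dropped with a message.
#'
#' @param matrix_path path to the `.mtx` or wide TSV file.
#' @param gene_map a data.frame from [read_gene_map()] or a path to one.
#' @param cell_meta a data.frame from [read_cell_meta()] or a path to one;
#'   optional (`NULL` skips the metadata consistency check).
#' @param genes_path,cells_path sidecar ID files for the MatrixMarket route.
#' @return list with `counts` (integer matrix, genes x cells), `gene_map`
#'   (restricted to retained genes), and `meta` (reordered to the matrix's
#'   cell order, or `NULL`).
#' @export
read_counts <- function(matrix_path, gene_map, cell_meta = NULL,
                        genes_path = NULL, cells_path = NULL) {
  if (is.character(gene_map)) gene_map <- read_gene_map(gene_map)
  if (is.character(cell_meta)) cell_meta <- read_cell_meta(cell_meta)

  if (grepl("\\.mtx$", matrix_path)) {
    dirn <- dirname(matrix_path)
    if (is.null(genes_path)) genes_path <- file.path(dirn, "genes.tsv")
    if (is.null(cells_path)) cells_path <- file.path(dirn, "cells.tsv")
    m <- as.matrix(Matrix::readMM(matrix_path))
    gid <- readLines(genes_path)
    cid <- readLines(cells_path)
    if (nrow(m) != length(gid) || ncol(m) != length(cid))
      stop("MatrixMarket dimensions do not match sidecar ID files")
    dimnames(m) <- list(gid, cid)
  } else {
    # read.delim uniquifies duplicated header names, so check them raw
    header <- strsplit(readLines(matrix_path, n = 1), "\t", fixed = TRUE)[[1]]
    cid <- header[-1]
    if (anyDuplicated(cid))
      stop("duplicate cell ID in count matrix: ", cid[duplicated(cid)][1])
    tab <- utils::read.delim(matrix_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    gid <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    dimnames(m) <- list(gid, cid)
  }
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene ID in count matrix: ",
         rownames(m)[duplicated(rownames(m))][1])
  if (anyDuplicated(colnames(m)))
    stop("duplicate cell ID in count matrix: ",
         colnames(m)[duplicated(colnames(m))][1])
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  storage.mode(m) <- "integer"

  keep <- rownames(m) %in% gene_map$gene_id
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("dropping ", n_drop,
            " gene(s) absent from the autosomal gene map")
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) stop("no genes retained")

  gene_map <- gene_map[match(rownames(m), gene_map$gene_id), ]
  rownames(gene_map) <- NULL
  if (!is.null(cell_meta)) {
    missing <- setdiff(colnames(m), cell_meta$cell_id)
    if (length(missing) > 0)
      stop("cells missing from metadata: ",
           paste(utils::head(missing, 3), collapse = ", "))
    cell_meta <- cell_meta[match(colnames(m), cell_meta$cell_id), ]
    rownames(cell_meta) <- NULL
  }
  list(counts = m, gene_map = gene_map, meta = cell_meta)
}

#' Read a per-cell allele count table
#'
#' The expected dialect is the GATK ASEReadCounter output with a leading
#' `cell_id` column: `cell_id`, `contig`, `position`, `variantID`,
#' `refAllele`, `altAllele`, `refCount`, `altCount`, `totalCount` (only
#' `cell_id`, `contig`, `position`, `refCount`, `altCount` are required).
#' Positions are 1-based. Non-autosomal contigs and rows with zero total
#' coverage are dropped.
#'
#' @param path TSV file.
#' @return data.frame with columns `cell_id`, `chromosome`, `position`,
#'   `ref_count`, `alt_count`.
#' @export
read_allele_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "contig", "position", "refCount", "altCount")
  if (!all(req %in% names(tab)))
    stop("allele count table must have columns: ", paste(req, collapse = ", "))
  out <- data.frame(
    cell_id = as.character(tab$cell_id),
    chromosome = normalize_chrom(tab$contig),
    position = as.integer(tab$position),
    ref_count = as.integer(tab$refCount),
    alt_count = as.integer(tab$altCount),
    stringsAsFactors = FALSE
  )
  if (any(out$ref_count < 0 | out$alt_count < 0, na.rm = TRUE))
    stop("allele counts must be non-negative")
  out <- out[!is.na(out$chromosome) & (out$ref_count + out$alt_count) >= 1, ]
  rownames(out) <- NULL
  out
}

# Canonical TSV writer: tab-separated, no quoting, no row names, so written
# outputs re-read byte-identically.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
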