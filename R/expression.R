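# Leave-one-out median per row: entry (g, i) is the median of row g with
# column i removed. Rank-based so the whole matrix costs one sort per row.
loo_median <- function(m) {
  n <- ncol(m)
  stopifnot(n >= 3)
  k <- n - 1L
  out <- matrix(0, nrow(m), n, dimnames = dimnames(m))
  for (g in seq_len(nrow(m))) {
    x <- m[g, ]
    r <- rank(x, ties.method = "first")
    xs <- x[order(r)]
    if (k %% 2L == 1L) {
      p <- (k + 1L) %/% 2L
      out[g, ] <- ifelse(r <= p, xs[p + 1L], xs[p])
    } else {
      p <- k %/% 2L
      lo <- ifelse(r <= p, xs[p + 1L], xs[p])
      hi <- ifelse(r <= p + 1L, xs[p + 2L], xs[p + 1L])
      out[g, ] <- (lo + hi) / 2
    }
  }
  out
}

#' Per-cell, per-chromosome expression dosage scores
#'
#' For cell *i* in a stratum, each gene's CPM is divided by the leave-one-out
#' median CPM of the same gene across the other stratum cells; the dosage
#' score `s` for chromosome *j* is the median of these ratios over the
#' chromosome's retained genes. `s` has null expectation 1, is approximately
#' 0.5 under monosomy and 1.5 under trisomy. Genes whose leave-one-out
#' reference is 0 are skipped for that cell; chromosomes with fewer than
#' `min_genes_per_chrom` contributing genes yield no score.
#'
#' @param cpm gene-by-cell CPM matrix.
#' @param stratum_cells cell IDs of one QC-passing stratum (>= 3 cells).
#' @param gene_map gene map restricted to the stratum's retained genes.
#' @param genes optional subset of gene IDs to use (the stratum's retained
#'   gene list); default all genes in `gene_map` present in `cpm`.
#' @param min_genes_per_chrom minimum genes per chromosome; default 25.
#' @return data.frame with columns `cell_id`, `chromosome`, `s`, `n_genes`.
#' @export
dosage_scores <- function(cpm, stratum_cells, gene_map, genes = NULL,
                          min_genes_per_chrom = 25) {
  if (is.null(genes)) genes <- gene_map$gene_id
  genes <- intersect(intersect(genes, rownames(cpm)), gene_map$gene_id)
  stratum_cells <- intersect(stratum_cells, colnames(cpm))
  if (length(stratum_cells) < 3)
    stop("dosage scores need at least 3 cells in the stratum")
  m <- cpm[genes, stratum_cells, drop = FALSE]
  ref <- loo_median(m)
  rho <- m / ref
  rho[ref == 0] <- NA # zero reference: gene uninformative for that cell
  chrom <- gene_map$chromosome[match(genes, gene_map$gene_id)]

  res <- lapply(unique(chrom), function(j) {
    rj <- rho[chrom == j, , drop = FALSE]
    n_ok <- colSums(!is.na(rj))
    s <- apply(rj, 2, stats::median, na.rm = TRUE)
    data.frame(cell_id = colnames(rj), chromosome = j, s = unname(s),
               n_genes = unname(n_ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[out$n_genes >= min_genes_per_chrom, ]
  rownames(out) <- NULL
  # per-chromosome gene-level ratio matrices, kept for the exact median
  # tail test in expression_pvalues()
  attr(out, "rho") <- lapply(split(seq_along(chrom), chrom),
                             function(i) rho[i, , drop = FALSE])
  out
}

# Exact tail p-value for the median of K gene ratios: under the null the
# number of a cell's ratios exceeding a threshold t is approximately
# Binomial(K, p0) with p0 estimated from the pooled ratios of the other
# stratum cells (add-one smoothed). ceiling(K/2) exceedances can move the
# median past t. The normal approximation to the median is anti-conservative
# here: at K ~ 25-200 genes, 4 SDs of the median is under one SD of a single
# ratio, where the binomial tail decays much more slowly than the Gaussian.
median_tail_p <- function(rho, s, cells) {
  flat <- rho[!is.na(rho)]
  all_v <- sort(flat)
  N <- length(all_v)
  vapply(seq_along(cells), function(k) {
    own <- rho[, cells[k]]
    own <- own[!is.na(own)]
    K <- length(own)
    t <- s[k]
    n_gt <- (N - findInterval(t, all_v)) - sum(own > t)
    n_lt <- findInterval(t, all_v, left.open = TRUE) - sum(own < t)
    tot <- N - K
    m <- ceiling(K / 2)
    p_up <- stats::pbinom(m - 1, K, (n_gt + 1) / (tot + 2),
                          lower.tail = FALSE)
    p_lo <- stats::pbinom(m - 1, K, (n_lt + 1) / (tot + 2),
                          lower.tail = FALSE)
    min(1, 2 * min(p_up, p_lo))
  }, numeric(1))
}

#' Z-statistics and p-values for dosage scores
#'
#' Within each (stratum, chromosome) family the score is standardized against
#' the theoretical null center 1 with a robust scale: 1.4826 times the median
#' absolute deviation of the stratum's scores for that chromosome. Centering
#' at 1 (rather than the empirical median) keeps the statistic honest in
#' strata where many cells share the same aneuploidy.
#'
#' P-values come from an exact empirical-binomial tail test of the
#' chromosome median when the gene-level ratio matrices are available (as
#' attached by [dosage_scores()]): the per-gene exceedance probability at
#' the observed score is estimated from the other stratum cells' pooled
#' ratios and referred to the binomial tail of "at least half the
#' chromosome's genes exceed it". On a bare score table the two-sided
#' standard-normal tail of `z_expr` is used instead; that approximation is
#' anti-conservative beyond about 3 SDs. Both are clipped to \[1e-300, 1\].
#'
#' @param scores data.frame from [dosage_scores()] for one stratum.
#' @return `scores` with `z_expr` and `p_expr` columns appended.
#' @export
expression_pvalues <- function(scores) {
  if (length(unique(scores$cell_id)) < 5)
    stop("expression p-values need at least 5 cells for scale estimation")
  rho <- attr(scores, "rho")
  out <- lapply(split(scores, scores$chromosome), function(sc) {
    sigma <- stats::mad(sc$s) # 1.4826 * MAD, median-centered
    if (sigma == 0) {
      warning("degenerate stratum scale (MAD = 0) on chromosome ",
              sc$chromosome[1], "; p_expr set to 1")
      sc$z_expr <- 0
      sc$p_expr <- 1
      return(sc)
    }
    sc$z_expr <- (sc$s - 1) / sigma
    rj <- rho[[sc$chromosome[1]]]
    if (is.null(rj)) {
      sc$p_expr <- clip_p(2 * stats::pnorm(-abs(sc$z_expr)))
    } else {
      sc$p_expr <- clip_p(median_tail_p(rj, sc$s, sc$cell_id))
    }
    sc
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Expression dosage signal for all QC-passing strata
#'
#' @param qc a `mosaiscan_qc` object from [run_qc()].
#' @param min_genes_per_chrom minimum genes per chromosome; default 25.
#' @return data.frame (`cell_id`, `chromosome`, `s`, `n_genes`, `z_expr`,
#'   `p_expr`, `stratum_id`), one row per scored cell-chromosome.
#' @export
expression_signal <- function(qc, min_genes_per_chrom = 25) {
  pass <- qc$strata$stratum_id[qc$strata$pass]
  res <- lapply(pass, function(sid) {
    cells <- qc$stratum_cells[[sid]]
    if (length(cells) < 5) return(NULL)
    sc <- dosage_scores(qc$cpm, cells, qc$gene_map,
                        genes = qc$stratum_genes[[sid]],
                        min_genes_per_chrom = min_genes_per_chrom)
    if (nrow(sc) == 0) return(NULL)
    sc <- expression_pvalues(sc)
    sc$stratum_id <- sid
    sc
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
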