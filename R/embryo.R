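#' Classify aneuploidies as meiotic or mitotic per embryo
#'
#' Meiotic errors arise in the gametes and are expected in (nearly) every
#' cell of the embryo, whereas mitotic errors affect a clonal subset. Two
#' heuristics are implemented, applied per "particular aneuploidy", i.e. per
#' (chromosome, monosomy-or-trisomy) pair:
#' * `fraction_75`: meiotic when at least `cutoff` (default 75%) of the
#'   embryo's cells carry that exact aneuploidy;
#' * `lt2_normal`: meiotic when fewer than 2 of the embryo's cells are
#'   non-aneuploid for that chromosome.
#' A chromosome carrying reciprocal monosomies and trisomies in different
#' cells therefore counts as two mitotic events, not one meiotic one.
#'
#' @param calls data.frame of rejected leaves with `embryo_id`, `cell_id`,
#'   `chromosome`, `call` (from [assign_ploidy_type()]).
#' @param meta retained-cell metadata (`cell_id`, `embryo_id`): defines each
#'   embryo's cell census, including euploid cells.
#' @param cutoff fraction threshold for `fraction_75`; default 0.75.
#' @param criterion `"fraction_75"` (default) or `"lt2_normal"`.
#' @param denominator `"all_cells"` (default): all retained cells of the
#'   embryo; `"callable"`: only cells with a non-missing combined p-value on
#'   that chromosome (requires a `callable` table, see below).
#' @param callable optional data.frame (`cell_id`, `chromosome`) of leaves
#'   with non-missing p-values, used by the `"callable"` denominator.
#' @return object of class `mosaiscan_origin`: list with `events` (one row
#'   per embryo x chromosome x type: `n_carrier`, `n_cells`, `fraction`,
#'   `origin`) and `embryos` (`embryo_id`, `n_cells`, `n_aneuploid_cells`,
#'   `category` in euploid/meiotic_only/mitotic_only/both/indeterminate).
#' @export
classify_embryo_errors <- function(calls, meta, cutoff = 0.75,
                                   criterion = c("fraction_75", "lt2_normal"),
                                   denominator = c("all_cells", "callable"),
                                   callable = NULL) {
  criterion <- match.arg(criterion)
  denominator <- match.arg(denominator)
  if (denominator == "callable" && is.null(callable))
    stop("denominator = 'callable' needs a callable-leaf table")

  embryos <- unique(meta$embryo_id)
  events <- NULL
  categories <- character(length(embryos))
  names(categories) <- embryos

  for (e in embryos) {
    cells <- meta$cell_id[meta$embryo_id == e]
    ec <- calls[calls$embryo_id == e, , drop = FALSE]
    if (length(cells) < 2) {
      categories[e] <- "indeterminate"
      next
    }
    if (nrow(ec) == 0) {
      categories[e] <- "euploid"
      next
    }
    grp <- unique(ec[, c("chromosome", "call")])
    grp$embryo_id <- e
    grp$n_carrier <- NA_integer_
    grp$n_cells <- NA_integer_
    for (i in seq_len(nrow(grp))) {
      carriers <- unique(ec$cell_id[ec$chromosome == grp$chromosome[i] &
                                      ec$call == grp$call[i]])
      denom_cells <- cells
      if (denominator == "callable") {
        denom_cells <- intersect(
          cells, callable$cell_id[callable$chromosome == grp$chromosome[i]])
      }
      grp$n_carrier[i] <- length(intersect(carriers, denom_cells))
      grp$n_cells[i] <- length(denom_cells)
    }
    grp$fraction <- grp$n_carrier / pmax(grp$n_cells, 1)
    if (criterion == "fraction_75") {
      grp$origin <- ifelse(grp$fraction >= cutoff, "meiotic", "mitotic")
    } else {
      # cells non-aneuploid for that chromosome, regardless of gain/loss
      grp$origin <- vapply(seq_len(nrow(grp)), function(i) {
        abn <- unique(ec$cell_id[ec$chromosome == grp$chromosome[i]])
        n_normal <- length(setdiff(cells, abn))
        if (n_normal < 2) "meiotic" else "mitotic"
      }, character(1))
    }
    events <- rbind(events, grp)
    has_mei <- any(grp$origin == "meiotic")
    has_mit <- any(grp$origin == "mitotic")
    categories[e] <- if (has_mei && has_mit) "both"
      else if (has_mei) "meiotic_only" else "mitotic_only"
  }

  emb <- data.frame(embryo_id = embryos, stringsAsFactors = FALSE)
  emb$n_cells <- as.integer(table(meta$embryo_id)[embryos])
  n_aneu <- tapply(calls$cell_id, calls$embryo_id,
                   function(x) length(unique(x)))
  emb$n_aneuploid_cells <- as.integer(
    ifelse(is.na(n_aneu[embryos]), 0L, n_aneu[embryos]))
  emb$fraction_aneuploid <- emb$n_aneuploid_cells / emb$n_cells
  emb$category <- unname(categories[embryos])
  if (!is.null(events)) {
    events <- events[, c("embryo_id", "chromosome", "call", "n_carrier",
                         "n_cells", "fraction", "origin")]
    rownames(events) <- NULL
  }
  structure(list(events = events, embryos = emb,
                 criterion = criterion, cutoff = cutoff),
            class = "mosaiscan_origin")
}

#' @export
print.mosaiscan_origin <- function(x, ...) {
  cat("embryo error classification (", x$criterion, "):\n", sep = "")
  print(table(x$embryos$category))
  invisible(x)
}

#' Cohort summary at a grid of FDR levels
#'
#' Re-runs hierarchical selection at each level of `q_grid` and reports the
#' proportions of rejected leaves (cell-chromosomes), cells and embryos.
#' All three curves are non-decreasing in q.
#'
#' @param leaves omnibus leaf table (see [omnibus_table()]).
#' @param q_grid FDR levels; default `c(0.001, 0.005, 0.01, 0.05, 0.1)`.
#' @return data.frame with one row per level: counts and proportions at the
#'   leaf, cell and embryo levels.
#' @export
summarize_cohort <- function(leaves, q_grid = c(0.001, 0.005, 0.01, 0.05, 0.1)) {
  res <- lapply(q_grid, function(q) {
    sel <- treebh_select(leaves, q)
    data.frame(
      q = q,
      n_leaves = nrow(sel$leaves),
      n_leaves_aneuploid = sum(sel$leaves$rejected_leaf),
      n_cells = nrow(sel$cells),
      n_cells_aneuploid = sum(sel$cells$rejected),
      n_embryos = nrow(sel$embryos),
      n_embryos_aneuploid = sum(sel$embryos$rejected)
    )
  })
  out <- do.call(rbind, res)
  out$prop_leaves <- out$n_leaves_aneuploid / out$n_leaves
  out$prop_cells <- out$n_cells_aneuploid / out$n_cells
  out$prop_embryos <- out$n_embryos_aneuploid / out$n_embryos
  out
}

#' Hierarchical clustering of aneuploidy signatures within an embryo
#'
#' Cells are clustered on their chromosome-wide signature vectors (Z-scores
#' or dosage scores) with Euclidean distance and average linkage; clonal
#' mitotic errors shared by a lineage pull its cells together, so the
#' dendrogram roughly reflects common ancestry. Missing entries are imputed
#' to the null value (0 for Z-scores, 1 for dosage scores).
#'
#' @param sig cells-by-chromosomes numeric matrix for one embryo (row names
#'   are cell IDs).
#' @param null_value imputation value for missing entries; default 0.
#' @return list with `hclust` (the fitted tree), `order` (deterministic leaf
#'   order), and `matrix` (the imputed matrix in leaf order, ready for
#'   heat-map rendering), or `NULL` when fewer than 2 cells are available.
#' @export
cluster_cells_hierarchical <- function(sig, null_value = 0) {
  sig <- as.matrix(sig)
  keep <- rowSums(!is.na(sig)) > 0
  sig <- sig[keep, , drop = FALSE]
  if (nrow(sig) < 2) {
    message("skipping clustering: fewer than 2 cells with signatures")
    return(NULL)
  }
  sig[is.na(sig)] <- null_value
  hc <- stats::hclust(stats::dist(sig), method = "average")
  list(hclust = hc, order = rownames(sig)[hc$order],
       matrix = sig[hc$order, , drop = FALSE])
}

#' Correlation of per-chromosome aneuploidy rates with gene content
#'
#' Chromosome-specific aneuploidy rates (rejected leaves / tested leaves)
#' against the number of protein-coding genes per chromosome, Pearson
#' correlation with a two-sided p-value. Gene-poor chromosomes tolerate
#' aneuploidy better, so a negative correlation is expected.
#'
#' @param leaves selected leaf table with `chromosome` and `rejected_leaf`.
#' @param gene_map gene map with `chromosome` and `is_protein_coding`.
#' @return list with `rates` (per-chromosome table), `r`, `p_value`.
#' @export
chromosome_rate_gene_correlation <- function(leaves, gene_map) {
  chrs <- autosomes()
  tested <- table(factor(leaves$chromosome, levels = chrs))
  flagged <- table(factor(leaves$chromosome[leaves$rejected_leaf],
                          levels = chrs))
  genes <- table(factor(gene_map$chromosome[gene_map$is_protein_coding],
                        levels = chrs))
  rates <- data.frame(
    chromosome = chrs,
    n_tested = as.integer(tested),
    n_flagged = as.integer(flagged),
    rate = as.integer(flagged) / pmax(as.integer(tested), 1),
    n_genes = as.integer(genes)
  )
  if (stats::var(rates$rate) == 0 || stats::var(rates$n_genes) == 0)
    stop("zero variance in rates or gene counts; correlation undefined")
  ct <- stats::cor.test(rates$rate, rates$n_genes, method = "pearson")
  list(rates = rates, r = unname(ct$estimate), p_value = ct$p.value)
}
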