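#' Gate expression p-values on dosage effect size
#'
#' A chromosome only counts as a candidate aneuploidy when its dosage score
#' departs from the null by at least `threshold` (|1 - s| >= 0.2 by default,
#' i.e. roughly mid-way toward the monosomy/trisomy expectations of 0.5 and
#' 1.5); otherwise the expression p-value is set to 1 so that small but
#' statistically crisp fluctuations cannot drive a call.
#'
#' @param s dosage scores.
#' @param p_expr matching expression p-values.
#' @param threshold effect-size floor, inclusive; default 0.2.
#' @return gated p-values.
#' @export
gate_expression_p <- function(s, p_expr, threshold = 0.2) {
  stopifnot(all(s > 0, na.rm = TRUE))
  # inclusive boundary, robust to floating-point representation of |1 - s|
  ifelse(abs(1 - s) - threshold >= -1e-12, p_expr, 1)
}

#' Combine two p-values with Fisher's method
#'
#' `chi2 = -2 (ln p1 + ln p2)` referred to the chi-square upper tail with 4
#' degrees of freedom. When exactly one p-value is missing the available one
#' is carried through unchanged (the df = 2 case of Fisher's statistic);
#' when both are missing the result is `NA`.
#'
#' @param p1,p2 p-values in (0, 1], already clipped away from 0; `NA` allowed.
#' @return combined p-values.
#' @export
fisher_combine <- function(p1, p2) {
  p1 <- clip_p(p1)
  p2 <- clip_p(p2)
  both <- !is.na(p1) & !is.na(p2)
  out <- ifelse(is.na(p1), p2, p1) # single-signal fallback (df = 2)
  chi2 <- -2 * (log(p1[both]) + log(p2[both]))
  out[both] <- stats::pchisq(chi2, df = 4, lower.tail = FALSE)
  out
}

#' Simes combination of child p-values
#'
#' `p_parent = min_i { m p_(i) / i }` over the sorted child p-values, capped
#' at 1. This is the within-family aggregation used to carry evidence up the
#' hypothesis tree.
#'
#' @param p non-empty numeric vector of child p-values (`NA`s dropped).
#' @return a single aggregated p-value.
#' @export
simes_p <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) return(NA_real_)
  p <- sort(p)
  m <- length(p)
  min(min(m * p / seq_len(m)), 1)
}

# Benjamini-Hochberg rejection at level alpha; returns a logical vector.
bh_reject <- function(p, alpha) {
  m <- length(p)
  rej <- rep(FALSE, m)
  ok <- !is.na(p)
  if (!any(ok) || alpha <= 0) return(rej)
  ps <- sort(p[ok])
  below <- ps <= alpha * seq_along(ps) / sum(ok)
  if (!any(below)) return(rej)
  thr <- ps[max(which(below))]
  rej[ok] <- p[ok] <= thr
  rej
}

#' Hierarchical FDR selection on the embryo-cell-chromosome tree
#'
#' Tree-structured Benjamini-Hochberg selection: child p-values are
#' aggregated to their parents with Simes' rule, embryos are selected by BH
#' at level `q`, cells within each selected embryo by BH at level
#' `q * R1/m1` (the fraction of embryos selected), and chromosomes within
#' each selected cell by BH at level `q * (R1/m1) * (R2e/m2e)` (further
#' scaled by the fraction of that embryo's cells selected). A leaf can only
#' be rejected when its cell and embryo are, so the FDR is controlled at
#' every level of the hierarchy.
#'
#' @param leaves data.frame with columns `embryo_id`, `cell_id`,
#'   `chromosome`, `p` (`NA` = untestable leaf, never rejected).
#' @param q nominal FDR level at each tree level; default 0.01.
#' @return object of class `mosaiscan_treebh`: list with `leaves` (input plus
#'   `rejected_leaf`, `rejected_cell`, `rejected_embryo`), `cells` and
#'   `embryos` tables holding aggregated p-values, rejection flags and the
#'   BH level applied to each family, and `q`.
#' @export
treebh_select <- function(leaves, q = 0.01) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  req <- c("embryo_id", "cell_id", "chromosome", "p")
  stopifnot(all(req %in% names(leaves)))
  if (anyDuplicated(leaves[, c("cell_id", "chromosome")]))
    stop("duplicate (cell, chromosome) leaf")

  cell_tab <- unique(leaves[, c("embryo_id", "cell_id")])
  if (anyDuplicated(cell_tab$cell_id))
    stop("a cell is attached to more than one embryo")
  cell_p <- vapply(split(leaves$p, leaves$cell_id), simes_p, numeric(1))
  cell_tab$p <- unname(cell_p[cell_tab$cell_id])

  embryo_tab <- data.frame(embryo_id = unique(cell_tab$embryo_id),
                           stringsAsFactors = FALSE)
  emb_p <- vapply(split(cell_tab$p, cell_tab$embryo_id), simes_p, numeric(1))
  embryo_tab$p <- unname(emb_p[embryo_tab$embryo_id])

  # Level 1: embryos
  embryo_tab$rejected <- bh_reject(embryo_tab$p, q)
  embryo_tab$level <- q
  m1 <- sum(!is.na(embryo_tab$p))
  r1 <- sum(embryo_tab$rejected)
  frac1 <- if (m1 > 0) r1 / m1 else 0

  # Level 2: cells within selected embryos
  cell_tab$rejected <- FALSE
  cell_tab$level <- NA_real_
  for (e in embryo_tab$embryo_id[embryo_tab$rejected]) {
    idx <- cell_tab$embryo_id == e
    lvl <- q * frac1
    cell_tab$rejected[idx] <- bh_reject(cell_tab$p[idx], lvl)
    cell_tab$level[idx] <- lvl
  }

  # Level 3: chromosomes within selected cells
  cell_frac <- vapply(split(cell_tab, cell_tab$embryo_id), function(ct) {
    m <- sum(!is.na(ct$p))
    if (m == 0) 0 else sum(ct$rejected) / m
  }, numeric(1))
  leaves$rejected_leaf <- FALSE
  leaves$leaf_level <- NA_real_
  for (ci in which(cell_tab$rejected)) {
    cell <- cell_tab$cell_id[ci]
    e <- cell_tab$embryo_id[ci]
    idx <- leaves$cell_id == cell
    lvl <- q * frac1 * cell_frac[[e]]
    leaves$rejected_leaf[idx] <- bh_reject(leaves$p[idx], lvl)
    leaves$leaf_level[idx] <- lvl
  }
  leaves$rejected_cell <-
    leaves$cell_id %in% cell_tab$cell_id[cell_tab$rejected]
  leaves$rejected_embryo <-
    leaves$embryo_id %in% embryo_tab$embryo_id[embryo_tab$rejected]
  stopifnot(!any(leaves$rejected_leaf & !leaves$rejected_cell),
            !any(leaves$rejected_cell & !leaves$rejected_embryo))

  structure(list(leaves = leaves, cells = cell_tab, embryos = embryo_tab,
                 q = q), class = "mosaiscan_treebh")
}

#' @export
print.mosaiscan_treebh <- function(x, ...) {
  cat("hierarchical FDR selection at q =", x$q, "\n")
  cat("  embryos rejected:", sum(x$embryos$rejected), "of",
      nrow(x$embryos), "\n")
  cat("  cells rejected:  ", sum(x$cells$rejected), "of",
      nrow(x$cells), "\n")
  cat("  leaves rejected: ", sum(x$leaves$rejected_leaf), "of",
      nrow(x$leaves), "\n")
  invisible(x)
}

#' Label selected aneuploidies as monosomy or trisomy
#'
#' 2-means clustering of the (z_expr, z_ai) pairs of rejected leaves with
#' deterministic initialization (centers at the componentwise minimum and
#' maximum); the cluster with the lower mean Z is labeled monosomy, the
#' other trisomy. With fewer than 2 leaves, or degenerate (identical)
#' points, the label falls back to the sign of `z_expr` (negative means
#' monosomy), or of `z_ai` when `z_expr` is missing. A missing Z coordinate
#' is imputed to 0 for clustering.
#'
#' @param rejected data.frame of rejected leaves with columns `z_expr`,
#'   `z_ai` (either may be `NA`, not both in the same row).
#' @return `rejected` with a `call` column in `{"monosomy", "trisomy"}`.
#' @export
assign_ploidy_type <- function(rejected) {
  if (nrow(rejected) == 0) {
    rejected$call <- character(0)
    return(rejected)
  }
  z <- cbind(ifelse(is.na(rejected$z_expr), 0, rejected$z_expr),
             ifelse(is.na(rejected$z_ai), 0, rejected$z_ai))
  sign_fallback <- function(ze, za) {
    base <- ifelse(!is.na(ze) & ze != 0, ze, za)
    ifelse(!is.na(base) & base < 0, "monosomy", "trisomy")
  }
  lo <- apply(z, 2, min)
  hi <- apply(z, 2, max)
  # fewer than 3 points cannot support a meaningful 2-means split (and two
  # same-type leaves would be forced into opposite labels), so small or
  # degenerate call sets use the sign rule directly
  if (nrow(rejected) < 3 || all(lo == hi)) {
    rejected$call <- sign_fallback(rejected$z_expr, rejected$z_ai)
    return(rejected)
  }
  km <- stats::kmeans(z, centers = rbind(lo, hi))
  means <- tapply(rowMeans(z), km$cluster, mean)
  mono_cluster <- as.integer(names(means)[which.min(means)]) # tie -> first
  rejected$call <- ifelse(km$cluster == mono_cluster, "monosomy", "trisomy")
  rejected
}

#' Build the omnibus leaf table from the two signal tables
#'
#' Full outer join of the expression and allelic signals on the complete
#' (retained cell x autosome) hypothesis ledger, expression effect-size
#' gating, and Fisher combination. Leaves with neither signal carry `p = NA`
#' and are never rejected, but remain in the ledger so every cell tests all
#' 22 autosomes.
#'
#' @param meta retained-cell metadata (`cell_id`, `embryo_id`).
#' @param expr data.frame from [expression_signal()] or `NULL`
#'   (allelic-only mode).
#' @param ai data.frame from [allelic_signal()] or `NULL` (expression-only
#'   mode).
#' @param effect_threshold dosage effect-size gate; default 0.2.
#' @return data.frame with one row per ledger leaf: `embryo_id`, `cell_id`,
#'   `chromosome`, `s`, `z_expr`, `p_expr`, `p_expr_gated`, `ai_ratio`,
#'   `z_ai`, `p_ai`, `p` (combined).
#' @export
omnibus_table <- function(meta, expr, ai, effect_threshold = 0.2) {
  led <- hypothesis_ledger(meta$cell_id, meta$embryo_id)
  key <- function(d) paste(d$cell_id, d$chromosome, sep = "\r")
  lk <- key(led)
  for (col in c("s", "z_expr", "p_expr")) led[[col]] <- NA_real_
  if (!is.null(expr)) {
    i <- match(lk, key(expr))
    led$s <- expr$s[i]
    led$z_expr <- expr$z_expr[i]
    led$p_expr <- expr$p_expr[i]
  }
  for (col in c("ai_ratio", "z_ai", "p_ai")) led[[col]] <- NA_real_
  if (!is.null(ai)) {
    i <- match(lk, key(ai))
    led$ai_ratio <- ai$ai_ratio[i]
    led$z_ai <- ai$z_ai[i]
    led$p_ai <- ai$p_ai[i]
  }
  led$p_expr_gated <- gate_expression_p(led$s, led$p_expr, effect_threshold)
  led$p <- fisher_combine(led$p_expr_gated, led$p_ai)
  led
}
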