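#' Chromosome-level allelic imbalance ratios
#'
#' For every (cell, chromosome) the minor-allele read count (the minimum of
#' reference- and alternate-supporting reads) is summed over the
#' chromosome's heterozygous SNPs and divided by the total read count, giving
#' a ratio in \[0, 0.5\]: 0.5 under perfectly balanced biallelic expression,
#' 0 under fully monoallelic expression (as in monosomy). Under-covered
#' combinations are dropped.
#'
#' @param allelic data.frame from [read_allele_counts()].
#' @param min_reads minimum summed reads per cell-chromosome; default 20.
#' @param min_snps minimum contributing SNPs; default 5.
#' @return data.frame with `cell_id`, `chromosome`, `n_snps`, `total_reads`,
#'   `ai_ratio`.
#' @export
chromosome_ai_ratio <- function(allelic, min_reads = 20, min_snps = 5) {
  key <- paste(allelic$cell_id, allelic$chromosome, sep = "\r")
  tot <- allelic$ref_count + allelic$alt_count
  minc <- pmin(allelic$ref_count, allelic$alt_count)
  agg <- rowsum(cbind(n_snps = 1, total_reads = tot, min_reads = minc), key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(
    cell_id = vapply(parts, `[`, "", 1),
    chromosome = vapply(parts, `[`, "", 2),
    n_snps = as.integer(agg[, "n_snps"]),
    total_reads = as.integer(agg[, "total_reads"]),
    ai_ratio = agg[, "min_reads"] / agg[, "total_reads"],
    stringsAsFactors = FALSE
  )
  out <- out[out$total_reads >= min_reads & out$n_snps >= min_snps, ]
  out <- out[order(out$cell_id, as.integer(out$chromosome)), ]
  rownames(out) <- NULL
  out
}

#' Remove the read-depth trend from allelic imbalance ratios
#'
#' Observed min-allele ratios correlate positively with the number of reads
#' used to compute them (shallow chromosomes look spuriously imbalanced), so
#' an ordinary least-squares fit of `ai_ratio` on `log10(total_reads)`,
#' pooled across all cell-chromosomes, is removed before null estimation.
#'
#' @param obs data.frame from [chromosome_ai_ratio()].
#' @return `obs` with a `residual` column; the fit's coefficients are
#'   attached as attribute `depth_fit`.
#' @export
residualize_depth <- function(obs) {
  if (nrow(obs) < 30)
    stop("depth residualization needs at least 30 observations")
  ld <- log10(obs$total_reads)
  if (stats::var(ld) == 0) {
    warning("all depths equal; residuals are mean-centered ratios")
    obs$residual <- obs$ai_ratio - mean(obs$ai_ratio)
    attr(obs, "depth_fit") <- c(intercept = mean(obs$ai_ratio), slope = 0)
    return(obs)
  }
  fit <- stats::lm.fit(cbind(1, ld), obs$ai_ratio)
  obs$residual <- unname(fit$residuals)
  attr(obs, "depth_fit") <- c(intercept = unname(fit$coefficients[1]),
                              slope = unname(fit$coefficients[2]))
  obs
}

#' Fit the allelic-imbalance null model from the interquartile range
#'
#' Most cell-chromosomes are disomic, so residuals between the first and
#' third quartiles are taken as null points: their mean is the null center,
#' and under approximate normality the null SD is
#' `IQR / (2 * qnorm(0.75))` (the middle 50% of a normal spans
#' `2 * sigma * qnorm(0.75)`). Quantiles use the linear-interpolation
#' (type 7) convention.
#'
#' @param residuals numeric vector of depth-adjusted ratios (>= 30 values).
#' @return object of class `mosaiscan_ai_null`: list with `mu_null`,
#'   `sigma_null`, `iqr`, `q1`, `q3`, `n`.
#' @export
fit_null <- function(residuals) {
  residuals <- residuals[!is.na(residuals)]
  if (length(residuals) < 30)
    stop("null fitting needs at least 30 residuals")
  q <- stats::quantile(residuals, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) stop("degenerate null: interquartile range is zero")
  inner <- residuals[residuals >= q[1] & residuals <= q[2]]
  structure(list(
    mu_null = mean(inner),
    sigma_null = iqr / (2 * stats::qnorm(0.75)),
    iqr = iqr, q1 = q[1], q3 = q[2], n = length(residuals)
  ), class = "mosaiscan_ai_null")
}

#' @export
print.mosaiscan_ai_null <- function(x, ...) {
  cat("allelic-imbalance null model (n =", x$n, "):\n")
  cat(sprintf("  mu_null = %.4f, sigma_null = %.4f (IQR = %.4f)\n",
              x$mu_null, x$sigma_null, x$iqr))
  invisible(x)
}

#' One-sided allelic-imbalance p-values
#'
#' Both monosomy and trisomy increase allelic imbalance, i.e. *decrease* the
#' min-allele ratio, so evidence accumulates in the lower tail:
#' `z_ai = (residual - mu_null) / sigma_null` and `p_ai = P(Z <= z_ai)`.
#'
#' @param obs data.frame with a `residual` column.
#' @param null a `mosaiscan_ai_null` from [fit_null()].
#' @return `obs` with `z_ai` and `p_ai` columns appended.
#' @export
ai_pvalues <- function(obs, null) {
  obs$z_ai <- (obs$residual - null$mu_null) / null$sigma_null
  obs$p_ai <- clip_p(stats::pnorm(obs$z_ai))
  obs
}

#' Allelic-imbalance signal, end to end
#'
#' Ratio computation, depth residualization, pooled (global) null fit, and
#' one-sided p-values.
#'
#' @param allelic data.frame from [read_allele_counts()].
#' @param min_reads,min_snps coverage floors per cell-chromosome.
#' @return data.frame with all [chromosome_ai_ratio()] columns plus
#'   `residual`, `z_ai`, `p_ai`; the null model is attached as attribute
#'   `null_model`.
#' @export
allelic_signal <- function(allelic, min_reads = 20, min_snps = 5) {
  obs <- chromosome_ai_ratio(allelic, min_reads, min_snps)
  obs <- residualize_depth(obs)
  null <- fit_null(obs$residual)
  obs <- ai_pvalues(obs, null)
  attr(obs, "null_model") <- null
  obs
}
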