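#' Autosome labels used throughout the package
#'
#' Analysis is restricted to the 22 human autosomes; sex chromosomes are
#' excluded because X-inactivation and hemizygosity confound both the dosage
#' and the allelic-imbalance signatures.
#'
#' @param prefix logical; if `TRUE` return `"chr1"`-style labels, otherwise
#'   bare `"1"`-style labels. Both spellings are accepted on input everywhere.
#' @return character vector of length 22.
#' @export
autosomes <- function(prefix = FALSE) {
  a <- as.character(1:22)
  if (prefix) paste0("chr", a) else a
}

#' Normalize chromosome labels to the bare autosome spelling
#'
#' Strips a leading `"chr"` prefix; labels that are not autosomes map to `NA`.
#'
#' @param x character vector of chromosome labels.
#' @return character vector with entries in `autosomes()` or `NA`.
#' @export
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x))
  x[!x %in% autosomes()] <- NA_character_
  x
}

# Lower clip keeps log(p) finite for Fisher combination; upper clip guards
# rounding past 1.
clip_p <- function(p, lower = 1e-300) pmin(pmax(p, lower), 1)

# Full grid of leaf hypotheses: one test per retained cell x autosome.

#' Enumerate the leaf hypotheses of the selection tree
#'
#' One hypothesis is tested per retained cell and autosome, so a cohort of
#' `n` cells contributes `n * 22` leaf tests regardless of how many of them
#' end up with informative signal.
#'
#' @param cell_ids character vector of retained cell IDs.
#' @param embryo_ids embryo ID per cell (same length as `cell_ids`).
#' @param chromosomes chromosome labels tested per cell.
#' @return data.frame with columns `embryo_id`, `cell_id`, `chromosome`.
#' @export
hypothesis_ledger <- function(cell_ids, embryo_ids = cell_ids,
                              chromosomes = autosomes()) {
  stopifnot(length(embryo_ids) == length(cell_ids), !anyDuplicated(cell_ids))
  out <- data.frame(
    embryo_id = rep(embryo_ids, each = length(chromosomes)),
    cell_id = rep(cell_ids, each = length(chromosomes)),
    chromosome = rep(chromosomes, times = length(cell_ids)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
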