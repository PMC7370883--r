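# Small in-code fixtures shared across test files.

# Deterministic toy count matrix with a gene map; one gene on chrX so the
# autosome-only rule has something to drop.
toy_counts_files <- function(dir) {
  counts <- data.frame(
    gene_id = c("gA", "gB", "gX"),
    cell1 = c(10L, 20L, 5L),
    cell2 = c(30L, 40L, 2L)
  )
  gm <- data.frame(gene_id = c("gA", "gB", "gX"),
                   chromosome = c("chr1", "chr2", "chrX"),
                   is_protein_coding = c(TRUE, TRUE, TRUE))
  meta <- data.frame(cell_id = c("cell1", "cell2"),
                     embryo_id = c("E1", "E1"), stage = 5L,
                     cell_type = "TE", mapped_reads = c(1e5, 2e5),
                     pct_mapped = c(0.8, 0.9))
  paths <- list(counts = file.path(dir, "counts.tsv"),
                gene_map = file.path(dir, "gene_map.tsv"),
                meta = file.path(dir, "meta.tsv"))
  utils::write.table(counts, paths$counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(gm, paths$gene_map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(meta, paths$meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

# Metadata for n cells with given depth metrics, one embryo.
toy_meta <- function(mapped_reads, pct_mapped = rep(0.9, length(mapped_reads))) {
  n <- length(mapped_reads)
  data.frame(cell_id = sprintf("c%02d", seq_len(n)),
             embryo_id = "E1", stage = 5L, cell_type = "TE",
             mapped_reads = mapped_reads, pct_mapped = pct_mapped,
             stringsAsFactors = FALSE)
}

# Hand-rolled truth table (bypasses the lineage layer) for conditioning the
# simulators on chosen copy-number states.
manual_truth <- function(states) {
  # states: named list cell_id -> named int vector chromosome -> copy number
  rows <- lapply(names(states), function(cell) {
    cn <- rep(2L, 22)
    names(cn) <- autosomes()
    cn[names(states[[cell]])] <- states[[cell]]
    data.frame(embryo_id = sub("_c.*", "", cell), cell_id = cell,
               chromosome = autosomes(), copy_number = unname(cn),
               origin = ifelse(cn == 2L, "none", "mitotic"),
               division = NA_integer_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# All-disomic truth over n cells split into embryos of size k.
disomic_truth <- function(n_cells, per_embryo = 8) {
  emb <- sprintf("E%02d", rep(seq_len(ceiling(n_cells / per_embryo)),
                              each = per_embryo)[seq_len(n_cells)])
  cells <- sprintf("%s_c%02d", emb, stats::ave(seq_len(n_cells), emb,
                                               FUN = seq_along))
  data.frame(embryo_id = rep(emb, each = 22), cell_id = rep(cells, each = 22),
             chromosome = rep(autosomes(), n_cells),
             copy_number = 2L, origin = "none", division = NA_integer_,
             stringsAsFactors = FALSE)
}
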