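Package: mosaiscan
Title: Aneuploidy and Mosaicism Inference from Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects whole-chromosome aneuploidies in single-cell RNA-seq data
    by integrating two complementary signatures: chromosome-wide gene expression
    dosage alteration and allelic imbalance at heterozygous SNPs. Per
    cell-chromosome p-values from the two signatures are combined with Fisher's
    method and selected under hierarchical false discovery rate control on the
    embryo-cell-chromosome hypothesis tree (Simes aggregation with
    Benjamini-Hochberg selection at levels adjusted by ancestor selection
    fractions). Selected aneuploidies are classified as monosomy or trisomy by
    2-means clustering of the two Z-scores, and as meiotic or mitotic in origin
    from their prevalence across cells of each embryo. A matched simulator
    generates cohorts with lineage-structured mitotic and embryo-wide meiotic
    errors, overdispersed expression counts, and ploidy-conditioned allelic
    ratios, so every stage of the caller can be benchmarked without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
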