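# mosaiscan

Aneuploidy and mosaicism inference from single-cell RNA-seq of
preimplantation embryos (or any disaggregated multi-cell sample with
per-cell allele counts).

## What problem this solves

Whole-chromosome gains (trisomy) and losses (monosomy) drive most early
human embryonic mortality. Meiotic errors affect every cell of an embryo;
mitotic errors create *mosaicism* — clonal lineages with different
chromosome complements inside one embryo — which biopsy-based testing
(PGT-A) fundamentally cannot census. Single-cell RNA-seq can: chromosome
dosage alters both (1) chromosome-wide expression and (2) the balance of
expression between the two parental haplotypes at heterozygous SNPs.

`mosaiscan` is for computational biologists analyzing disaggregated
single-cell transcriptomes who want per-cell, per-chromosome copy-number
calls with honest error control, plus meiotic/mitotic origin
classification per embryo.

## The method in brief

For cell *i*, chromosome *j*, within a stratum of comparable cells (same
stage and cell type):

* **Dosage score** s<sub>ij</sub> = median over the chromosome's genes of
  CPM<sub>ig</sub> / (leave-one-out median CPM of gene *g*); null value 1,
  ~0.5 under monosomy, ~1.5 under trisomy.
  z<sub>expr</sub> = (s − 1)/(1.4826·MAD); the p-value is an exact
  empirical-binomial tail for the chromosome median (the Gaussian tail of
  a K-gene median is anti-conservative). Evidence is gated on effect size:
  p := 1 unless |1 − s| ≥ 0.2.
* **Allelic imbalance** = Σ min(ref, alt) / Σ (ref + alt) over the
  chromosome's heterozygous SNPs ∈ [0, 0.5]; depth-detrended by OLS on
  log10 reads; null estimated from the interquartile range of residuals,
  σ = IQR/(2·Φ⁻¹(0.75)); one-sided lower-tail p (both monosomy and
  trisomy *decrease* the min-allele ratio).
* **Omnibus**: Fisher's method, χ² = −2(ln p₁ + ln p₂) on 4 df.
* **Selection**: tree-structured Benjamini–Hochberg over
  embryos → cells → chromosomes (Simes aggregation; levels scaled by
  ancestor selection fractions) at 1% FDR per level.
* **Typing**: 2-means on (z<sub>expr</sub>, z<sub>AI</sub>); the lower-Z
  cluster is monosomy. **Origin**: an aneuploidy carried by ≥ 75% of an
  embryo's cells is meiotic, otherwise mitotic (alternative criterion:
  fewer than two normal cells).

A matched simulator plants embryo-wide meiotic and lineage-clonal mitotic
errors, then generates negative-binomial counts and ploidy-conditioned
beta-distributed allelic ratios, so the whole caller is benchmarkable
offline. See the vignette (`vignettes/aneuploidy-inference.Rmd`) for the
full model, parameter table, and design rationale.

## Worked example

```r
library(mosaiscan)

sim <- simulate_cohort(sim_config(seed = 7))   # 20 embryos x 8 cells
res <- run_caller(sim, mode = "combined", fdr = 0.01)
res$selection
#> hierarchical FDR selection at q = 0.01
#>   embryos rejected: 6 of 20
#>   cells rejected:   27 of 160
#>   leaves rejected:  28 of 3520
```

Six embryos harbor at least one aneuploid cell; 28 of 3520 cell-chromosome
tests are called. Each call carries both Z-scores and a type:

```r
head(res$calls[, c("embryo_id","cell_id","chromosome","s","z_expr","z_ai","p","call")], 4)
#>     embryo_id cell_id chromosome    s z_expr   z_ai        p    call
#> 184       E02 E02_c01          8 1.38   5.70 -0.542 2.88e-05 trisomy
#> 250       E02 E02_c04          8 1.62   9.32 -1.190 7.88e-11 trisomy
#> 272       E02 E02_c05          8 1.55   8.24 -2.508 3.25e-10 trisomy
#> 294       E02 E02_c06          8 1.49   7.26 -2.086 1.90e-08 trisomy
```

Embryo E02 carries a chromosome-8 trisomy across its cells (s ≈ 1.5,
depressed min-allele ratios). Scoring against the planted truth and
classifying origins:

```r
score_calls(res, sim$truth)
#>   tp fp   tn fn sensitivity specificity precision fdp_leaf fdp_cell fdp_embryo
#> 1 28  0 3490  2       0.933           1         1        0        0          0

classify_embryo_errors(res$calls, sim$meta)
#> embryo error classification (fraction_75):
#>         both      euploid meiotic_only mitotic_only
#>            1           14            2            3
```

28 of the 30 planted aneuploid cell-chromosomes are recovered with no
false positives; embryos split into euploid, meiotic-only, mitotic-only
and mixed categories.

Real data enter through `read_counts()` (MatrixMarket or wide TSV plus a
gene map and cell metadata), `read_allele_counts()` (ASEReadCounter-style
TSV with a leading `cell_id` column) and `run_pipeline()` /
`run_qc()`, which add depth-based cell filtering and per-stratum gene QC.
A thin command-line front end with `qc`, `call`, `simulate` and
`benchmark` subcommands is installed at `inst/cli/mosaiscan.R`.

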