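---
title: "Detecting aneuploidy and mosaicism in single-cell RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting aneuploidy and mosaicism in single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaiscan)
```

## The inference problem

Whole-chromosome gains (trisomies) and losses (monosomies) are the leading
cause of early embryonic mortality in humans. Meiotic errors arise in the
gametes and affect every cell of the embryo; mitotic errors arise after
fertilization and produce *mosaicism* — clonal lineages with distinct
chromosome complements inside one embryo. Disaggregated single-cell RNA-seq
of embryos offers a way to census both kinds of error at cellular
resolution, because chromosome dosage leaves two independent fingerprints in
a cell's transcriptome:

1. **Expression dosage.** Genes on a monosomic chromosome are transcribed
   from one template instead of two, genes on a trisomic chromosome from
   three. Relative to comparable cells, chromosome-wide expression shifts
   toward 0.5x or 1.5x.
2. **Allelic imbalance.** At heterozygous SNPs, a disomic chromosome
   expresses both parental haplotypes at roughly 1:1. Monosomy makes
   expression monoallelic; trisomy shifts it toward 2:1. Summarizing each
   chromosome by the *min-allele ratio* — the summed minor-allele read count
   divided by the total — gives a statistic in [0, 0.5] that *decreases* as
   imbalance grows, for gains and losses alike.

`mosaiscan` computes both signals per cell-chromosome, combines them into
one omnibus p-value, selects calls under hierarchical FDR control on the
embryo → cell → chromosome hypothesis tree, labels calls monosomy or
trisomy, and classifies each embryo's errors as meiotic or mitotic. A
matched simulator generates cohorts with known planted errors so that every
stage is benchmarkable without any external data.

## The expression dosage score

Cells are first grouped into *strata* of one embryonic stage and one
annotated cell type, since expression baselines are only comparable within
such groups. Within a stratum, for cell $i$ and gene $g$,

$$\rho_{ig} = \frac{\mathrm{CPM}_{ig}}{\mathrm{med}_{i' \ne i}\,\mathrm{CPM}_{i'g}},$$

and the dosage score of chromosome $j$ is the median of $\rho_{ig}$ over
the chromosome's retained genes. The score has null value 1 and moves
toward 0.5 under monosomy and 1.5 under trisomy. Two robustness choices
matter here:

* **Leave-one-out median reference.** A mean reference looks natural but is
  biased for skewed count data: the median of ratios-to-the-mean sits below
  1 (about 0.96 under realistic negative-binomial noise), which shifts the
  whole Z-scale by roughly half a standard deviation. Ratios to the
  leave-one-out *median* have population median 1 by construction, so the
  score is centered without any empirical recentering, and the reference
  stays robust in strata where many cells share an aneuploidy.
* **Center at the theoretical null.** The Z-statistic
  $z_{ij} = (s_{ij} - 1)/\hat\sigma_j$ uses the fixed null center 1 rather
  than the stratum median of scores, so a meiotic aneuploidy shared by many
  cells cannot absorb itself into the center. The scale $\hat\sigma_j$ is
  $1.4826 \times \mathrm{MAD}$ of the stratum's scores for chromosome $j$.

### Why the p-value is not a normal tail

For a median over $K \approx 25$–$200$ genes, the Gaussian approximation is
dangerously anti-conservative in exactly the region FDR selection cares
about: 4 standard deviations of the *median* correspond to less than one
standard deviation of a *single gene ratio*, and the probability that half
the genes jointly exceed such a threshold decays binomially, not like a
Gaussian tail. Empirically this inflates $P(|z| > 4)$ by a factor of 5–8
and pushed realized false discovery proportions above the nominal level.
`expression_pvalues()` therefore computes an exact empirical-binomial tail:
the probability $p_0$ that one gene ratio exceeds the observed score is
estimated from the pooled ratios of the *other* stratum cells (add-one
smoothed), and the p-value is the binomial tail probability that at least
$\lceil K/2 \rceil$ of $K$ genes do so (two-sided, doubled). Contamination
by aneuploid cells inflates $p_0$ slightly and therefore errs conservative.

Finally, dosage evidence is *gated* on effect size: a chromosome only
counts as a candidate when $|1 - s_{ij}| \ge 0.2$, i.e. at least mid-way
toward the monosomy/trisomy expectation; otherwise its expression p-value
is set to 1. This suppresses statistically crisp but biologically
irrelevant fluctuations (and most segmental events, which this package does
not attempt to distinguish from whole-chromosome aneuploidy).

## The allelic imbalance Z-score

Per cell-chromosome, the min-allele ratio is
$\sum_k \min(\mathrm{ref}_k, \mathrm{alt}_k) / \sum_k (\mathrm{ref}_k +
\mathrm{alt}_k)$ over heterozygous SNPs, retained when at least 20 reads
and 5 SNPs contribute (configurable floors; without them the ratio's
variance explodes). Because shallowly covered chromosomes look spuriously
imbalanced, the ratio is regressed on $\log_{10}$ total reads (ordinary
least squares, pooled across the whole data set) and the analysis continues
on residuals. Most cell-chromosomes are disomic, so residuals between the
first and third quartile are treated as null points: their mean is the null
center, and under approximate normality the null SD is

$$\hat\sigma_{\mathrm{null}} = \frac{\mathrm{IQR}}{2\,\Phi^{-1}(0.75)},$$

the middle 50% of a normal spanning $2\sigma\Phi^{-1}(0.75)$. P-values are
one-sided lower tails of $z = (\mathrm{residual} - \hat\mu)/\hat\sigma$,
since both monosomy and trisomy decrease the min-allele ratio. The null is
fitted once, pooled across the whole data set — one empirical distribution,
matching the assumption that most cell-chromosomes are disomic regardless
of stratum; `residualize_depth()`, `fit_null()` and `ai_pvalues()` are
exported separately so a per-group fit remains a three-line variation.
Quantiles use the type-7 linear-interpolation convention
throughout the package, and all p-values are clipped to $[10^{-300}, 1]$ so
their logarithms stay finite in Fisher's statistic.

Monoallelic chromosomes give $z$ around $-7$ and vanishing p-values, which
is what makes genome-wide monoallelic (haploid-like) cells detectable even
though their expression signal has no baseline to deviate from.

## Omnibus test and hierarchical selection

The two p-values are combined with Fisher's method,
$\chi^2 = -2(\ln p_{\mathrm{expr}}^{\mathrm{gated}} + \ln p_{\mathrm{AI}})$
against the $\chi^2_4$ upper tail. When only one signal exists for a leaf
(no SNP coverage, or expression-only mode) the available p-value carries
through unchanged — the $\chi^2_2$ case — rather than dropping the leaf,
which would silently bias per-cell aneuploidy counts.

Every retained cell tests all 22 autosomes (sex chromosomes are excluded:
X-inactivation and hemizygosity confound both signals), so a cohort of
1115 cells poses 24,530 correlated hypotheses. Selection uses
tree-structured Benjamini–Hochberg control: child p-values aggregate to
parents by Simes' rule; embryos are selected by BH at level $q$ (default
0.01); cells within selected embryos at $q \cdot R_1/m_1$; chromosomes
within selected cells at $q \cdot (R_1/m_1)(R_{2e}/m_{2e})$, the ancestor
selection fractions. A leaf can be rejected only when its cell and embryo
are, and rejection sets are nested in $q$. Simes aggregation and the
product-of-fractions level adjustment are this package's fixed contract for
the procedure's internals.

Selected leaves are labeled by 2-means clustering on $(z_{\mathrm{expr}},
z_{\mathrm{AI}})$ with deterministic initialization (componentwise min and
max); the cluster with the lower mean Z is monosomy. With fewer than three
rejected leaves, or identical points, the label falls back to the sign of
$z_{\mathrm{expr}}$ (then $z_{\mathrm{AI}}$): a forced 2-way split of two
same-type leaves would always mislabel one, and Hartigan–Wong requires
more points than centers anyway. A missing coordinate is imputed to 0 for
clustering only.

## Meiotic versus mitotic origin

Within each embryo with at least two retained cells, each *particular
aneuploidy* — a (chromosome, gain-or-loss) pair — is classified meiotic
when at least 75% of the embryo's cells carry it (`fraction_75`, the
default; the threshold allows for false negatives), or alternatively when
fewer than two of the embryo's cells are normal for that chromosome
(`lt2_normal`). A chromosome carrying reciprocal monosomies and trisomies
in different cells — the signature of mitotic nondisjunction — counts as
two mitotic events, never one meiotic one. The denominator of the 75% rule
is all retained cells of the embryo by default; a flag restricts it to
cells with callable (non-missing) data for that chromosome, since either
reading is defensible. Embryos with fewer than two cells are
`indeterminate`: clonality is meaningless for a single cell.

## The simulator

`simulate_cohort()` generates a full cohort with known truth:

* **Lineage layer.** Each embryo starts disomic; with probability 0.2 a
  meiotic gain or loss is planted on a random chromosome in every cell.
  Cells then arise from a balanced binary division tree; each division
  carries a 0.05 probability of a mitotic gain/loss propagated to one
  daughter lineage, with probability 0.5 of the reciprocal event in the
  sister lineage (mitotic nondisjunction). Events that would push a copy
  number outside {1, 2, 3} are skipped.
* **Expression layer.** Per-gene baseline means are log-normal
  (meanlog = log 50, sdlog = 1 over 40 genes per autosome); counts are
  negative-binomial with mean baseline x (copy number / 2) x a log-normal
  cell size factor (sdlog 0.2) and size parameter 10 at overdispersion 1.
  The overdispersion factor scales the extra-Poisson variance component
  (size = 10 / factor): a total-variance reading cannot drop below the
  Poisson floor for factors < 1.
* **Allelic layer.** Per cell-chromosome, a target min-allele ratio is
  drawn from a per-ploidy beta distribution — disomy mean 0.38 / SD 0.06,
  trisomy 0.28 / 0.07, monosomy 0.02 / 0.02, package defaults on the scale
  of observed blastocyst ratios, refittable from data with
  `estimate_sim_params()` — with variance scaled by the overdispersion
  factor and capped below the beta feasibility bound. Thirty SNPs per
  chromosome receive negative-binomial depths (mean 40, Smart-Seq2-like
  full-transcript coverage, deep enough that the count layer can realize
  the stated ratio distributions), and minor-allele reads are allocated
  proportionally with stochastic rounding, so the chromosome-level
  min-ratio equals the drawn target in expectation at every feasible
  value. The beta is treated as describing *observed* ratios, i.e. it
  already carries the technical variance: resampling each SNP binomially
  on top would double-count that variance, and the min() collapse would
  additionally bias ratios near 0.5 downward (at finite depth a binomial
  chromosome cannot average a min-ratio above roughly
  $1/2 - 0.4/\sqrt{d}$).

What the simulator does **not** emulate: doublets, ambient RNA, segmental
CNVs, X-inactivation, allele-specific expression bursting, reference
mapping bias at SNPs, or stage/cell-type expression heterogeneity (a
simulated cohort is one stratum). Passing benchmarks therefore demonstrate
the statistical machinery under the stated generative model, not
performance on any particular real data set.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `cell_depth_quantile` | 0.10 | cells strictly below this type-7 quantile of mapped reads *or* percent mapped are removed (union) |
| `min_median_cpm` | 50 CPM | per-stratum gene filter on median CPM (CPM computed on the full autosome gene set, before stratum subsetting) |
| `min_genes` | 2000 | strata retaining fewer genes fail QC; separates usable groups (~3000+ genes in practice) from failed ones |
| `min_genes_per_chrom` | 25 | median-of-ratios stability floor per chromosome |
| `min_reads`, `min_snps` | 20, 5 | allelic coverage floors per cell-chromosome |
| `effect_threshold` | 0.2 | dosage effect gate on \|1 - s\| |
| `fdr_level` | 0.01 | nominal FDR at every tree level |
| `meiotic_cutoff` | 0.75 | carrier fraction for meiotic origin |

## Numerical conventions and degenerate inputs

Type-7 quantiles everywhere; strict inequality in the depth filter (both
exposed, since conventions are rarely stated by data descriptions);
p-values clipped to $[10^{-300}, 1]$; zero-MAD chromosomes emit a warning
and p = 1; a zero leave-one-out reference excludes that gene for that cell
rather than introducing a pseudocount that would bias the score; an
all-equal-depth allelic table falls back to mean-centering with a warning;
a zero IQR aborts null fitting; hierarchical clustering uses Euclidean
distance with average linkage and imputes missing signatures to the null
value (0 for Z-scores, 1 for scores). All simulator randomness flows from
one integer seed; replicate seeds are derived deterministically from it.

## Problem sizes used by the test-suite benchmarks

The packaged checks run desk-scale versions of the benchmarks: FDR
calibration uses 100 replicates of 12-embryo x 8-cell cohorts; the
sensitivity comparison of combined versus expression-only calling uses 15
replicates at each overdispersion factor in {0.3, 1, 5}; calibration checks
use euploid cohorts of ~130–260 cells (about 3000–5600 cell-chromosomes).
The acceptance script uses 100 replicates of 20 x 8 cohorts. These sizes
are the package's chosen trade-off between Monte-Carlo error and runtime;
all of them are parameters of `sim_config()`/`run_benchmark()` and scale up
freely.

## Known limitations

* Segmental (sub-chromosomal) events are not distinguished from
  whole-chromosome aneuploidy; large structural variants can be
  misclassified as aneuploidy.
* No haplotype phasing: trisomy detection from allelic imbalance relies on
  the 2:1 shift alone, which is much subtler than the monoallelic signature
  of monosomy — the allelic signal is correspondingly more sensitive for
  losses than gains.
* Uniparental diploidy is indistinguishable from haploidy: both are
  genome-wide monoallelic.
* A genome-wide aneuploid cell (e.g. haploid) offers no within-cell
  expression baseline; such cells are detectable through allelic imbalance
  only.
* The expression signal needs a stratum of comparable cells; strata that
  fail QC (too few well-expressed genes, fewer than 2 cells) contribute no
  calls, and their absence should be reported alongside results.
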