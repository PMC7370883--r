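#' Simulation configuration
#'
#' Defaults describe a desk-scale cohort of preimplantation-like embryos:
#' 20 embryos of 8 cells each, an embryo-wide meiotic error probability of
#' 0.2, a mitotic (post-zygotic) error probability of 0.05 per cell
#' division, 40 informative genes per autosome with log-normal baseline
#' expression and negative-binomial counts, and 30 expressed heterozygous
#' SNPs per chromosome. Per-ploidy allelic-ratio beta parameters (disomy
#' mean 0.38 / SD 0.06, trisomy 0.28 / 0.07, monosomy 0.02 / 0.02) are
#' package defaults on the scale observed in blastocyst-stage scRNA-seq
#' data; [estimate_sim_params()] re-fits them from data when available.
#'
#' @param n_embryos,cells_per_embryo cohort shape.
#' @param p_meiotic probability an embryo carries a meiotic error.
#' @param p_mitotic probability of a mitotic error at each cell division.
#' @param p_reciprocal given a mitotic event, probability that the sister
#'   lineage receives the reciprocal event (mitotic nondisjunction).
#' @param genes_per_chrom genes simulated per autosome.
#' @param base_meanlog,base_sdlog log-normal parameters of per-gene baseline
#'   mean counts.
#' @param nb_size negative-binomial size (inverse dispersion) at
#'   overdispersion factor 1.
#' @param sf_sdlog log-normal SD of per-cell size factors.
#' @param n_snps_per_chrom,snp_depth_mean,snp_depth_size heterozygous SNPs
#'   per chromosome and the negative-binomial parameters of per-SNP depth
#'   (shifted by +1 so every SNP has coverage). The default depth (mean 40,
#'   full-transcript coverage) is deep enough that the binomial sampling
#'   layer can realize the per-ploidy observed-ratio distributions; at much
#'   shallower depths a chromosome-level min-ratio near 0.5 is unreachable.
#' @param beta_params named list (`disomy`, `trisomy`, `monosomy`) of
#'   `c(mean, sd)` for the per-ploidy allelic-ratio beta distributions.
#' @param overdispersion variance scaling factor for both signatures.
#' @param seed integer seed.
#' @return list of class `mosaiscan_sim_config`.
#' @export
sim_config <- function(n_embryos = 20, cells_per_embryo = 8,
                       p_meiotic = 0.2, p_mitotic = 0.05,
                       p_reciprocal = 0.5, genes_per_chrom = 40,
                       base_meanlog = log(50), base_sdlog = 1,
                       nb_size = 10, sf_sdlog = 0.2,
                       n_snps_per_chrom = 30, snp_depth_mean = 40,
                       snp_depth_size = 2,
                       beta_params = list(disomy = c(mean = 0.38, sd = 0.06),
                                          trisomy = c(mean = 0.28, sd = 0.07),
                                          monosomy = c(mean = 0.02, sd = 0.02)),
                       overdispersion = 1, seed = 1L) {
  cfg <- as.list(environment())
  for (b in cfg$beta_params) {
    m <- b[["mean"]]
    if (m <= 0 || m >= 0.5) stop("beta means must lie in (0, 0.5)")
    if (b[["sd"]]^2 >= m * (1 - m)) stop("infeasible beta variance")
  }
  if (cfg$overdispersion <= 0) stop("overdispersion must be positive")
  structure(cfg, class = "mosaiscan_sim_config")
}

#' Plant meiotic and lineage-structured mitotic errors
#'
#' Each embryo starts disomic on all 22 autosomes. With probability
#' `p_meiotic` a random chromosome gains or loses one copy in every cell
#' (meiotic origin). Cells then arise from a balanced binary division tree;
#' at each division, with probability `p_mitotic`, a random chromosome gains
#' or loses a copy in one daughter lineage (propagating to all its
#' descendants), and with probability `p_reciprocal` the sister lineage
#' receives the opposite event, mimicking mitotic nondisjunction. Events
#' that would push a copy number outside \{1, 2, 3\} are skipped.
#'
#' @param config a `mosaiscan_sim_config`.
#' @return data.frame (the truth table) with one row per
#'   (embryo, cell, chromosome): `embryo_id`, `cell_id`, `chromosome`,
#'   `copy_number`, `origin` in none/meiotic/mitotic, and `division` (the
#'   division at which a mitotic event arose, `NA` otherwise).
#' @export
simulate_ploidy_states <- function(config) {
  chrs <- autosomes()
  res <- vector("list", config$n_embryos)
  n_cells <- config$cells_per_embryo
  depth <- ceiling(log2(max(n_cells, 2)))
  for (e in seq_len(config$n_embryos)) {
    eid <- sprintf("E%02d", e)
    cn <- matrix(2L, n_cells, 22, dimnames = list(NULL, chrs))
    origin <- matrix("none", n_cells, 22, dimnames = list(NULL, chrs))
    division <- matrix(NA_integer_, n_cells, 22)

    if (stats::runif(1) < config$p_meiotic) {
      j <- sample(22, 1)
      delta <- sample(c(-1L, 1L), 1)
      cn[, j] <- 2L + delta
      origin[, j] <- "meiotic"
    }

    # Balanced binary tree over 2^depth leaf slots; cells are the first
    # n_cells slots. At division d, leaf slots split into 2^d sibling blocks.
    n_slots <- 2^depth
    apply_event <- function(slots, j, delta, d) {
      slots <- slots[slots <= n_cells]
      if (length(slots) == 0) return(invisible(NULL))
      ok <- cn[slots, j] + delta >= 1L & cn[slots, j] + delta <= 3L
      if (!all(ok)) return(invisible(NULL)) # event would leave {1,2,3}
      cn[slots, j] <<- cn[slots, j] + delta
      origin[slots, j] <<- "mitotic"
      division[slots, j] <<- d
      invisible(NULL)
    }
    for (d in seq_len(depth)) {
      block <- n_slots / 2^d # slots per daughter lineage at this division
      for (node in seq_len(2^(d - 1))) {
        if (stats::runif(1) >= config$p_mitotic) next
        j <- sample(22, 1)
        delta <- sample(c(-1L, 1L), 1)
        left <- ((node - 1) * 2 * block + 1):((node - 1) * 2 * block + block)
        right <- left + block
        if (stats::runif(1) < 0.5) {
          daughter <- left; sister <- right
        } else {
          daughter <- right; sister <- left
        }
        apply_event(daughter, j, delta, d)
        if (stats::runif(1) < config$p_reciprocal)
          apply_event(sister, j, -delta, d)
      }
    }

    res[[e]] <- data.frame(
      embryo_id = eid,
      cell_id = sprintf("%s_c%02d", eid, rep(seq_len(n_cells), each = 22)),
      chromosome = rep(chrs, times = n_cells),
      copy_number = as.integer(t(cn)),
      origin = as.character(t(origin)),
      division = as.integer(t(division)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simulate expression counts conditional on ploidy states
#'
#' Per-gene baseline means are drawn once per cohort from a log-normal;
#' counts are negative-binomial with mean
#' `baseline x (copy_number / 2) x cell size factor`. The overdispersion
#' factor scales the extra-Poisson component of the variance (size
#' parameter `nb_size / overdispersion`), so larger factors give noisier
#' counts at unchanged means.
#'
#' @param truth truth table from [simulate_ploidy_states()].
#' @param config a `mosaiscan_sim_config`.
#' @param overdispersion variance scaling factor; default from `config`.
#' @return list with `counts` (genes x cells integer matrix), `gene_map`,
#'   and `meta` (stage/cell-type constants, `mapped_reads` = column sums).
#' @export
simulate_expression <- function(truth, config,
                                overdispersion = config$overdispersion) {
  if (config$genes_per_chrom < 1) stop("no genes configured")
  chrs <- autosomes()
  gene_map <- data.frame(
    gene_id = sprintf("g%s_%03d", rep(chrs, each = config$genes_per_chrom),
                      rep(seq_len(config$genes_per_chrom), times = 22)),
    chromosome = rep(chrs, each = config$genes_per_chrom),
    is_protein_coding = TRUE, stringsAsFactors = FALSE
  )
  cells <- unique(truth$cell_id)
  base <- stats::rlnorm(nrow(gene_map), config$base_meanlog, config$base_sdlog)
  sf <- stats::rlnorm(length(cells), 0, config$sf_sdlog)
  size <- config$nb_size / overdispersion

  cn <- matrix(truth$copy_number[order(match(truth$cell_id, cells),
                                       match(truth$chromosome, chrs))],
               nrow = 22, dimnames = list(chrs, cells))
  dose <- cn[gene_map$chromosome, , drop = FALSE] / 2
  mu <- (base * dose) * rep(sf, each = nrow(gene_map))
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = size),
    nrow = nrow(gene_map),
    dimnames = list(gene_map$gene_id, cells)
  )
  storage.mode(counts) <- "integer"
  meta <- data.frame(
    cell_id = cells,
    embryo_id = truth$embryo_id[match(cells, truth$cell_id)],
    stage = 5L, cell_type = "simulated",
    mapped_reads = colSums(counts), pct_mapped = 0.9,
    stringsAsFactors = FALSE
  )
  list(counts = counts, gene_map = gene_map, meta = meta)
}

# Beta shape parameters from a target mean and variance (method of moments).
beta_shapes <- function(mean, var) {
  stopifnot(var > 0, var < mean * (1 - mean))
  nu <- mean * (1 - mean) / var - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Simulate per-SNP allele counts conditional on ploidy states
#'
#' For each cell-chromosome a target min-allele ratio is drawn from the
#' ploidy-state-specific beta distribution, with its variance scaled by the
#' overdispersion factor (capped below the beta feasibility bound
#' `0.95 m (1 - m)` with a warning). Per-SNP depths are negative-binomial
#' (+1); minor-allele counts are allocated proportionally to depth with
#' stochastic rounding (`floor(d r)` plus a Bernoulli on the fractional
#' part), so the chromosome-level min-ratio matches the drawn target in
#' expectation at every feasible target. The fitted beta already carries
#' the full (biological plus technical) variance of observed ratios, so no
#' further count-level noise is layered on top: naive binomial resampling
#' of each SNP would both double-count that variance and bias ratios near
#' 0.5 downward through the min() collapse.
#'
#' @param truth truth table from [simulate_ploidy_states()].
#' @param config a `mosaiscan_sim_config`.
#' @param overdispersion variance scaling factor; default from `config`.
#' @return data.frame in the [read_allele_counts()] layout: `cell_id`,
#'   `chromosome`, `position`, `ref_count`, `alt_count`.
#' @export
simulate_allelic <- function(truth, config,
                             overdispersion = config$overdispersion) {
  state <- c("1" = "monosomy", "2" = "disomy", "3" = "trisomy")
  st <- state[as.character(truth$copy_number)]
  target <- numeric(nrow(truth))
  capped <- FALSE
  for (s in unique(st)) {
    b <- config$beta_params[[s]]
    v <- b[["sd"]]^2 * overdispersion
    vmax <- 0.95 * b[["mean"]] * (1 - b[["mean"]])
    if (v >= vmax) {
      v <- vmax
      capped <- TRUE
    }
    sh <- beta_shapes(b[["mean"]], v)
    idx <- st == s
    target[idx] <- stats::rbeta(sum(idx), sh["alpha"], sh["beta"])
  }
  if (capped)
    warning("beta variance capped at the feasibility bound after scaling")

  k <- config$n_snps_per_chrom
  n <- nrow(truth)
  depth <- stats::rnbinom(n * k, mu = config$snp_depth_mean,
                          size = config$snp_depth_size) + 1L
  r <- rep(target, each = k)
  exp_minor <- depth * r
  minor <- floor(exp_minor) +
    stats::rbinom(n * k, 1L, exp_minor - floor(exp_minor))
  # randomize which allele is the minor one per SNP
  flip <- stats::runif(n * k) < 0.5
  alt <- ifelse(flip, minor, depth - minor)
  data.frame(
    cell_id = rep(truth$cell_id, each = k),
    chromosome = rep(truth$chromosome, each = k),
    position = rep(seq_len(k) * 1000L, times = n),
    ref_count = as.integer(depth - alt),
    alt_count = as.integer(alt),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full cohort with known truth
#'
#' @param config a `mosaiscan_sim_config`.
#' @param overdispersion variance scaling factor; default from `config`.
#' @param seed integer seed; default from `config`. All randomness in the
#'   cohort flows from this single seed.
#' @return list of class `mosaiscan_sim`: `counts`, `gene_map`, `meta`,
#'   `allelic`, `truth`, `config`, `overdispersion`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            overdispersion = config$overdispersion,
                            seed = config$seed) {
  set.seed(seed)
  truth <- simulate_ploidy_states(config)
  expr <- simulate_expression(truth, config, overdispersion)
  allelic <- simulate_allelic(truth, config, overdispersion)
  structure(list(counts = expr$counts, gene_map = expr$gene_map,
                 meta = expr$meta, allelic = allelic, truth = truth,
                 config = config, overdispersion = overdispersion),
            class = "mosaiscan_sim")
}

#' Estimate simulation parameters from observed signals
#'
#' Method-of-moments fits, stratified by ploidy state: the mean and variance
#' of the allelic-imbalance ratio per state, and a pooled per-gene
#' extra-Poisson dispersion estimate for expression. States with fewer than
#' `min_n` observations fall back to the defaults in `config`.
#'
#' @param ai_obs data.frame with `ai_ratio` and a `state` column in
#'   monosomy/disomy/trisomy (e.g. calls joined to [chromosome_ai_ratio()]
#'   output, or simulator truth).
#' @param counts optional gene-by-cell count matrix for the expression
#'   dispersion estimate.
#' @param config defaults to fall back on; default [sim_config()].
#' @param min_n minimum observations per state; default 30.
#' @return list with `beta_params` (per-state `c(mean, sd)`) and `nb_size`.
#' @export
estimate_sim_params <- function(ai_obs, counts = NULL, config = sim_config(),
                                min_n = 30) {
  beta_params <- config$beta_params
  names(beta_params) <- names(config$beta_params)
  for (s in c("monosomy", "disomy", "trisomy")) {
    x <- ai_obs$ai_ratio[ai_obs$state == s]
    x <- x[!is.na(x)]
    if (length(x) < min_n) {
      warning("fewer than ", min_n, " observations for state '", s,
              "'; keeping default parameters")
      next
    }
    v <- stats::var(x)
    if (v == 0) stop("degenerate ratios (zero variance) for state '", s, "'")
    beta_params[[s]] <- c(mean = mean(x), sd = sqrt(v))
  }
  nb_size <- config$nb_size
  if (!is.null(counts)) {
    mu <- rowMeans(counts)
    v <- apply(counts, 1, stats::var)
    ok <- mu > 1 & v > mu
    if (sum(ok) >= 10)
      nb_size <- 1 / stats::median((v[ok] - mu[ok]) / mu[ok]^2)
  }
  list(beta_params = beta_params, nb_size = nb_size)
}
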