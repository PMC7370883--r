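test_that("cohort simulation is deterministic given config and seed", {
  cfg <- sim_config(n_embryos = 3, cells_per_embryo = 8)
  a <- simulate_cohort(cfg, seed = 101)
  b <- simulate_cohort(cfg, seed = 101)
  expect_identical(a$counts, b$counts)
  expect_identical(a$allelic, b$allelic)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(cfg, seed = 102)
  expect_false(identical(a$counts, c$counts))
})

test_that("planted error structure follows the lineage model", {
  # zero error probabilities: everything disomic
  cfg0 <- sim_config(n_embryos = 4, p_meiotic = 0, p_mitotic = 0)
  t0 <- simulate_cohort(cfg0, seed = 103)$truth
  expect_true(all(t0$copy_number == 2L))
  expect_true(all(t0$origin == "none"))

  # meiotic errors cover every cell of the embryo
  cfg1 <- sim_config(n_embryos = 20, p_meiotic = 1, p_mitotic = 0)
  t1 <- simulate_cohort(cfg1, seed = 104)$truth
  mei <- t1[t1$origin == "meiotic", ]
  cover <- tapply(mei$cell_id, paste(mei$embryo_id, mei$chromosome),
                  function(x) length(unique(x)))
  expect_true(all(cover == 20 * 8 / 20)) # all 8 cells per embryo
  expect_true(all(mei$copy_number %in% c(1L, 3L)))

  # mitotic errors at division d of a balanced 8-cell tree affect 8/2^d
  # cells (checked on events that did not stack with others)
  cfg2 <- sim_config(n_embryos = 60, p_meiotic = 0, p_mitotic = 0.08,
                     p_reciprocal = 0)
  t2 <- simulate_cohort(cfg2, seed = 105)$truth
  mit <- t2[t2$origin == "mitotic", ]
  groups <- split(mit, paste(mit$embryo_id, mit$chromosome))
  checked <- 0
  for (g in groups) {
    if (length(unique(g$division)) == 1 &&
        length(unique(g$copy_number)) == 1) {
      expect_equal(nrow(g), 8 / 2^g$division[1])
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})

test_that("expression counts scale with chromosome dosage", {
  states <- list()
  for (i in 1:12) {
    cn <- c("5" = if (i <= 4) 1L else if (i <= 8) 2L else 3L)
    states[[sprintf("E01_c%02d", i)]] <- cn
  }
  truth <- manual_truth(states)
  cfg <- sim_config(genes_per_chrom = 200, sf_sdlog = 0)
  set.seed(107)
  expr <- simulate_expression(truth, cfg)
  cpm <- cpm_normalize(expr$counts)
  chr5 <- expr$gene_map$chromosome == "5"
  chr5_share <- colSums(cpm[chr5, ]) / 1e6
  mono <- mean(chr5_share[1:4])
  di <- mean(chr5_share[5:8])
  tri <- mean(chr5_share[9:12])
  expect_equal(mono / di, 0.5, tolerance = 0.1)
  expect_equal(tri / di, 1.5, tolerance = 0.1)

  # overdispersion monotonicity: paired per-gene variance comparison
  set.seed(109)
  t_dis <- disomic_truth(40)
  lo <- simulate_expression(t_dis, cfg, overdispersion = 0.3)$counts
  set.seed(109)
  hi <- simulate_expression(t_dis, cfg, overdispersion = 5)$counts
  v_lo <- apply(lo, 1, stats::var)
  v_hi <- apply(hi, 1, stats::var)
  expect_gt(mean(v_hi > v_lo), 0.95)

  expect_error(simulate_expression(truth, sim_config(genes_per_chrom = 0)),
               "no genes")
})

test_that("beta moment matching recovers target moments", {
  sh <- mosaiscan:::beta_shapes(0.4, 0.01)
  expect_equal(unname(sh["alpha"]), 9.2)
  expect_equal(unname(sh["beta"]), 13.8)
  set.seed(113)
  draws <- stats::rbeta(1e5, sh["alpha"], sh["beta"])
  expect_equal(mean(draws), 0.4, tolerance = 0.01)
  expect_equal(stats::var(draws), 0.01, tolerance = 0.05)
  expect_error(mosaiscan:::beta_shapes(0.4, 0.3), "var")
})

test_that("allelic simulation tracks ploidy-specific ratio distributions", {
  set.seed(127)
  states <- lapply(1:30, function(i) c("7" = 1L))
  names(states) <- sprintf("E01_c%02d", 1:30)
  truth <- manual_truth(states)
  cfg <- sim_config()
  ase <- simulate_allelic(truth, cfg)
  obs <- chromosome_ai_ratio(ase)
  mono <- obs$ai_ratio[obs$chromosome == "7"]
  expect_gte(min(mono), 0)
  expect_lte(mean(mono), 0.06) # nearly monoallelic
  di <- obs$ai_ratio[obs$chromosome != "7"]
  expect_equal(mean(di), cfg$beta_params$disomy[["mean"]], tolerance = 0.02)

  # overdispersion scales the drawn ratio variance
  set.seed(131)
  t_dis <- disomic_truth(60)
  v <- vapply(c(0.5, 2), function(od) {
    a <- simulate_allelic(t_dis, cfg, overdispersion = od)
    stats::var(chromosome_ai_ratio(a)$ai_ratio)
  }, numeric(1))
  expect_gt(v[2] / v[1], 2.5) # nominal factor 4, allow sampling noise
})

test_that("simulation parameters are recoverable from generated ratios", {
  set.seed(137)
  states <- lapply(1:60, function(i) {
    cn <- sample(1:3, 22, replace = TRUE, prob = c(0.2, 0.6, 0.2))
    names(cn) <- autosomes()
    cn
  })
  names(states) <- sprintf("E%02d_c%02d", rep(1:6, each = 10), 1:60)
  truth <- manual_truth(states)
  cfg <- sim_config()
  obs <- chromosome_ai_ratio(simulate_allelic(truth, cfg))
  key <- paste(obs$cell_id, obs$chromosome)
  tkey <- paste(truth$cell_id, truth$chromosome)
  obs$state <- c("monosomy", "disomy", "trisomy")[
    truth$copy_number[match(key, tkey)]]
  est <- estimate_sim_params(obs, config = cfg)
  for (s in c("disomy", "trisomy", "monosomy")) {
    expect_equal(est$beta_params[[s]][["mean"]],
                 cfg$beta_params[[s]][["mean"]], tolerance = 0.02)
    expect_equal(est$beta_params[[s]][["sd"]]^2,
                 cfg$beta_params[[s]][["sd"]]^2, tolerance = 0.35)
  }

  # under-populated stratum falls back to defaults with a warning
  few <- obs[obs$state != "monosomy", ]
  expect_warning(est2 <- estimate_sim_params(few, config = cfg),
                 "monosomy")
  expect_equal(est2$beta_params$monosomy, cfg$beta_params$monosomy)

  # degenerate constant ratios
  const <- obs
  const$ai_ratio <- 0.3
  expect_error(estimate_sim_params(const, config = cfg), "degenerate")
})

test_that("a tiny benchmark runs end-to-end quickly in both modes", {
  t0 <- Sys.time()
  bm <- run_benchmark(sim_config(n_embryos = 4, cells_per_embryo = 8,
                                 seed = 5L),
                      overdispersions = 1, n_replicates = 1)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 30)
  expect_setequal(bm$replicates$mode, c("combined", "expression_only"))
  with(bm$replicates,
       expect_true(all(tp + fp + tn + fn == 4 * 8 * 22)))

  # all-null run: no planted errors, sensitivity undefined (NA)
  bm0 <- run_benchmark(sim_config(n_embryos = 4, cells_per_embryo = 8,
                                  p_meiotic = 0, p_mitotic = 0, seed = 6L),
                       overdispersions = 1, n_replicates = 1,
                       modes = "combined")
  expect_true(is.na(bm0$replicates$sensitivity))
  expect_lte(bm0$replicates$fdp_leaf, 0.01)
})
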