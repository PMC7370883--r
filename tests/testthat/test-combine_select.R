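test_that("effect-size gating neutralizes small dosage deviations", {
  expect_equal(gate_expression_p(0.5, 1e-6), 1e-6)
  expect_equal(gate_expression_p(1.1, 0.001), 1)
  expect_equal(gate_expression_p(0.8, 0.003), 0.003) # boundary is inclusive
  expect_equal(gate_expression_p(c(0.5, 1.05), c(0.01, 0.01)), c(0.01, 1))
})

test_that("Fisher combination matches the df-4 closed form", {
  expect_equal(fisher_combine(1, 1), 1)
  closed <- function(p1, p2) {
    x <- -2 * (log(p1) + log(p2))
    exp(-x / 2) * (1 + x / 2)
  }
  expect_equal(fisher_combine(0.05, 0.05), closed(0.05, 0.05))
  expect_equal(round(fisher_combine(0.05, 0.05), 5), 0.01748)
  expect_equal(round(fisher_combine(1, 0.5), 4), 0.8466)
  for (p in list(c(0.3, 0.7), c(1e-8, 0.2), c(0.99, 0.01)))
    expect_equal(fisher_combine(p[1], p[2]), closed(p[1], p[2]))
  # single-signal fallback carries the available p through
  expect_equal(fisher_combine(NA, 0.2), 0.2)
  expect_equal(fisher_combine(0.07, NA), 0.07)
  expect_true(is.na(fisher_combine(NA, NA)))
})

test_that("Fisher combination of independent uniforms is uniform", {
  set.seed(37)
  p <- fisher_combine(stats::runif(10000), stats::runif(10000))
  ks <- stats::ks.test(p, "punif")
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("Simes aggregation follows the sorted-minimum rule", {
  expect_equal(simes_p(c(0.001, 0.8)), 0.002)
  expect_equal(simes_p(c(0.8, 0.001)), 0.002) # order-free
  expect_equal(simes_p(rep(1, 5)), 1)
  expect_equal(simes_p(0.123), 0.123)
  set.seed(43)
  for (i in 1:20) {
    p <- stats::runif(sample(2:10, 1))
    expect_equal(simes_p(p),
                 min(1, min(length(p) * sort(p) / seq_along(p))))
  }
})

worked_leaves <- function() {
  data.frame(
    embryo_id = c("A", "A", "A", "A", "B", "B"),
    cell_id = c("A1", "A1", "A2", "A2", "B1", "B1"),
    chromosome = c("1", "2", "1", "2", "1", "2"),
    p = c(0.001, 0.8, 0.7, 0.9, 1, 1),
    stringsAsFactors = FALSE
  )
}

test_that("the hierarchical selection worked example is reproduced exactly", {
  sel <- treebh_select(worked_leaves(), q = 0.01)
  expect_equal(sel$cells$p[sel$cells$cell_id == "A1"], 0.002)
  expect_equal(sel$cells$p[sel$cells$cell_id == "A2"], 0.9)
  expect_equal(sel$embryos$p[sel$embryos$embryo_id == "A"], 0.004)
  expect_equal(sel$embryos$rejected,
               sel$embryos$embryo_id == "A")
  expect_equal(sel$cells$rejected, sel$cells$cell_id == "A1")
  # adjusted levels: 0.01 * 1/2 for cells, * 1/2 again for leaves
  expect_equal(unique(sel$cells$level[sel$cells$embryo_id == "A"]), 0.005)
  expect_equal(unique(stats::na.omit(sel$leaves$leaf_level)), 0.0025)
  expect_equal(sum(sel$leaves$rejected_leaf), 1)
  expect_true(sel$leaves$rejected_leaf[sel$leaves$p == 0.001])
})

test_that("all-null trees yield no rejections and q = 1 bounds error", {
  leaves <- worked_leaves()
  leaves$p <- 1
  sel <- treebh_select(leaves, 0.01)
  expect_equal(sum(sel$leaves$rejected_leaf), 0)
  expect_equal(sum(sel$embryos$rejected), 0)
  expect_error(treebh_select(leaves, 0), "q must")
  expect_error(treebh_select(leaves, 1), "q must")
})

random_tree <- function(n_embryos = 5, cells = 2, chroms = 5,
                        signal = 0.3) {
  led <- hypothesis_ledger(
    cell_ids = sprintf("e%d_c%d", rep(1:n_embryos, each = cells),
                       rep(1:cells, n_embryos)),
    embryo_ids = sprintf("e%d", rep(1:n_embryos, each = cells)),
    chromosomes = as.character(1:chroms))
  n <- nrow(led)
  led$p <- ifelse(stats::runif(n) < signal,
                  stats::rbeta(n, 0.05, 1), stats::runif(n))
  led
}

test_that("rejection sets are nested in q and respect the hierarchy", {
  set.seed(47)
  led <- random_tree()
  prev <- NULL
  for (q in c(0.001, 0.01, 0.05)) {
    sel <- treebh_select(led, q)
    rejected <- which(sel$leaves$rejected_leaf)
    if (!is.null(prev)) expect_true(all(prev %in% rejected))
    prev <- rejected
    # no rejected leaf without rejected ancestors
    expect_true(all(sel$leaves$rejected_cell[sel$leaves$rejected_leaf]))
    expect_true(all(sel$leaves$rejected_embryo[sel$leaves$rejected_cell]))
  }
})

test_that("embryo-level false rejections stay below q on global nulls", {
  set.seed(53)
  n_rep <- 500
  fp <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    led <- random_tree(n_embryos = 10, cells = 2, chroms = 4, signal = 0)
    sel <- treebh_select(led, 0.05)
    fp[r] <- mean(sel$embryos$rejected)
  }
  se <- stats::sd(fp) / sqrt(n_rep)
  expect_lte(mean(fp), 0.05 + 2 * se)
})

test_that("2-means labels monosomies by the lower-Z cluster", {
  rej <- data.frame(z_expr = c(-5, -6, 4, 5), z_ai = c(-4, -5, -3, -4))
  out <- assign_ploidy_type(rej)
  expect_equal(out$call, c("monosomy", "monosomy", "trisomy", "trisomy"))

  # single rejected leaf: sign fallback
  one <- assign_ploidy_type(data.frame(z_expr = -6, z_ai = -2))
  expect_equal(one$call, "monosomy")
  one_t <- assign_ploidy_type(data.frame(z_expr = 6, z_ai = -2))
  expect_equal(one_t$call, "trisomy")
  # missing expression Z: allelic sign decides
  na_e <- assign_ploidy_type(data.frame(z_expr = NA_real_, z_ai = -5))
  expect_equal(na_e$call, "monosomy")
  # empty input passes through
  expect_equal(nrow(assign_ploidy_type(
    data.frame(z_expr = numeric(0), z_ai = numeric(0)))), 0)
})

test_that("planted monosomies and trisomies are labeled accurately", {
  sim <- simulate_cohort(sim_config(p_meiotic = 0.4), seed = 59)
  cs <- run_caller(sim)
  expect_gt(nrow(cs$calls), 10)
  key <- paste(cs$calls$cell_id, cs$calls$chromosome)
  tkey <- paste(sim$truth$cell_id, sim$truth$chromosome)
  cn <- sim$truth$copy_number[match(key, tkey)]
  true_pos <- cn != 2L
  acc <- mean((cs$calls$call[true_pos] == "monosomy") == (cn[true_pos] == 1L))
  expect_gte(acc, 0.95)
})

test_that("the omnibus table covers the full ledger with gated combination", {
  sim <- simulate_cohort(sim_config(n_embryos = 3, cells_per_embryo = 8),
                         seed = 61)
  cpm <- cpm_normalize(sim$counts)
  expr <- expression_pvalues(
    dosage_scores(cpm, sim$meta$cell_id, sim$gene_map))
  ai <- allelic_signal(sim$allelic)
  tab <- omnibus_table(sim$meta, expr, ai)
  expect_equal(nrow(tab), nrow(sim$meta) * 22)
  gated <- tab$p_expr_gated[!is.na(tab$s)]
  expect_true(all(gated[abs(1 - tab$s[!is.na(tab$s)]) < 0.2] == 1))
  # expression-only mode: combined p equals the gated expression p
  tab_e <- omnibus_table(sim$meta, expr, NULL)
  expect_equal(tab_e$p, tab_e$p_expr_gated)
})
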