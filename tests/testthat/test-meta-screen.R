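# A cohort whose survival depends on a single gene, for direction checks.
sim_one_gene_cohort <- function(seed, n = 200, beta = 0.8) {
  sim <- simulate_multi_cohort(sim_config(
    n_cohorts = 1L, n_per_cohort = n, n_genes = 5L, n_planted = 1L,
    effect_size_range = c(abs(beta), abs(beta)), seed = seed))
  sim
}

test_that("screen_gene_cohort dichotomizes at the median with ties to low", {
  # 4 samples, gene values 1..4: median 2.5, high = samples 3,4.
  # Survival is chosen so the high group dies early: hr > 1.
  expr <- rbind(g1 = c(1, 2, 3, 4), g2 = c(5, 5, 5, 6))
  colnames(expr) <- paste0("s", 1:4)
  clin <- data.frame(sample_id = paste0("s", 1:4),
                     os_time = c(10, 3, 4, 1), os_event = c(1, 1, 1, 1))
  co <- cohort("toy", expr, clin)
  res <- screen_gene_cohort(co, "g1")
  expect_gt(res$hr, 1)
  expect_identical(res$n, 4L)
  expect_identical(res$n_events, 4)

  # g2: 3 of 4 samples tied at the median value 5 -> degenerate
  expect_error(screen_gene_cohort(co, "g2"), "degenerate dichotomization")
  expect_error(screen_gene_cohort(co, "nope"), "not in cohort")
})

test_that("screening recovers the planted direction in nearly all simulations", {
  hits <- vapply(1:100, function(s) {
    sim <- sim_one_gene_cohort(seed = s)
    g <- sim$truth$planted_gene_ids
    res <- screen_gene_cohort(sim$cohorts[[1]], g)
    sign(res$log_hr) == sign(sim$truth$planted_log_hr[g])
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})

test_that("fixed_effects_pool reproduces closed forms", {
  one <- fixed_effects_pool(data.frame(log_hr = 0.5, se_log_hr = 0.2))
  expect_equal(one$pooled_log_hr, 0.5)
  expect_equal(one$pooled_se_log_hr, 0.2)
  expect_equal(one$se_hr, exp(0.5) * 0.2)  # delta method
  expect_identical(one$direction, "poor")

  # k identical studies shrink the SE by exactly sqrt(k)
  for (k in 2:10) {
    rep_k <- fixed_effects_pool(data.frame(log_hr = rep(0.5, k),
                                           se_log_hr = rep(0.2, k)))
    expect_equal(rep_k$pooled_log_hr, 0.5, tolerance = 1e-12)
    expect_equal(rep_k$pooled_se_log_hr, 0.2 / sqrt(k), tolerance = 1e-12)
  }

  # hand inverse-variance arithmetic
  two <- fixed_effects_pool(data.frame(log_hr = c(0.5, 0.1),
                                       se_log_hr = c(0.1, 0.3)))
  expect_equal(two$pooled_log_hr, 0.46, tolerance = 1e-10)
  expect_equal(two$pooled_se_log_hr, 0.09486833, tolerance = 1e-6)

  expect_error(fixed_effects_pool(data.frame(log_hr = 1, se_log_hr = 0)),
               "positive")
  expect_error(fixed_effects_pool(data.frame(log_hr = numeric(0),
                                             se_log_hr = numeric(0))),
               "at least 1")
})

test_that("fixed_effects_pool agrees with metafor on random inputs", {
  set.seed(3)
  for (i in 1:10) {
    k <- sample(2:8, 1)
    b <- rnorm(k, 0, 0.5); se <- runif(k, 0.05, 0.4)
    mine <- fixed_effects_pool(data.frame(log_hr = b, se_log_hr = se))
    ref <- metafor::rma(yi = b, sei = se, method = "FE")
    expect_equal(mine$pooled_log_hr, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(mine$pooled_se_log_hr, ref$se, tolerance = 1e-8)
  }
})

test_that("bh_adjust matches the step-up oracle and hand examples", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 4 * 0.02 / 3, 0.04), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")

  set.seed(77)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("meta_analyse pools per gene and fdr never undercuts the raw p", {
  sim <- simulate_multi_cohort(sim_config(n_cohorts = 3L, n_per_cohort = 60L,
                                          n_genes = 15L, n_planted = 3L,
                                          seed = 2))
  scr <- screen_cohorts(sim$cohorts, sim$truth$glyco_genes)
  meta <- meta_analyse(scr)
  expect_identical(nrow(meta), 15L)
  expect_true(all(meta$fdr_q >= meta$meta_p))
  expect_true(all(meta$pooled_hr > 0 & meta$se_hr > 0))
  expect_identical(meta$direction, ifelse(meta$pooled_hr > 1, "poor", "good"))
  expect_true(all(meta$n_cohorts == 3L))
})

test_that("genes missing from one cohort are pooled over the cohorts measuring them", {
  sim <- simulate_multi_cohort(sim_config(n_cohorts = 3L, n_per_cohort = 60L,
                                          n_genes = 10L, n_planted = 0L,
                                          seed = 5))
  cohorts <- sim$cohorts
  drop_gene <- rownames(cohorts[[1]]$expression)[1]
  cohorts[[1]]$expression <-
    cohorts[[1]]$expression[-1, , drop = FALSE]
  scr <- screen_cohorts(cohorts, sim$truth$glyco_genes)
  meta <- meta_analyse(scr)
  expect_identical(meta$n_cohorts[meta$gene_id == drop_gene], 2L)
  expect_true(all(meta$n_cohorts[meta$gene_id != drop_gene] == 3L))
})

test_that("select_prognostic_genes applies strict double thresholds", {
  meta <- data.frame(gene_id = c("a", "b", "c"),
                     meta_p = c(0.001, 0.0005, 0.5),
                     fdr_q = c(0.001, 0.0008, 0.6),
                     pooled_hr = c(2, 0.5, 1.1),
                     se_hr = c(0.2, 0.1, 0.3),
                     direction = c("poor", "good", "poor"))
  sel <- select_prognostic_genes(meta)
  expect_identical(sel$gene_id, "b")  # exact 0.001 excluded

  expect_warning(empty <- select_prognostic_genes(
    transform(meta, meta_p = 0.5, fdr_q = 0.5)), "empty selection")
  expect_identical(nrow(empty), 0L)
  expect_error(select_prognostic_genes(meta, p_threshold = 0), "\\(0, 1\\)")
  expect_error(select_prognostic_genes(meta, fdr_threshold = 1), "\\(0, 1\\)")
})

test_that("null multi-cohort data yields a median of zero sub-0.001 genes", {
  counts <- vapply(1:20, function(s) {
    sim <- simulate_multi_cohort(sim_config(n_per_cohort = 60L,
                                            n_planted = 0L, seed = s))
    scr <- screen_cohorts(sim$cohorts, sim$truth$glyco_genes)
    meta <- meta_analyse(scr)
    sum(meta$meta_p < 0.001)
  }, numeric(1L))
  expect_identical(median(counts), 0)
})
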