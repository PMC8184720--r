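test_that("ssgsea_scores matches the naive running-sum oracle", {
  # fixed 5-gene example, one sample
  x <- c(g1 = 3.2, g2 = 1.1, g3 = 5.0, g4 = 0.4, g5 = 2.2)
  expr <- cbind(s1 = x, s2 = rev(unname(x)))
  rownames(expr) <- names(x)
  sets <- list(S = c("g1", "g4"))
  got <- ssgsea_scores(expr, sets, alpha = 0.25, normalize = FALSE)
  expect_lt(abs(got["S", "s1"] - ssgsea_oracle_one(x, sets$S, 0.25)), 1e-10)

  # random instances, several sets and samples
  set.seed(31)
  for (i in 1:10) {
    ng <- sample(8:20, 1); ns <- sample(2:4, 1)
    genes <- paste0("g", seq_len(ng))
    e <- matrix(rnorm(ng * ns), ng, ns,
                dimnames = list(genes, paste0("s", seq_len(ns))))
    st <- list(A = sample(genes, 3), B = sample(genes, 5))
    got <- ssgsea_scores(e, st, alpha = 0.25, normalize = FALSE)
    for (s in colnames(e)) {
      expect_lt(abs(got["A", s] - ssgsea_oracle_one(e[, s], st$A, 0.25)),
                1e-10)
      expect_lt(abs(got["B", s] - ssgsea_oracle_one(e[, s], st$B, 0.25)),
                1e-10)
    }
  }
})

test_that("ssgsea_scores is rank-based and monotone in set placement", {
  set.seed(12)
  e <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  sets <- list(A = paste0("g", 1:4), B = paste0("g", 11:16))
  base <- ssgsea_scores(e, sets)
  # strictly increasing transform of expression: identical scores
  expect_equal(ssgsea_scores(2^e + 5, sets), base, tolerance = 1e-12)

  # set genes at the top ranks score higher than at the bottom ranks
  x_top <- setNames(c(10, 9, 1:8 / 10), paste0("g", 1:10))
  x_bot <- setNames(c(0.1, 0.05, 10:3), paste0("g", 1:10))
  st <- list(S = c("g1", "g2"))
  top <- ssgsea_scores(cbind(s1 = x_top, s2 = x_bot), st,
                       normalize = FALSE)
  expect_gt(top["S", "s1"], top["S", "s2"])
})

test_that("ssgsea_scores drops empty-overlap sets and rejects degenerate ones", {
  e <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  expect_warning(got <- ssgsea_scores(e, list(ok = c("g1", "g2"),
                                              gone = c("zz", "yy"))),
                 "gone")
  expect_identical(rownames(got), "ok")
  expect_error(ssgsea_scores(e, list(all = paste0("g", 1:10))),
               "entire gene universe")
  expect_error(ssgsea_scores(e, list(ok = "g1"), alpha = 0), "positive")
  expect_error(suppressWarnings(ssgsea_scores(e, list(gone = "zz"))),
               "no gene set overlaps")
})

test_that("random-set ssGSEA scores centre near the matrix mid-range", {
  devs <- vapply(1:50, function(s) {
    set.seed(s)
    e <- matrix(rnorm(150 * 25), 150, 25,
                dimnames = list(paste0("g", 1:150), paste0("s", 1:25)))
    sc <- ssgsea_scores(e, list(R = sample(rownames(e), 15)))
    mean(sc) - (max(sc) + min(sc)) / 2
  }, numeric(1L))
  # centred on average over draws; single-draw mid-ranges are noisy
  expect_lt(abs(mean(devs)), 0.1)
  expect_lt(mean(abs(devs)), 0.1)
})

test_that("rank_sum_test reproduces exact and asymptotic references", {
  # identical groups: no shift
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 4.5)  # n1*n2/2
  expect_equal(same$p, 1)

  ab <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(ab$U, 0)
  expect_equal(ab$p, 1 / 3, tolerance = 1e-12)  # 2 of C(4,2) assignments

  swapped <- rank_sum_test(c(3, 4), c(1, 2))
  expect_equal(swapped$U, 4 - ab$U)
  expect_equal(swapped$p, ab$p, tolerance = 1e-12)

  # large-sample route agrees with the tie-corrected normal approximation
  set.seed(4)
  a <- round(rnorm(25, 0, 1), 1); b <- round(rnorm(30, 0.4, 1), 1)
  mine <- rank_sum_test(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)

  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("spearman_corr matches hand rank arithmetic", {
  x <- c(1, 2, 3, 4)
  expect_equal(spearman_corr(x, x)$rho, 1)
  expect_equal(spearman_corr(x, rev(x))$rho, -1)
  got <- spearman_corr(x, c(1, 3, 2, 4))
  expect_equal(got$rho, 0.8)  # 1 - 6*2/(4*15)
  ref <- cor.test(x, c(1, 3, 2, 4), method = "spearman", exact = FALSE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_error(spearman_corr(c(1, 1, 1), x[1:3]), "constant")
  expect_error(spearman_corr(1:2, 1:2), "at least 3")
})

test_that("contingency_test picks chi-square or Fisher per expected counts", {
  flat <- contingency_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  expect_identical(flat$method_used, "chi_square")

  f <- contingency_test(matrix(c(3, 1, 1, 3), 2))
  expect_identical(f$method_used, "fisher")
  expect_equal(f$p, fisher.test(matrix(c(3, 1, 1, 3), 2))$p.value,
               tolerance = 1e-12)
  expect_equal(f$p, 0.4857, tolerance = 1e-4)

  big <- matrix(c(20, 30, 25, 15, 30, 40), 2)
  ref <- chisq.test(big, correct = FALSE)
  got <- contingency_test(big)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_identical(got$method_used, "chi_square")

  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
  expect_error(contingency_test(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("immune enrichment drops in the high-risk stratum when planted", {
  sim <- simulate_multi_cohort(sim_config(n_cohorts = 1L,
                                          n_per_cohort = 150L,
                                          n_immune_sets = 6L,
                                          immune_shift = 0.5, seed = 14))
  co <- sim$cohorts[[1]]
  eta <- sim$truth$latent_risk[[co$name]]
  strata <- stratify_by_median(eta)
  em <- ssgsea_scores(co$expression, sim$truth$immune_sets)
  cmp <- compare_enrichment(em, strata[colnames(em)])
  expect_identical(nrow(cmp), 6L)
  expect_true(all(cmp$direction == "down_in_high"))
  expect_true(all(cmp$q < 0.05))
  expect_true(all(cmp$q >= cmp$p))
})
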