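# Fixture builders and independent oracles used across the suite.
# Every oracle here is a deliberately naive re-derivation (loops, grids,
# enumeration) kept independent of the package's implementation path.

# A small deterministic cohort: expression is seeded noise, survival is
# seeded exponential; not meant to carry signal.
make_test_cohort <- function(n = 20L, n_genes = 6L, name = "TEST",
                             seed = 1L) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  sid <- sprintf("%s_%02d", name, seq_len(n))
  expr <- matrix(rnorm(n_genes * n, 6, 1), n_genes, n,
                 dimnames = list(genes, sid))
  clin <- data.frame(sample_id = sid,
                     os_time = round(rexp(n, 1 / 400), 3) + 1,
                     os_event = rbinom(n, 1, 0.6),
                     stringsAsFactors = FALSE)
  cohort(name, expr, clin)
}

# Grid + golden-refine maximization of the (untied) Cox partial likelihood
# for a single covariate. Distinct event times assumed, so the Efron and
# Breslow conventions coincide with the plain partial likelihood.
cox_loglik_1cov <- function(b, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
  }
  ll
}

cox_grid_oracle <- function(time, event, x, lo = -5, hi = 5) {
  grid <- seq(lo, hi, by = 0.01)
  ll <- vapply(grid, cox_loglik_1cov, numeric(1L), time, event, x)
  b0 <- grid[which.max(ll)]
  optimize(cox_loglik_1cov, c(b0 - 0.02, b0 + 0.02), maximum = TRUE,
           time = time, event = event, x = x, tol = 1e-9)$maximum
}

# Step-up Benjamini-Hochberg from first principles.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Hand product-limit over risk sets (events only create steps).
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    n_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = ut, survival = surv)
}

# Two-group log-rank by explicit observed-minus-expected over risk sets.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1L)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# IPCW cumulative/dynamic AUC by explicit weighted-pair enumeration, with
# its own product-limit censoring-survival computation (events precede
# censorings at tied times).
ipcw_auc_oracle <- function(score, time, event, t0) {
  G <- function(u, left = FALSE) {
    ut <- sort(unique(time))
    g <- 1
    n_risk <- length(time)
    for (tt in ut) {
      if ((left && tt >= u) || (!left && tt > u)) break
      d_ev <- sum(time == tt & event == 1)
      d_cn <- sum(time == tt & event == 0)
      if (d_cn > 0 && (n_risk - d_ev) > 0)
        g <- g * (1 - d_cn / (n_risk - d_ev))
      n_risk <- n_risk - d_ev - d_cn
    }
    g
  }
  cases <- which(time <= t0 & event == 1)
  ctrls <- which(time > t0)
  num <- 0; den <- 0
  for (i in cases) for (j in ctrls) {
    w <- (1 / G(time[i], left = TRUE)) * (1 / G(t0))
    cc <- if (score[i] > score[j]) 1 else if (score[i] == score[j]) 0.5 else 0
    num <- num + w * cc
    den <- den + w
  }
  num / den
}

# Naive running-sum ssGSEA statistic for one sample and one set.
ssgsea_oracle_one <- function(x, set_members, alpha) {
  genes <- names(x)
  r <- rank(x, ties.method = "average")
  ord <- order(x, decreasing = TRUE)
  inset <- genes %in% set_members
  denom <- sum(r[inset]^alpha)
  n_out <- sum(!inset)
  cum_in <- 0; cum_out <- 0; es <- 0
  for (k in ord) {
    if (inset[k]) cum_in <- cum_in + r[k]^alpha / denom
    else cum_out <- cum_out + 1 / n_out
    es <- es + (cum_in - cum_out)
  }
  es
}

# Numeric-integration oracle for the AUC of a Normal(0,1) score against a
# logistic response P(y = 1) = plogis(a + b * score): trapezoid rule for
# P(S_pos > S_neg) + 0.5 P(equal) (the tie term vanishes for continuous S).
binormal_logistic_auc_oracle <- function(a, b, lim = 8, n_grid = 20001L) {
  x <- seq(-lim, lim, length.out = n_grid)
  dx <- x[2L] - x[1L]
  phi <- dnorm(x)
  p1 <- plogis(a + b * x)
  f1 <- phi * p1; f0 <- phi * (1 - p1)
  e1 <- sum(f1) * dx; e0 <- sum(f0) * dx
  F0 <- (cumsum(f0) - f0 / 2) * dx
  sum(f1 * F0) * dx / (e1 * e0)
}

# Recovery summary for a planted-gene screen: fraction of planted genes
# selected with the correct direction, and count of false positives.
recovery_summary <- function(selected, truth) {
  planted <- truth$planted_gene_ids
  rec <- intersect(selected$gene_id, planted)
  est_dir <- ifelse(selected$direction[match(rec, selected$gene_id)] ==
                      "poor", 1, -1)
  list(frac_correct = sum(est_dir == sign(truth$planted_log_hr[rec])) /
         length(planted),
       false_pos = sum(!selected$gene_id %in% planted))
}
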