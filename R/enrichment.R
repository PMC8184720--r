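# Raw ssGSEA enrichment statistic for one sample and one set.
# r: ascending ranks of expression (highest expressed gene has rank N),
# ord: gene indices in descending-expression order, inset: logical per gene.
ssgsea_one <- function(r, ord, inset, alpha) {
  w <- r[ord]^alpha * inset[ord]
  denom_in <- sum(w)
  step_in <- cumsum(w) / denom_in
  n_out <- sum(!inset)
  step_out <- cumsum(!inset[ord]) / n_out
  sum(step_in - step_out)
}

#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For every sample, genes are ranked by expression (descending; tied
#' values share average ranks). Walking down that ranking, the score is the
#' sum of the difference between the weighted in-set empirical CDF (weights
#' rank^alpha, normalized within the set) and the unweighted out-of-set
#' ECDF — an integrated running-sum statistic. Being rank-based, scores are
#' invariant to any strictly increasing transform of the expression values.
#' With `normalize = TRUE` (default) all scores are divided by the global
#' range (max - min) across the whole matrix.
#'
#' @param expression Genes x samples numeric matrix (or `grp_cohort`).
#' @param gene_sets List of `grp_geneset` objects or named list of
#'   character vectors.
#' @param alpha Rank-weighting exponent (> 0); default 0.25, the convention
#'   of the ssGSEA implementation family.
#' @param normalize Divide by the global score range (default `TRUE`).
#' @return Matrix, sets x samples. Sets with no gene in the matrix are
#'   dropped with a warning; a set covering the entire gene universe is an
#'   error (its out-of-set ECDF is undefined).
#' @export
ssgsea_scores <- function(expression, gene_sets, alpha = 0.25,
                          normalize = TRUE) {
  if (inherits(expression, "grp_cohort")) expression <- expression$expression
  if (alpha <= 0) stop("alpha must be positive")
  genes <- rownames(expression)
  members <- lapply(gene_sets, function(s)
    if (inherits(s, "grp_geneset")) s$members else s)
  if (is.null(names(members)) || any(!nzchar(names(members))))
    names(members) <- vapply(gene_sets, function(s) s$name, character(1L))
  keep <- vapply(members, function(m) any(m %in% genes), logical(1L))
  if (any(!keep))
    warning("gene set(s) with no gene in the matrix dropped: ",
            paste(names(members)[!keep], collapse = ", "), call. = FALSE)
  members <- members[keep]
  if (!length(members)) stop("no gene set overlaps the expression matrix")
  full <- vapply(members, function(m) all(genes %in% m), logical(1L))
  if (any(full))
    stop("gene set covers the entire gene universe: ",
         paste(names(members)[full], collapse = ", "))
  inset <- lapply(members, function(m) genes %in% m)
  scores <- matrix(NA_real_, length(members), ncol(expression),
                   dimnames = list(names(members), colnames(expression)))
  for (j in seq_len(ncol(expression))) {
    x <- expression[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(x, decreasing = TRUE)
    for (i in seq_along(inset))
      scores[i, j] <- ssgsea_one(r, ord, inset[[i]], alpha)
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

# Exact two-sided p for the Mann-Whitney U by enumerating all C(n, n1)
# group assignments of the pooled sample (handles ties correctly).
rank_sum_exact_p <- function(pooled_ranks, n1, u_obs) {
  n <- length(pooled_ranks)
  idx <- combn(n, n1)
  u_all <- apply(idx, 2L, function(ii)
    sum(pooled_ranks[ii]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' U is computed from average ranks of the pooled sample. For small samples
#' (n1 + n2 <= 10) the two-sided p comes from exact enumeration of all
#' group assignments (valid under ties); otherwise from the normal
#' approximation with the tie-corrected variance.
#'
#' @param values_a,values_b Numeric vectors, both non-empty.
#' @return List with `U` (for group a) and two-sided `p`.
#' @export
rank_sum_test <- function(values_a, values_b) {
  n1 <- length(values_a); n2 <- length(values_b)
  if (!n1 || !n2) stop("both groups must be non-empty")
  pooled <- c(values_a, values_b)
  r <- rank(pooled, ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= 10L) {
    p <- rank_sum_exact_p(r, n1, u)
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - n1 * n2 / 2) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  list(U = u, p = p)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks; two-sided p from the t
#' approximation with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `rho` and `p`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop("constant vector: Spearman correlation undefined")
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2))
}

#' Chi-square / Fisher contingency test for a 2 x k table
#'
#' Pearson chi-square without continuity correction; for 2 x 2 tables with
#' any expected count below 5 the Fisher exact test is used instead and
#' reported in `method_used`.
#'
#' @param table_2xk Matrix of non-negative integer counts, 2 rows, >= 2
#'   columns, no zero row/column margin.
#' @return List with `statistic` (chi-square; `NA` for Fisher), `p`,
#'   `method_used` ("chi_square" or "fisher").
#' @export
contingency_test <- function(table_2xk) {
  tab <- as.matrix(table_2xk)
  if (nrow(tab) != 2L || ncol(tab) < 2L)
    stop("need a 2 x k table with k >= 2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in contingency table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (ncol(tab) == 2L && any(expected < 5)) {
    ft <- fisher.test(tab)
    return(list(statistic = NA_real_, p = ft$p.value,
                method_used = "fisher"))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       method_used = "chi_square")
}

#' Compare enrichment scores between two strata across all sets
#'
#' For each gene set (row of an enrichment matrix), runs the rank-sum test
#' between the two strata and applies a single Benjamini-Hochberg
#' correction across sets (raw p reported alongside q).
#'
#' @param enrichment Sets x samples matrix ([ssgsea_scores()] output).
#' @param strata Character vector ("high"/"low") aligned with the matrix
#'   columns.
#' @return data.frame: `set`, `median_high`, `median_low`, `direction`
#'   ("down_in_high"/"up_in_high"), `U`, `p`, `q`.
#' @export
compare_enrichment <- function(enrichment, strata) {
  stopifnot(ncol(enrichment) == length(strata),
            all(strata %in% c("high", "low")))
  hi <- strata == "high"
  if (!any(hi) || all(hi)) stop("both strata must be non-empty")
  res <- lapply(rownames(enrichment), function(s) {
    a <- enrichment[s, hi]
    b <- enrichment[s, !hi]
    rs <- rank_sum_test(a, b)
    data.frame(set = s, median_high = median(a), median_low = median(b),
               direction = if (median(a) < median(b)) "down_in_high"
                           else "up_in_high",
               U = rs$U, p = rs$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}
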