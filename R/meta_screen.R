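#' Median-dichotomized survival screen of one gene in one cohort
#'
#' The gene's expression is split at the within-cohort median (values equal
#' to the median go to the low group, same tie rule as score stratification)
#' and the binary high-expression indicator is tested in a univariate Cox
#' model.
#'
#' @param cohort A `grp_cohort`.
#' @param gene_id Gene identifier present in the cohort's expression matrix.
#' @return One-row data.frame: `gene_id`, `cohort_name`, `log_hr`,
#'   `se_log_hr`, `hr`, `wald_p`, `n`, `n_events`.
#' @export
screen_gene_cohort <- function(cohort, gene_id) {
  stopifnot(inherits(cohort, "grp_cohort"))
  if (!gene_id %in% rownames(cohort$expression))
    stop("gene '", gene_id, "' not in cohort '", cohort$name, "'")
  x <- cohort$expression[gene_id, ]
  if (diff(range(x)) == 0)
    stop("gene '", gene_id, "' has no expression variation")
  high <- as.numeric(x > median(x))
  if (mean(x == median(x)) > 0.5)
    stop("degenerate dichotomization for gene '", gene_id,
         "': >50% of samples tied at the median")
  fit <- fit_cox(matrix(high, ncol = 1L, dimnames = list(NULL, "high")),
                 cohort$clinical$os_time, cohort$clinical$os_event)
  data.frame(gene_id = gene_id, cohort_name = cohort$name,
             log_hr = fit$log_hr, se_log_hr = fit$se_log_hr, hr = fit$hr,
             wald_p = fit$wald_p, n = attr(fit, "n_samples"),
             n_events = attr(fit, "n_events"), stringsAsFactors = FALSE)
}

#' Screen many genes across many cohorts
#'
#' Runs [screen_gene_cohort()] for every requested gene in every cohort in
#' which it is measured. Genes absent from a cohort are screened in the
#' remaining cohorts only; genes that fail in a cohort (no variation,
#' degenerate dichotomization, non-convergence) are skipped there with a
#' warning.
#'
#' @param cohorts List of `grp_cohort` objects.
#' @param gene_ids Genes to screen; default: union of all cohort genes.
#' @return data.frame of per-gene, per-cohort results (rbind of
#'   [screen_gene_cohort()] rows).
#' @export
screen_cohorts <- function(cohorts, gene_ids = NULL) {
  stopifnot(length(cohorts) >= 1L)
  if (is.null(gene_ids))
    gene_ids <- Reduce(union, lapply(cohorts, function(co)
      rownames(co$expression)))
  out <- vector("list", length(cohorts) * length(gene_ids))
  k <- 0L
  for (co in cohorts) {
    present <- intersect(gene_ids, rownames(co$expression))
    for (g in present) {
      row <- tryCatch(screen_gene_cohort(co, g), error = function(e) {
        warning(sprintf("cohort '%s', gene '%s': %s", co$name, g,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (!is.null(row)) {
        k <- k + 1L
        out[[k]] <- row
      }
    }
  }
  if (k == 0L) stop("no gene could be screened in any cohort")
  do.call(rbind, out[seq_len(k)])
}

#' Fixed-effects inverse-variance pooling of one gene's cohort results
#'
#' Pooling is performed on the log-HR scale: with per-cohort estimates b_i
#' and standard errors se_i, weights are w_i = 1/se_i^2, the pooled log HR
#' is sum(w b)/sum(w) and its SE is sum(w)^(-1/2). The pooled HR is
#' exp(pooled log HR) and SE(HR) is recovered on the hazard-ratio scale by
#' the delta method, SE(HR) = HR * SE(log HR) — the scale the score weights
#' consume. The meta p-value is two-sided normal on the pooled z.
#'
#' @param results data.frame of per-cohort rows for a single gene, with
#'   columns `log_hr` and `se_log_hr` (as produced by
#'   [screen_gene_cohort()]).
#' @return One-row data.frame: `gene_id` (if present in input),
#'   `pooled_log_hr`, `pooled_se_log_hr`, `pooled_hr`, `se_hr`, `meta_p`,
#'   `direction` ("poor" iff pooled HR > 1, else "good"), `n_cohorts`.
#' @export
fixed_effects_pool <- function(results) {
  b <- results$log_hr
  se <- results$se_log_hr
  if (!length(b)) stop("need at least 1 cohort result")
  if (any(!is.finite(se)) || any(se <= 0))
    stop("all standard errors must be positive and finite")
  w <- 1 / se^2
  pooled <- sum(w * b) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  hr <- exp(pooled)
  z <- pooled / pooled_se
  data.frame(
    gene_id = if ("gene_id" %in% names(results)) results$gene_id[1L] else NA,
    pooled_log_hr = pooled,
    pooled_se_log_hr = pooled_se,
    pooled_hr = hr,
    se_hr = hr * pooled_se,
    meta_p = 2 * pnorm(-abs(z)),
    direction = if (hr > 1) "poor" else "good",
    n_cohorts = length(b),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector, each in (0, 1].
#' @return Adjusted q-values, order-preserving with the input.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Pool every screened gene and attach FDR
#'
#' Applies [fixed_effects_pool()] gene by gene and a single
#' Benjamini-Hochberg correction across the whole screened gene universe
#' (not per cohort: the selection is one corrected list).
#'
#' @param screen_results Output of [screen_cohorts()].
#' @return data.frame, one row per gene, pooled columns plus `fdr_q`.
#' @export
meta_analyse <- function(screen_results) {
  pieces <- lapply(split(screen_results, screen_results$gene_id),
                   fixed_effects_pool)
  meta <- do.call(rbind, pieces)
  rownames(meta) <- NULL
  meta$fdr_q <- bh_adjust(meta$meta_p)
  meta
}

#' Select prognostic genes from meta-analysis results
#'
#' Keeps genes with `meta_p < p_threshold` and `fdr_q < fdr_threshold`
#' (strict inequalities). Defaults are the stringent double cut
#' p < 0.001 and FDR < 0.001. Each selected gene is labelled "poor"
#' (pooled HR > 1) or "good" (pooled HR < 1).
#'
#' @param meta_results Output of [meta_analyse()].
#' @param p_threshold,fdr_threshold Thresholds in (0, 1).
#' @return The selected rows; empty selection returns an empty data.frame
#'   with a prominent warning (the caller decides whether to abort).
#' @export
select_prognostic_genes <- function(meta_results, p_threshold = 0.001,
                                    fdr_threshold = 0.001) {
  if (p_threshold <= 0 || p_threshold >= 1 ||
      fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("thresholds must lie in (0, 1)")
  keep <- meta_results$meta_p < p_threshold &
    meta_results$fdr_q < fdr_threshold
  sel <- meta_results[keep, , drop = FALSE]
  if (nrow(sel) == 0L)
    warning("no gene passed p < ", p_threshold, " and FDR < ",
            fdr_threshold, ": empty selection", call. = FALSE)
  rownames(sel) <- NULL
  sel
}
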