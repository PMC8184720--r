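#' Build GRP weights from selected meta-analysis results
#'
#' Each selected gene i contributes weight w_i = (HR_i - 1) / SE(HR_i),
#' with HR_i the pooled hazard ratio and SE(HR_i) its delta-method standard
#' error on the hazard-ratio scale. Dividing by SE(HR) damps the influence
#' of genes whose pooled HR is imprecisely estimated, so cohort sample size
#' does not dominate the weighting. The weight's sign equals the sign of
#' (HR - 1): poor-prognosis genes add to the score, protective genes
#' subtract.
#'
#' @param selected_meta_results Non-empty output of
#'   [select_prognostic_genes()] (columns `gene_id`, `pooled_hr`, `se_hr`).
#' @return An object of class `grp_weights`: data.frame with `gene_id`,
#'   `weight`, and provenance columns `pooled_hr`, `se_hr`.
#' @export
compute_weights <- function(selected_meta_results) {
  m <- selected_meta_results
  if (is.null(m) || nrow(m) == 0L)
    stop("empty gene selection: cannot compute weights")
  if (any(m$se_hr <= 0)) stop("se_hr must be positive")
  w <- data.frame(gene_id = m$gene_id,
                  weight = (m$pooled_hr - 1) / m$se_hr,
                  pooled_hr = m$pooled_hr,
                  se_hr = m$se_hr,
                  stringsAsFactors = FALSE)
  class(w) <- c("grp_weights", "data.frame")
  w
}

#' Raw GRP score per sample
#'
#' The score is the weighted sum of each selected gene's expression as
#' loaded (log2 scale): score(s) = sum_i w_i * expression(i, s), over the
#' genes shared between the weights and the matrix. The expression is used
#' as-is, not gene-wise standardized (the single z-normalization is applied
#' afterwards to the final score, per cohort); set
#' `standardize_genes = TRUE` for a gene-wise z-scored sensitivity variant.
#'
#' @param expression Genes x samples numeric matrix (or a `grp_cohort`).
#' @param weights A `grp_weights` object (or data.frame with `gene_id`,
#'   `weight`).
#' @param standardize_genes If `TRUE`, z-score each gene's expression across
#'   samples before weighting (sensitivity analysis switch; default `FALSE`).
#' @return Named numeric vector of raw scores (one per sample).
#' @export
compute_grp_scores <- function(expression, weights,
                               standardize_genes = FALSE) {
  if (inherits(expression, "grp_cohort")) expression <- expression$expression
  shared <- intersect(weights$gene_id, rownames(expression))
  missing <- setdiff(weights$gene_id, rownames(expression))
  if (!length(shared))
    stop("no weight gene present in expression matrix; missing: ",
         paste(missing, collapse = ", "))
  if (length(missing))
    message("compute_grp_scores: ", length(missing),
            " weight gene(s) absent from matrix: ",
            paste(missing, collapse = ", "))
  sub <- expression[shared, , drop = FALSE]
  if (standardize_genes)
    sub <- t(scale(t(sub)))
  w <- weights$weight[match(shared, weights$gene_id)]
  drop(crossprod(sub, w))[colnames(expression)] |>
    setNames(colnames(expression))
}

#' Z-normalize scores within a cohort
#'
#' (x - mean) / sample SD (n - 1 denominator).
#'
#' @param raw_scores Numeric vector, length >= 2, non-constant.
#' @return Z-scores with mean 0 and sample SD 1.
#' @export
z_normalize <- function(raw_scores) {
  if (length(raw_scores) < 2L) stop("need at least 2 samples")
  s <- sd(raw_scores)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot z-normalize")
  (raw_scores - mean(raw_scores)) / s
}

#' Stratify samples at the cohort-median score
#'
#' score <= median -> "low", score > median -> "high" (the same tie rule as
#' gene screening). The stratification is invariant to strictly increasing
#' transforms of the score, so raw and z-normalized scores give identical
#' strata.
#'
#' @param scores Numeric vector, length >= 2.
#' @return Character vector ("high"/"low"), named like `scores`.
#' @export
stratify_by_median <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 samples")
  if (diff(range(scores)) == 0)
    stop("all scores identical: cannot stratify")
  ifelse(scores > median(scores), "high", "low") |>
    setNames(names(scores))
}

#' Score and stratify one cohort with frozen weights
#'
#' Weights come frozen from the training meta-analysis; only the score's
#' z-normalization and the median cut-off are recomputed within the cohort
#' being scored (training/validation design: validation cohorts never
#' contribute to the weights).
#'
#' @param cohort A `grp_cohort`.
#' @param weights A `grp_weights`.
#' @inheritParams compute_grp_scores
#' @return data.frame: `sample_id`, `raw_score`, `z_score`, `stratum`,
#'   `cohort_name`.
#' @export
score_cohort <- function(cohort, weights, standardize_genes = FALSE) {
  stopifnot(inherits(cohort, "grp_cohort"))
  raw <- compute_grp_scores(cohort$expression, weights,
                            standardize_genes = standardize_genes)
  z <- z_normalize(raw)
  data.frame(sample_id = names(raw), raw_score = unname(raw),
             z_score = unname(z), stratum = unname(stratify_by_median(z)),
             cohort_name = cohort$name, stringsAsFactors = FALSE)
}

#' Export / import GRP weights as a two-column TSV
#'
#' The file carries provenance (`pooled_hr`, `se_hr`) in extra columns and
#' a `# grpscore weights` header line.
#'
#' @param weights A `grp_weights`.
#' @param path Output path.
#' @return `path` invisibly (`write_weights`); a `grp_weights`
#'   (`read_weights`).
#' @export
write_weights <- function(weights, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grpscore weights (%d genes)", nrow(weights)), con)
  write.table(as.data.frame(weights), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  w <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "weight") %in% names(w)))
  class(w) <- c("grp_weights", "data.frame")
  w
}
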