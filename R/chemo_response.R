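#' Encode RECIST-style chemotherapy response as a binary label
#'
#' Two schemes: `"CRPR_vs_SDPD"` (complete/partial response = 1, stable or
#' progressive disease = 0) and `"CR_vs_nonCR"` (complete response = 1,
#' everything else = 0). Samples with missing response are dropped with the
#' count reported via message.
#'
#' @param clinical Clinical data.frame with `sample_id` and
#'   `chemo_response` in \{CR, PR, SD, PD, NA\}.
#' @param scheme One of `"CRPR_vs_SDPD"`, `"CR_vs_nonCR"`.
#' @return List: `scheme`, `labels` (named 0/1 vector), `n_pos`, `n_neg`.
#' @export
encode_response <- function(clinical, scheme = c("CRPR_vs_SDPD",
                                                 "CR_vs_nonCR")) {
  scheme <- match.arg(scheme)
  if (!"chemo_response" %in% names(clinical))
    stop("clinical table has no chemo_response column")
  resp <- as.character(clinical$chemo_response)
  resp[resp == ""] <- NA_character_
  known <- c("CR", "PR", "SD", "PD")
  bad <- setdiff(unique(resp[!is.na(resp)]), known)
  if (length(bad))
    stop("unknown response label(s): ", paste(bad, collapse = ", "))
  ok <- !is.na(resp)
  if (!any(ok)) stop("no non-missing response labels")
  n_drop <- sum(!ok)
  if (n_drop) message("encode_response: ", n_drop,
                      " sample(s) with missing response dropped")
  pos_set <- if (scheme == "CRPR_vs_SDPD") c("CR", "PR") else "CR"
  labels <- as.numeric(resp[ok] %in% pos_set)
  names(labels) <- as.character(clinical$sample_id)[ok]
  if (all(labels == 1) || all(labels == 0))
    stop("all responses fall in one class under scheme ", scheme)
  list(scheme = scheme, labels = labels,
       n_pos = sum(labels == 1), n_neg = sum(labels == 0))
}

#' ROC area under the curve
#'
#' Computed through the Mann-Whitney identity: the proportion of
#' (positive, negative) pairs in which the positive sample scores higher,
#' with half credit for ties. Orientation is as given — scores that rank
#' negatives higher yield AUC < 0.5, no automatic flipping.
#'
#' @param scores Numeric vector.
#' @param binary_labels 0/1 vector aligned with `scores`; both classes must
#'   be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, binary_labels) {
  stopifnot(length(scores) == length(binary_labels))
  if (!all(binary_labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(binary_labels == 1)
  n0 <- sum(binary_labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present (n_pos = ", n1, ", n_neg = ", n0, ")")
  r <- rank(scores, ties.method = "average")
  u <- sum(r[binary_labels == 1]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

# Ridge-penalized logistic regression via iteratively reweighted least
# squares. The small fixed penalty (never on the intercept) keeps the
# optimum finite under complete separation.
ridge_logistic <- function(x, y, lambda = 1e-3, max_iter = 100L,
                           tol = 1e-10) {
  x <- as.matrix(x)
  xd <- cbind(`(Intercept)` = 1, x)
  p <- ncol(xd)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(xd, y - mu) - pen %*% beta
    hess <- crossprod(xd * w, xd) + pen
    delta <- solve(hess, grad)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) break
  }
  beta
}

#' Combine predictors for response discrimination
#'
#' Fits a ridge-regularized logistic regression of the binary response on
#' the supplied features (a small fixed penalty keeps estimates finite even
#' for separable data) and reports the in-sample AUC of the combined linear
#' predictor. With `select_features = TRUE`, features are pre-filtered by
#' the rank-sum test between classes at `select_p` before fitting —
#' mirroring the step of keeping only immune cell types whose enrichment
#' differs between responders and non-responders. In-sample AUC matches the
#' reporting style of single combined ROC curves; it is optimistic, so an
#' honest k-fold mode is provided.
#'
#' @param feature_matrix Samples x features numeric matrix or data.frame
#'   (a single feature is allowed); all values finite.
#' @param binary_labels 0/1 vector, both classes present.
#' @param lambda Ridge penalty (default 1e-3).
#' @param select_features Pre-filter features by rank-sum p < `select_p`.
#' @param select_p Feature-selection threshold (default 0.05).
#' @param k_fold If > 1, additionally report cross-validated AUC.
#' @param seed Seed for the fold assignment (only used when `k_fold > 1`).
#' @return List: `coefficients` (named, incl. intercept), `kept_features`,
#'   `combined_scores` (linear predictor), `auc` (in-sample), and `cv_auc`
#'   when `k_fold > 1`.
#' @export
combine_predictors <- function(feature_matrix, binary_labels,
                               lambda = 1e-3, select_features = FALSE,
                               select_p = 0.05, k_fold = 1L, seed = 1L) {
  x <- as.matrix(feature_matrix)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!all(is.finite(x))) stop("non-finite feature values")
  y <- binary_labels
  if (!all(y %in% c(0, 1)) || !any(y == 1) || !any(y == 0))
    stop("binary_labels must contain both classes")
  if (nrow(x) != length(y)) stop("features and labels misaligned")
  if (select_features && ncol(x) > 1L) {
    keep <- vapply(seq_len(ncol(x)), function(j)
      rank_sum_test(x[y == 1, j], x[y == 0, j])$p < select_p, logical(1L))
    if (!any(keep)) {
      warning("no feature passed selection; keeping all", call. = FALSE)
      keep <- rep(TRUE, ncol(x))
    }
    x <- x[, keep, drop = FALSE]
  }
  beta <- ridge_logistic(x, y, lambda = lambda)
  lp <- drop(cbind(1, x) %*% beta)
  out <- list(coefficients = setNames(beta, c("(Intercept)", colnames(x))),
              kept_features = colnames(x),
              combined_scores = setNames(lp, rownames(x)),
              auc = roc_auc(lp, y))
  if (k_fold > 1L) {
    set.seed(seed)
    fold <- sample(rep_len(seq_len(k_fold), nrow(x)))
    cv_lp <- numeric(nrow(x))
    for (f in seq_len(k_fold)) {
      tr <- fold != f
      b <- ridge_logistic(x[tr, , drop = FALSE], y[tr], lambda = lambda)
      cv_lp[!tr] <- drop(cbind(1, x[!tr, , drop = FALSE]) %*% b)
    }
    out$cv_auc <- roc_auc(cv_lp, y)
  }
  out
}
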