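#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Efron-tie-corrected partial likelihood (the convention of
#' mainstream survival software; ties are common in day-resolution data) and
#' returns Wald inference per covariate. Wald (not likelihood-ratio) p-values
#' are reported because downstream meta-analysis consumes (log HR, SE) pairs,
#' for which Wald is the matching inference.
#'
#' @param covariate_matrix Numeric matrix or data.frame, samples x covariates,
#'   no missing values; a single vector is accepted for univariate fits.
#' @param os_time Positive survival/censoring times.
#' @param os_event Event indicator (1 = event observed, 0 = censored).
#' @param max_iter Iteration cap passed to the optimizer.
#' @return An object of class `grp_coxfit`: data.frame with one row per
#'   covariate (`term`, `log_hr`, `se_log_hr`, `hr`, `wald_p`) plus
#'   attributes `n_samples`, `n_events`.
#' @export
fit_cox <- function(covariate_matrix, os_time, os_event, max_iter = 50L) {
  x <- as.matrix(covariate_matrix)
  if (is.null(colnames(x)))
    colnames(x) <- if (ncol(x) == 1L) "x" else paste0("x", seq_len(ncol(x)))
  if (nrow(x) != length(os_time) || length(os_time) != length(os_event))
    stop("covariates, os_time and os_event must have matching lengths")
  if (anyNA(x) || anyNA(os_time) || anyNA(os_event))
    stop("missing values are not allowed")
  if (any(os_time <= 0)) stop("os_time must be positive")
  if (sum(os_event) < 1) stop("zero events: cannot fit Cox model")
  const <- apply(x, 2L, function(v) diff(range(v)) == 0)
  if (any(const))
    stop("covariate(s) with no variation: ",
         paste(colnames(x)[const], collapse = ", "))
  fit <- withCallingHandlers(
    coxph(Surv(os_time, os_event) ~ x, ties = "efron",
          control = survival::coxph.control(iter.max = max_iter)),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w)))
        stop("Cox model did not converge to finite estimates: ",
             conditionMessage(w), call. = FALSE)
    })
  beta <- unname(coef(fit))
  se <- unname(sqrt(diag(fit$var)))
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0))
    stop("Cox model did not converge to finite estimates ",
         "(possible monotone likelihood / complete separation)")
  res <- data.frame(
    term = colnames(x),
    log_hr = beta,
    se_log_hr = se,
    hr = exp(beta),
    wald_p = 2 * pnorm(-abs(beta / se)),
    stringsAsFactors = FALSE
  )
  attr(res, "n_samples") <- nrow(x)
  attr(res, "n_events") <- sum(os_event)
  class(res) <- c("grp_coxfit", "data.frame")
  res
}

#' Kaplan-Meier product-limit estimate
#'
#' @inheritParams fit_cox
#' @return An object of class `grp_survcurve`: data.frame with columns
#'   `time` (distinct event times, increasing), `n_risk`, `n_event`,
#'   `survival` (non-increasing, in \[0, 1\]). Censored times do not create
#'   steps and are not rows.
#' @export
km_estimate <- function(os_time, os_event) {
  if (!length(os_time)) stop("need at least 1 sample")
  if (any(os_time < 0)) stop("negative survival time")
  sf <- survfit(Surv(os_time, os_event) ~ 1)
  keep <- sf$n.event > 0
  res <- data.frame(time = sf$time[keep],
                    n_risk = sf$n.risk[keep],
                    n_event = sf$n.event[keep],
                    survival = sf$surv[keep])
  class(res) <- c("grp_survcurve", "data.frame")
  res
}

#' Two-group log-rank test
#'
#' @inheritParams fit_cox
#' @param group_labels Vector with exactly two distinct values.
#' @return List with `chi_square` (1 df) and `p`.
#' @export
logrank_test <- function(os_time, os_event, group_labels) {
  g <- as.factor(group_labels)
  if (nlevels(g) != 2L)
    stop("exactly 2 non-empty groups are required, got ", nlevels(g))
  sd <- survdiff(Surv(os_time, os_event) ~ g)
  chi <- unname(sd$chisq)
  list(chi_square = chi, p = pchisq(chi, df = 1L, lower.tail = FALSE))
}

# Product-limit estimate of the censoring survival function G(t), with the
# events-before-censoring convention at tied times: an event at t is removed
# from the risk set before censorings at t are counted. Returns a function
# G(t, left = FALSE); left = TRUE gives the left limit G(t-).
censoring_km <- function(os_time, os_event) {
  ut <- sort(unique(os_time))
  surv <- numeric(length(ut))
  n_at_risk <- length(os_time)
  g <- 1
  for (k in seq_along(ut)) {
    t <- ut[k]
    d_event <- sum(os_time == t & os_event == 1)
    d_cens <- sum(os_time == t & os_event == 0)
    risk_for_cens <- n_at_risk - d_event
    if (d_cens > 0 && risk_for_cens > 0)
      g <- g * (1 - d_cens / risk_for_cens)
    surv[k] <- g
    n_at_risk <- n_at_risk - d_event - d_cens
  }
  function(t, left = FALSE) {
    idx <- if (left) sum(ut < t) else sum(ut <= t)
    if (idx == 0L) 1 else surv[idx]
  }
}

#' Time-dependent (cumulative/dynamic) AUC for a survival score
#'
#' Discrimination of `score` for events occurring by `horizon_t` (cases:
#' event with time <= t) versus subjects still at risk after t (controls:
#' time > t). Censoring is handled by inverse-probability-of-censoring
#' weights from a Kaplan-Meier estimate of the censoring distribution:
#' case i gets weight 1/G(T_i-), every control gets weight 1/G(t). Tied
#' scores receive half credit. With no censoring before t all weights are
#' equal and the estimate reduces to the plain ROC AUC of the event
#' indicator.
#'
#' @inheritParams fit_cox
#' @param score Numeric risk score (higher = higher risk).
#' @param horizon_t Evaluation horizon (> 0), same units as `os_time`.
#' @return The AUC at `horizon_t` (scalar in \[0, 1\]).
#' @export
time_dependent_auc <- function(score, os_time, os_event, horizon_t) {
  if (horizon_t <= 0) stop("horizon_t must be positive")
  stopifnot(length(score) == length(os_time),
            length(os_time) == length(os_event))
  is_case <- os_time <= horizon_t & os_event == 1
  is_ctrl <- os_time > horizon_t
  if (!any(is_case)) stop("no cases (events by t = ", horizon_t, ")")
  if (!any(is_ctrl)) stop("no controls (subjects at risk after t = ",
                          horizon_t, ")")
  G <- censoring_km(os_time, os_event)
  w_case <- vapply(os_time[is_case], function(ti) 1 / G(ti, left = TRUE),
                   numeric(1L))
  w_ctrl <- rep(1 / G(horizon_t), sum(is_ctrl))
  sc <- score[is_case]
  sn <- score[is_ctrl]
  conc <- outer(sc, sn, function(a, b) (a > b) + 0.5 * (a == b))
  w <- outer(w_case, w_ctrl)
  sum(w * conc) / sum(w)
}
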