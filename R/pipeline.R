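#' Run the full GRP analysis pipeline
#'
#' Orchestrates screen -> pool -> select -> weight -> score -> stratify ->
#' evaluate -> enrich -> chemo. Score weights are derived exclusively from
#' the training cohorts; validation cohorts are scored with those frozen
#' weights, and only the z-normalization and the median cut are recomputed
#' within each validation cohort. When clinical tables carry
#' `rfs_time`/`rfs_event`, the survival evaluation is re-run on
#' recurrence-free survival through the same code path.
#'
#' @param training_cohorts Non-empty list of `grp_cohort` objects used for
#'   screening and weight estimation.
#' @param validation_cohorts List of `grp_cohort` objects scored with the
#'   frozen weights (may be empty).
#' @param gene_universe Character vector of candidate gene identifiers to
#'   screen (e.g. a glycolysis gene set); default: all genes of the first
#'   training cohort.
#' @param immune_sets Optional named list of marker gene sets (or
#'   `grp_geneset` list) for per-sample enrichment scoring.
#' @param p_threshold,fdr_threshold Selection thresholds (default 0.001 and
#'   0.001).
#' @param horizons_years Time-dependent ROC horizons in years (default
#'   1, 2, 3; times are interpreted as days).
#' @param response_scheme Binary response encoding for cohorts that carry
#'   `chemo_response` (see [encode_response()]).
#' @param standardize_genes Passed to [compute_grp_scores()].
#' @param output_dir If non-`NULL`, all stage tables are written there as
#'   TSV plus a `report.json` with the config echo and stage log.
#' @param seed Seed applied before any stochastic stage (the default
#'   pipeline is deterministic; the seed matters only for optional
#'   cross-validated AUC).
#' @return A `grp_report` list: `screening`, `meta`, `selected`, `weights`,
#'   `scores`, `evaluation`, `enrichment`, `chemo`, `log` (stage messages
#'   with counts), `config`.
#' @export
run_pipeline <- function(training_cohorts, validation_cohorts = list(),
                         gene_universe = NULL, immune_sets = NULL,
                         p_threshold = 0.001, fdr_threshold = 0.001,
                         horizons_years = c(1, 2, 3),
                         response_scheme = "CRPR_vs_SDPD",
                         standardize_genes = FALSE,
                         output_dir = NULL, seed = 1L) {
  stopifnot(length(training_cohorts) >= 1L)
  lapply(c(training_cohorts, validation_cohorts), function(co)
    stopifnot(inherits(co, "grp_cohort")))
  set.seed(seed)
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message("[grpscore] ", msg)
    log <<- c(log, msg)
  }
  if (is.null(gene_universe))
    gene_universe <- rownames(training_cohorts[[1L]]$expression)
  for (co in training_cohorts)
    note("training cohort %s: %d samples, %d events, %d/%d universe genes",
         co$name, ncol(co$expression), sum(co$clinical$os_event),
         length(intersect(gene_universe, rownames(co$expression))),
         length(gene_universe))

  screening <- screen_cohorts(training_cohorts, gene_universe)
  note("screened %d genes across %d training cohorts",
       length(unique(screening$gene_id)), length(training_cohorts))
  meta <- meta_analyse(screening)
  selected <- select_prognostic_genes(meta, p_threshold, fdr_threshold)
  if (nrow(selected) == 0L)
    stop("pipeline aborted: no gene passed meta_p < ", p_threshold,
         " and fdr_q < ", fdr_threshold)
  note("selected %d prognostic genes (%d poor, %d good)", nrow(selected),
       sum(selected$direction == "poor"), sum(selected$direction == "good"))
  weights <- compute_weights(selected)

  all_cohorts <- c(training_cohorts, validation_cohorts)
  role <- rep(c("training", "validation"),
              c(length(training_cohorts), length(validation_cohorts)))
  scores <- do.call(rbind, lapply(all_cohorts, score_cohort, weights,
                                  standardize_genes = standardize_genes))
  scores$role <- role[match(scores$cohort_name,
                            vapply(all_cohorts, `[[`, "", "name"))]

  evaluation <- do.call(rbind, lapply(seq_along(all_cohorts), function(i)
    evaluate_cohort(all_cohorts[[i]],
                    scores[scores$cohort_name == all_cohorts[[i]]$name, ],
                    horizons_years, role[i])))
  note("evaluated %d cohorts at horizons {%s} years", length(all_cohorts),
       paste(horizons_years, collapse = ", "))

  enrichment <- NULL
  if (!is.null(immune_sets) && length(immune_sets)) {
    enr <- lapply(all_cohorts, function(co) {
      em <- ssgsea_scores(co$expression, immune_sets)
      sc_co <- scores[scores$cohort_name == co$name, ]
      st <- sc_co$stratum[match(colnames(em), sc_co$sample_id)]
      cmp <- compare_enrichment(em, st)
      cmp$cohort_name <- co$name
      cmp
    })
    enrichment <- do.call(rbind, enr)
    note("enrichment scored: %d sets x %d cohorts", length(immune_sets),
         length(all_cohorts))
  } else note("enrichment stage skipped: no immune gene sets supplied")

  chemo <- NULL
  with_resp <- Filter(function(co)
    "chemo_response" %in% names(co$clinical) &&
      any(!is.na(co$clinical$chemo_response)), all_cohorts)
  if (length(with_resp)) {
    chemo <- do.call(rbind, lapply(with_resp, function(co)
      chemo_stage(co, scores, immune_sets, response_scheme)))
    note("chemosensitivity evaluated in %d cohort(s)", length(with_resp))
  } else note("chemo stage skipped: no cohort carries response labels")

  report <- list(screening = screening, meta = meta, selected = selected,
                 weights = weights, scores = scores,
                 evaluation = evaluation, enrichment = enrichment,
                 chemo = chemo, log = log,
                 config = list(p_threshold = p_threshold,
                               fdr_threshold = fdr_threshold,
                               horizons_years = horizons_years,
                               response_scheme = response_scheme,
                               standardize_genes = standardize_genes,
                               seed = seed,
                               n_training = length(training_cohorts),
                               n_validation = length(validation_cohorts),
                               version = as.character(
                                 utils::packageVersion("grpscore"))))
  class(report) <- "grp_report"
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

# Survival evaluation of one scored cohort: log-rank high vs low, Cox on
# the z score, time-dependent AUC at each horizon; repeated on RFS when
# the clinical table has rfs columns.
evaluate_cohort <- function(co, sc, horizons_years, role) {
  sc <- sc[match(co$clinical$sample_id, sc$sample_id), ]
  endpoints <- list(OS = c("os_time", "os_event"))
  if (all(c("rfs_time", "rfs_event") %in% names(co$clinical)))
    endpoints$RFS <- c("rfs_time", "rfs_event")
  out <- list()
  for (ep in names(endpoints)) {
    tt <- co$clinical[[endpoints[[ep]][1L]]]
    ev <- co$clinical[[endpoints[[ep]][2L]]]
    lr <- logrank_test(tt, ev, sc$stratum)
    cx <- fit_cox(matrix(sc$z_score, ncol = 1L,
                         dimnames = list(NULL, "grp_z")), tt, ev)
    aucs <- vapply(horizons_years, function(h)
      tryCatch(time_dependent_auc(sc$z_score, tt, ev, h * 365.25),
               error = function(e) NA_real_), numeric(1L))
    out[[ep]] <- data.frame(
      cohort_name = co$name, role = role, endpoint = ep,
      n = length(tt), n_events = sum(ev),
      logrank_chi_square = lr$chi_square, logrank_p = lr$p,
      cox_hr_per_z = cx$hr, cox_p = cx$wald_p,
      t(setNames(aucs, paste0("auc_", horizons_years, "y"))),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Chemo stage for one cohort: GRP-alone AUC (risk score negated so that
# higher values predict response) and, when immune sets are available, the
# ridge-logistic combination of GRP with significantly different immune
# enrichment scores.
chemo_stage <- function(co, scores, immune_sets, response_scheme) {
  enc <- encode_response(co$clinical, response_scheme)
  sc_co <- scores[scores$cohort_name == co$name, ]
  sc <- sc_co[match(names(enc$labels), sc_co$sample_id), ]
  grp_benefit <- -sc$z_score
  auc_grp <- roc_auc(grp_benefit, enc$labels)
  auc_combined <- NA_real_
  n_immune_kept <- NA_integer_
  if (!is.null(immune_sets) && length(immune_sets)) {
    em <- ssgsea_scores(co$expression, immune_sets)
    feats <- cbind(GRP = grp_benefit,
                   t(em[, names(enc$labels), drop = FALSE]))
    fit <- combine_predictors(feats, enc$labels, select_features = TRUE)
    auc_combined <- fit$auc
    n_immune_kept <- sum(fit$kept_features != "GRP")
  }
  data.frame(cohort_name = co$name, scheme = enc$scheme,
             n_pos = enc$n_pos, n_neg = enc$n_neg, auc_grp = auc_grp,
             n_immune_kept = n_immune_kept, auc_combined = auc_combined,
             stringsAsFactors = FALSE)
}

#' Write a pipeline report to disk
#'
#' Each stage table becomes a TSV; the stage log and config echo go to
#' `report.json`.
#'
#' @param report A `grp_report`.
#' @param output_dir Directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("screening", "meta", "selected", "scores", "evaluation",
              "enrichment", "chemo")
  for (nm in tables) {
    tab <- report[[nm]]
    if (!is.null(tab))
      write.table(tab, file.path(output_dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_weights(report$weights, file.path(output_dir, "weights.tsv"))
  jsonlite::write_json(list(log = report$log, config = report$config),
                       file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.grp_report <- function(x, ...) {
  cat("<grp_report>\n")
  for (l in x$log) cat("  - ", l, "\n", sep = "")
  invisible(x)
}
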