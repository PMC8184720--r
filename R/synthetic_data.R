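#' Configuration for the multi-cohort simulator
#'
#' Defaults emulate the structure of the public pancreatic-cancer cohort
#' compendia this package is designed for: six cohorts of 150 patients,
#' a 106-gene candidate universe of which a minority (15) carry survival
#' effects in consistent directions across cohorts, cohort-level location
#' shifts, exponential event times under proportional hazards, and an
#' administrative uniform censoring window tuned to the target censoring
#' rate.
#'
#' @param n_cohorts Number of cohorts (default 6, the training design).
#' @param n_per_cohort Samples per cohort (default 150; the real cohorts
#'   range 60-300).
#' @param n_genes Size of the candidate gene universe (default 106).
#' @param n_planted Number of genes with true survival effects (default 15).
#' @param effect_size_range Range of |log HR| per standardized expression
#'   unit for planted genes (default c(0.5, 0.9)); signs are random but
#'   identical across cohorts.
#' @param cohort_shift_sd SD of the per-cohort location shift added to
#'   every gene (default 0.3 log2 units).
#' @param noise_sd Within-cohort expression SD (default 1 log2 unit).
#' @param baseline_hazard Exponential baseline hazard per day (default
#'   0.002: median survival around one year at zero risk, typical of
#'   pancreatic ductal adenocarcinoma).
#' @param censoring_rate Target overall censoring proportion (default 0.35).
#' @param n_immune_sets,immune_set_size,immune_shift Optional immune marker
#'   genes appended to the matrix: `n_immune_sets` sets of
#'   `immune_set_size` genes whose expression is shifted by
#'   `-immune_shift * latent_risk` (higher-risk samples have lower immune
#'   marker expression). Default 0 sets.
#' @param response_intercept,response_slope Logistic link from latent risk
#'   to chemotherapy response, P(responder) = plogis(a + b * risk); the
#'   default slope -1 makes high-risk patients less likely to respond.
#' @param add_rfs Also generate recurrence-free survival columns (default
#'   `FALSE`).
#' @param seed Integer seed; fully determines the output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cohorts = 6L, n_per_cohort = 150L, n_genes = 106L,
                       n_planted = 15L,
                       effect_size_range = c(0.5, 0.9),
                       cohort_shift_sd = 0.3, noise_sd = 1,
                       baseline_hazard = 0.002, censoring_rate = 0.35,
                       n_immune_sets = 0L, immune_set_size = 12L,
                       immune_shift = 0.5,
                       response_intercept = 0, response_slope = -1,
                       add_rfs = FALSE, seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              n_per_cohort = as.integer(n_per_cohort),
              n_genes = as.integer(n_genes),
              n_planted = as.integer(n_planted),
              effect_size_range = effect_size_range,
              cohort_shift_sd = cohort_shift_sd, noise_sd = noise_sd,
              baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate,
              n_immune_sets = as.integer(n_immune_sets),
              immune_set_size = as.integer(immune_set_size),
              immune_shift = immune_shift,
              response_intercept = response_intercept,
              response_slope = response_slope,
              add_rfs = isTRUE(add_rfs), seed = as.integer(seed))
  stopifnot(cfg$n_cohorts >= 1L, cfg$n_per_cohort >= 4L, cfg$n_genes >= 2L,
            cfg$n_planted >= 0L, cfg$n_planted <= cfg$n_genes,
            length(cfg$effect_size_range) == 2L,
            all(cfg$effect_size_range >= 0),
            cfg$noise_sd > 0, cfg$baseline_hazard > 0,
            cfg$censoring_rate >= 0, cfg$censoring_rate < 1)
  class(cfg) <- "sim_config"
  cfg
}

# Expected censoring proportion for C ~ Uniform(0, W) given per-sample
# exponential event rates: E[(1 - exp(-rate * W)) / (rate * W)].
expected_censoring <- function(W, rates) {
  mean((1 - exp(-rates * W)) / (rates * W))
}

# Solve for the administrative window W hitting the target censoring rate.
tune_censoring_window <- function(rates, target) {
  lo <- 1e-6; hi <- 1e9
  f_lo <- expected_censoring(lo, rates)
  f_hi <- expected_censoring(hi, rates)
  if (target > f_lo || target < f_hi)
    stop(sprintf("infeasible censoring target %.3f; achievable range [%.4f, %.4f]",
                 target, f_hi, f_lo))
  uniroot(function(w) expected_censoring(w, rates) - target,
          lower = lo, upper = hi, tol = 1e-8)$root
}

#' Simulate multi-cohort expression + survival data with known truth
#'
#' Per cohort, gene expression is Normal(mu_g + delta_c, noise_sd^2) with a
#' cohort-level shift delta_c; the latent risk of a sample is the sum of
#' planted log-hazard coefficients times standardized expression (so
#' |log HR| is comparable across genes regardless of their means); event
#' times are exponential with rate baseline_hazard * exp(risk); censoring
#' times are uniform on (0, W) with W tuned per cohort to the target
#' censoring rate. Optional immune marker genes are appended with
#' expression down-shifted in high-risk samples.
#'
#' @param config A [sim_config()].
#' @return List with `cohorts` (list of `grp_cohort`) and `truth`
#'   (class `sim_truth`): `planted_gene_ids`, `planted_log_hr` (named,
#'   signed), `glyco_genes` (the candidate universe), `immune_sets`
#'   (named list of gene vectors), `latent_risk` (per cohort, named per
#'   sample), response parameters, `censoring_rate`, `seed`, `config`.
#' @export
simulate_multi_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  mu <- rnorm(config$n_genes, mean = 6, sd = 1.5)
  names(mu) <- genes
  planted <- sort(sample(genes, config$n_planted))
  beta <- runif(config$n_planted, config$effect_size_range[1L],
                config$effect_size_range[2L]) *
    sample(c(-1, 1), config$n_planted, replace = TRUE)
  names(beta) <- planted

  imm_sets <- list()
  imm_genes <- character(0)
  imm_mu <- numeric(0)
  if (config$n_immune_sets > 0L) {
    type_names <- immune_cell_type_names(config$n_immune_sets)
    for (k in seq_len(config$n_immune_sets)) {
      ids <- sprintf("IMM%02d_G%02d", k, seq_len(config$immune_set_size))
      imm_sets[[type_names[k]]] <- ids
      imm_genes <- c(imm_genes, ids)
    }
    imm_mu <- rnorm(length(imm_genes), mean = 5, sd = 1)
    names(imm_mu) <- imm_genes
  }

  cohorts <- vector("list", config$n_cohorts)
  latent <- vector("list", config$n_cohorts)
  cohort_names <- sprintf("SIM%02d", seq_len(config$n_cohorts))
  for (c_idx in seq_len(config$n_cohorts)) {
    n <- config$n_per_cohort
    delta <- rnorm(1L, 0, config$cohort_shift_sd)
    z <- matrix(rnorm(config$n_genes * n), config$n_genes, n,
                dimnames = list(genes, NULL))
    expr <- mu + delta + config$noise_sd * z
    eta <- drop(crossprod(z[planted, , drop = FALSE], beta))
    rates <- config$baseline_hazard * exp(eta)
    t_event <- rexp(n, rate = rates)
    if (config$censoring_rate > 0) {
      W <- tune_censoring_window(rates, config$censoring_rate)
      t_cens <- runif(n, 0, W)
    } else {
      t_cens <- rep(Inf, n)
    }
    os_time <- pmin(t_event, t_cens)
    os_event <- as.numeric(t_event <= t_cens)
    sid <- sprintf("%s_S%03d", cohort_names[c_idx], seq_len(n))
    colnames(expr) <- sid
    clin <- data.frame(sample_id = sid, os_time = os_time,
                       os_event = os_event, stringsAsFactors = FALSE)
    if (config$add_rfs) {
      t_rfs <- rexp(n, rate = 1.5 * rates)
      clin$rfs_time <- pmin(t_rfs, t_cens)
      clin$rfs_event <- as.numeric(t_rfs <= t_cens)
    }
    if (length(imm_genes)) {
      zi <- matrix(rnorm(length(imm_genes) * n), length(imm_genes), n,
                   dimnames = list(imm_genes, sid))
      imm_expr <- imm_mu + delta + config$noise_sd * zi -
        config$immune_shift * rep(eta, each = length(imm_genes))
      expr <- rbind(expr, imm_expr)
    }
    names(eta) <- sid
    latent[[c_idx]] <- eta
    cohorts[[c_idx]] <- cohort(cohort_names[c_idx], expr, clin)
  }
  names(cohorts) <- cohort_names
  names(latent) <- cohort_names
  truth <- structure(
    list(planted_gene_ids = planted, planted_log_hr = beta,
         glyco_genes = genes, immune_sets = imm_sets,
         latent_risk = latent,
         response_intercept = config$response_intercept,
         response_slope = config$response_slope,
         censoring_rate = config$censoring_rate,
         seed = config$seed, config = config),
    class = "sim_truth")
  list(cohorts = cohorts, truth = truth)
}

# 28 immune cell types of the standard tumour-infiltration marker panel;
# used to name simulated immune marker sets.
immune_cell_type_names <- function(n) {
  panel <- c(
    "Activated B cell", "Activated CD4 T cell", "Activated CD8 T cell",
    "Activated dendritic cell", "CD56bright natural killer cell",
    "CD56dim natural killer cell", "Central memory CD4 T cell",
    "Central memory CD8 T cell", "Effector memory CD4 T cell",
    "Effector memory CD8 T cell", "Eosinophil", "Gamma delta T cell",
    "Immature B cell", "Immature dendritic cell", "Macrophage",
    "Mast cell", "MDSC", "Memory B cell", "Monocyte",
    "Natural killer cell", "Natural killer T cell", "Neutrophil",
    "Plasmacytoid dendritic cell", "Regulatory T cell",
    "T follicular helper cell", "Type 1 T helper cell",
    "Type 17 T helper cell", "Type 2 T helper cell")
  if (n <= length(panel)) panel[seq_len(n)]
  else c(panel, sprintf("Immune set %02d", seq_len(n - length(panel))))
}

#' Simulate chemotherapy response from the latent risk
#'
#' P(responder) = plogis(a + b * risk) with the truth's response
#' parameters; responders are split CR/PR and non-responders SD/PD by a
#' secondary uniform draw, so both binary encoding schemes are exercised.
#'
#' @param cohort A simulated `grp_cohort`.
#' @param truth The matching `sim_truth`.
#' @param seed Seed for the response draws (default `truth$seed + 1`).
#' @param cr_fraction Probability a responder is CR rather than PR
#'   (default 0.5); non-responders are SD/PD with equal probability.
#' @return The cohort with a `chemo_response` column added to its clinical
#'   table.
#' @export
simulate_response <- function(cohort, truth, seed = truth$seed + 1L,
                              cr_fraction = 0.5) {
  stopifnot(inherits(cohort, "grp_cohort"), inherits(truth, "sim_truth"))
  eta <- truth$latent_risk[[cohort$name]]
  if (is.null(eta)) stop("no latent risk recorded for cohort ", cohort$name)
  set.seed(seed)
  p <- plogis(truth$response_intercept + truth$response_slope * eta)
  responder <- rbinom(length(eta), 1L, p)
  u <- runif(length(eta))
  resp <- ifelse(responder == 1L,
                 ifelse(u < cr_fraction, "CR", "PR"),
                 ifelse(u < 0.5, "SD", "PD"))
  cohort$clinical$chemo_response <- resp
  cohort
}

#' Write simulated cohorts plus ground truth to disk
#'
#' Emits the exact TSV dialects [load_cohort()] reads plus a `truth.json`
#' for test harnesses.
#'
#' @param sim Output of [simulate_multi_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (co in sim$cohorts) {
    ep <- file.path(dir, paste0(co$name, "_expression.tsv"))
    cp <- file.path(dir, paste0(co$name, "_clinical.tsv"))
    write_cohort(co, ep, cp)
    paths <- c(paths, ep, cp)
  }
  tj <- file.path(dir, "truth.json")
  truth <- sim$truth
  jsonlite::write_json(
    list(planted_gene_ids = truth$planted_gene_ids,
         planted_log_hr = as.list(truth$planted_log_hr),
         immune_sets = truth$immune_sets,
         response_intercept = truth$response_intercept,
         response_slope = truth$response_slope,
         censoring_rate = truth$censoring_rate, seed = truth$seed),
    tj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tj))
}
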