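# grpscore

Multi-cohort construction and evaluation of a glycolysis-related
prognostic (GRP) expression score for survival cohorts, with pancreatic
ductal adenocarcinoma (PDAC) as the motivating disease. Tumours that
rely on aerobic glycolysis (the Warburg effect) tend to behave more
aggressively, so the expression of glycolytic-process genes carries
prognostic information; `grpscore` turns a candidate gene list (e.g.
MSigDB `GO_GLYCOLYTIC_PROCESS`) plus several independent expression +
survival cohorts into a single weighted gene score, and then evaluates
that score for survival stratification, immune-infiltration contrasts
and chemotherapy-response prediction. It is aimed at computational
biologists building or auditing prognostic gene signatures from public
cohort compendia (TCGA / ICGC / GEO / ArrayExpress-style data).

## The method

For each candidate gene *i* and cohort *c*, samples are split at the
within-cohort median of the gene's (log2) expression — ties go to the
low group — and the high-expression indicator is tested by Cox
proportional-hazards regression (Efron tie correction), giving a log
hazard ratio *b<sub>ic</sub>* with standard error *s<sub>ic</sub>*.
Per-cohort estimates are pooled by fixed-effects inverse-variance
meta-analysis on the log scale:

    w_ic = 1 / s_ic^2
    b_i  = Σ_c w_ic b_ic / Σ_c w_ic ,   se(b_i) = (Σ_c w_ic)^(-1/2)

so `HR_i = exp(b_i)` and, by the delta method,
`SE(HR_i) = HR_i · se(b_i)`. Genes passing *p* < 0.001 **and**
Benjamini–Hochberg FDR < 0.001 (strict, across the whole screened
universe) form the signature, each labelled *poor* (HR > 1) or *good*
(HR < 1). The per-sample score is

    GRP(s) = Σ_i (HR_i − 1) / SE(HR_i) · x_is

with *x<sub>is</sub>* the gene's expression as loaded; dividing by
SE(HR) damps imprecisely estimated genes so cohort size does not
dominate the weighting. Scores are z-normalized within each cohort and
dichotomized at the cohort median into high/low GRP strata. Weights are
frozen on the training cohorts; validation cohorts only recompute the
z-normalization and the median cut.

Evaluation machinery included: Kaplan–Meier curves and the two-group
log-rank test; uni-/multivariate Cox fits; cumulative/dynamic
time-dependent ROC AUC with inverse-probability-of-censoring weights
(Kaplan–Meier censoring estimate, horizons 1/2/3 years by default);
single-sample gene-set enrichment (ssGSEA, exponent α = 0.25) for
immune cell-type marker sets with rank-sum contrasts between strata;
RECIST response encodings (CR/PR vs SD/PD, CR vs non-CR), ROC AUC via
the tie-aware Mann–Whitney identity, and a ridge-logistic combination
of the GRP score with immune enrichment features.

A seeded synthetic multi-cohort generator (`simulate_multi_cohort`)
plants known gene effects under proportional hazards, tunes an
administrative censoring window to a target rate, and links
chemotherapy response to the latent risk, so every pipeline stage is
testable against ground truth without any data downloads.

## Worked example

Six simulated training cohorts and one held-out cohort (150 patients
each, 106 candidate genes, 15 with planted effects):

```r
library(grpscore)

cfg <- sim_config(n_cohorts = 7L, n_immune_sets = 28L, seed = 42)
sim <- simulate_multi_cohort(cfg)
train <- sim$cohorts[1:6]
val   <- simulate_response(sim$cohorts[[7]], sim$truth)

glyco <- read_gmt(system.file("extdata", "glycolytic_process_synthetic.gmt",
                              package = "grpscore"))
report <- run_pipeline(train, list(val),
                       gene_universe = glyco[[1]]$members,
                       immune_sets   = sim$truth$immune_sets)
#> [grpscore] training cohort SIM01: 150 samples, 97 events, 106/106 universe genes
#> ...
#> [grpscore] screened 106 genes across 6 training cohorts
#> [grpscore] selected 11 prognostic genes (4 poor, 7 good)
#> [grpscore] evaluated 7 cohorts at horizons {1, 2, 3} years
#> [grpscore] enrichment scored: 28 sets x 7 cohorts
#> [grpscore] chemosensitivity evaluated in 1 cohort(s)

head(report$selected[, c("gene_id", "pooled_hr", "se_hr",
                         "meta_p", "fdr_q", "direction")], 3)
#>   gene_id pooled_hr  se_hr   meta_p    fdr_q direction
#> 1   G0005     0.587 0.0499 3.77e-10 9.98e-09      good
#> 2   G0010     1.479 0.1259 4.19e-06 5.55e-05      poor
#> 3   G0014     0.572 0.0489 6.36e-11 2.25e-09      good

subset(report$evaluation, role == "validation")
#>     cohort_name       role endpoint   n n_events logrank_chi_square logrank_p
#> OS6       SIM07 validation       OS 150      103               84.8  3.28e-20
#>     cox_hr_per_z    cox_p auc_1y auc_2y auc_3y
#> OS6         4.16 3.31e-26  0.896   0.88  0.939

report$chemo
#>   cohort_name       scheme n_pos n_neg auc_grp n_immune_kept auc_combined
#> 1       SIM07 CRPR_vs_SDPD    75    75   0.841            28        0.972
```

Reading the output: 11 of the 106 candidates pass the double threshold;
each selected gene's pooled hazard ratio and its delta-method standard
error become the score weight `(HR − 1)/SE(HR)` (e.g. G0005:
(0.587 − 1)/0.0499 ≈ −8.3, a protective gene subtracting from the
score). In the held-out cohort the frozen-weight score separates
survival (log-rank p ≈ 3e-20; hazard ratio ≈ 4.2 per score SD) and
discriminates events at 1–3 years (AUC 0.88–0.94). The negated score
predicts chemotherapy response (AUC 0.84) and improves when combined
with immune-infiltration enrichment scores by ridge-logistic regression
(in-sample AUC 0.97). These numbers come from strongly planted
synthetic effects; on real cohorts all of them would be lower.

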