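---
title: "Methods: building and evaluating a glycolysis-related prognostic score"
author: "grpscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and evaluating a glycolysis-related prognostic score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`grpscore` builds a weighted gene-expression score for survival
prognosis from several independent cohorts, in the tradition of
glycolysis-related prognostic (GRP) signatures for pancreatic ductal
adenocarcinoma. The pipeline has five statistical stages, each exposed
as ordinary functions so any stage can be run, audited or replaced on
its own:

1. **Per-gene screening.** Within each cohort, a candidate gene's
   samples are dichotomized at the cohort median of its log2
   expression; values equal to the median go to the *low* group. The
   high-expression indicator enters a univariate Cox
   proportional-hazards model (Efron correction for tied event times,
   the convention of mainstream survival software; ties are the norm in
   day-resolution registries). Wald inference is reported because the
   next stage consumes (log HR, SE) pairs, for which Wald is the
   matching p-value.
2. **Fixed-effects meta-analysis.** Per-cohort log hazard ratios are
   pooled by inverse-variance weighting on the log scale; the pooled
   SE is `(Σ 1/se²)^(-1/2)`. The hazard-ratio-scale standard error that
   the score weights need is recovered by the delta method,
   `SE(HR) = HR · se(log HR)`. Pooling on the log scale is the
   statistically standard choice; the delta method reconciles it with a
   weight formula stated on the HR scale without changing either.
   Genes missing from one cohort's platform are pooled over the
   cohorts that measure them (`n_cohorts` records how many).
3. **Selection.** Genes with meta-analysis `p < 0.001` **and**
   Benjamini–Hochberg `FDR < 0.001` (strict inequalities; BH applied
   once across the whole screened universe, not per cohort) form the
   signature, labelled *poor* (HR > 1) or *good* (HR < 1).
4. **Scoring.** `GRP(s) = Σ_i (HR_i − 1)/SE(HR_i) · x_is`. Dividing by
   SE(HR) shrinks the influence of imprecisely estimated genes, so a
   very large cohort cannot dominate the weighting through precision
   alone. The final score is z-normalized within each cohort
   (sample-SD, `n − 1`) and split at the cohort median (ties low) into
   high/low strata. Weights are *frozen* after training; a validation
   cohort only recomputes its own z-normalization and median cut, never
   the weights.
5. **Evaluation.** Kaplan–Meier/log-rank between strata, Cox models on
   the continuous z-score (optionally multivariate), time-dependent
   cumulative/dynamic ROC, ssGSEA immune-infiltration contrasts, and
   RECIST chemotherapy-response discrimination.

## Interpretation of `gene(i)` in the score

The weighted sum uses each gene's expression **as loaded** (log2
scale), not gene-wise standardized; the single z-normalization is
applied to the finished score per cohort. This follows the weighted-sum
formulation literally, and median-based stratification is invariant to
the choice anyway. Because the alternative reading (z-scoring each gene
first) changes continuous-score analyses across platforms with
different dynamic ranges, `compute_grp_scores(..., standardize_genes =
TRUE)` exposes it as a sensitivity switch; no default behaviour depends
on it.

## Time-dependent ROC

`time_dependent_auc` implements the cumulative/dynamic definition:
cases are subjects with an observed event by the horizon *t*, controls
are subjects still at risk after *t*. Censoring before *t* is handled
by inverse-probability-of-censoring weights from a Kaplan–Meier
estimate of the censoring distribution: a case observed at time *T*
gets weight `1/G(T−)` (left limit), every control gets `1/G(t)`. At
tied times, events are removed from the censoring-KM risk set before
censorings are counted. Tied scores receive half credit, which makes
the estimator reduce *exactly* to the plain Mann–Whitney AUC of the
event indicator when no one is censored before the horizon. Default
horizons are 1, 2 and 3 years (with times in days) — conventional for
pancreatic cancer, where median survival is near one year; they are a
plain argument, not a constant.

## ssGSEA scoring

For each sample, genes are ranked by expression (descending, average
ranks for ties). Walking down the ranking, the enrichment score is the
integrated difference between the weighted in-set empirical CDF
(weights `rank^α`, normalized within the set) and the unweighted
out-of-set ECDF. `α = 0.25` is the default of the single-sample GSEA
family this implements. With `normalize = TRUE` all scores are divided
by the global max–min range of the matrix, so scores are comparable
across sets within one matrix but not across matrices. A set covering
the whole gene universe has no out-of-set ECDF and is rejected; sets
with no measured genes are dropped with a warning. Being rank-based,
scores are exactly invariant to strictly increasing transforms of
expression — asserted in the tests.

## Small-sample statistics

* `rank_sum_test` computes U from average ranks. For `n₁ + n₂ ≤ 10` the
  two-sided p comes from exact enumeration of all `C(n, n₁)` label
  assignments (correct under ties, where the classical exact tables do
  not apply); otherwise from the normal approximation with the
  tie-corrected variance and no continuity correction.
* `contingency_test` uses the Pearson chi-square without continuity
  correction, falling back to the Fisher exact test for 2×2 tables with
  any expected count below 5, and reports which route was taken.
* `combine_predictors` fits ridge-penalized logistic regression by
  iteratively reweighted least squares with a small fixed penalty
  (default λ = 1e-3, never on the intercept). The penalty keeps the
  optimum finite under complete separation and makes the degenerate
  single-feature case well-defined. The reported AUC is in-sample,
  matching how a single combined ROC curve is usually presented;
  `k_fold > 1` adds an honest cross-validated AUC. Feature selection
  (`select_features = TRUE`) keeps predictors whose class-wise rank-sum
  p is below 0.05 before fitting, mirroring the practice of first
  asking which immune cell types differ between responders and
  non-responders.

Both RECIST encodings are first-class (`CRPR_vs_SDPD`, `CR_vs_nonCR`)
because published chemosensitivity ROC analyses use either grouping;
nothing in the pipeline assumes one of them.

## The synthetic cohort generator

`simulate_multi_cohort` emulates the structure of multi-centre PDAC
expression compendia:

| parameter | default | rationale |
|---|---|---|
| `n_cohorts` × `n_per_cohort` | 6 × 150 | six training cohorts; real cohorts span ~60–300 patients |
| `n_genes`, `n_planted` | 106, 15 | a glycolytic-process-sized candidate list with a minority of true effects |
| `effect_size_range` | \|log HR\| ∈ [0.5, 0.9] | per-SD effects typical of single-gene prognostic markers |
| `cohort_shift_sd` | 0.3 (log2 units) | cohort-level location shifts (platform/centre effects) |
| `noise_sd` | 1 (log2 units) | within-cohort biological + technical spread |
| `baseline_hazard` | 0.002 / day | median survival ≈ 1 year at zero risk, typical of PDAC |
| `censoring_rate` | 0.35 | registry-like follow-up: roughly two-thirds of patients die on study |

Expression is `Normal(μ_g + δ_c, σ²)`; effects are planted on
*standardized* expression so `|log HR|` is comparable across genes
regardless of their means; event times are exponential
(one-parameter baseline — sufficient for proportional-hazards recovery
and fewer knobs than a Weibull); censoring is an administrative uniform
window `U(0, W)` with `W` solved numerically per cohort so the expected
censored fraction hits the target (realized rates stay within ±5
points; asserted over 20 seeds). Chemotherapy response follows
`P(responder) = plogis(a + b·risk)` with default slope −1 (high-risk
patients respond less), split CR/PR and SD/PD by a secondary uniform
draw so both encodings are exercised. Optional immune marker sets are
appended with expression shifted by `−immune_shift · risk`, emulating
reduced immune infiltration in glycolysis-high tumours.

What the generator deliberately does **not** emulate: RNA-seq count
noise (expression is Gaussian on the log scale), gene–gene
co-expression (genes are independent given the cohort shift),
platform-specific missingness, informative censoring, and competing
risks. Tests passing on this generator therefore demonstrate
correctness of the statistical machinery and the training/validation
plumbing — not robustness to those real-data complications.

## Numerical choices and degenerate inputs

* Ties at the median go to the low group, both for gene screening and
  score stratification; a gene with more than half its samples at the
  median is refused (`degenerate dichotomization`).
* Constant covariates, zero-event cohorts, zero-variance scores,
  empty gene-set overlaps and single-class response vectors are
  explicit errors naming the offender, not silent NAs.
* Cox fits that fail to reach finite estimates (monotone likelihood /
  complete separation) error rather than returning a boundary value;
  the per-gene screen skips such genes in that cohort with a warning
  and pools the remaining cohorts.
* BH adjustment validates `p ∈ (0, 1]` and preserves input order;
  adjusted values can only increase, so `q ≥ p` always holds and is
  asserted in the tests.
* All simulation and pipeline behaviour is a pure function of the
  configuration seed; identical seeds give byte-identical output.

## A note on marginal attenuation

When many genes carry survival effects simultaneously, the latent risk
that *other* genes contribute acts as unobserved heterogeneity
(frailty) for any single gene's marginal Cox fit. With 15 planted genes
at |log HR| ∈ [0.5, 0.9], the latent-risk variance is ≈ 7, and the
marginal median-dichotomized coefficient of a gene shrinks to roughly
half its planted per-SD value (a single planted gene, by contrast,
yields a dichotomized coefficient *larger* than β, because the
between-half mean spread of a standard normal is ≈ 1.6). Consequently,
under the default generator the stringent double threshold recovers
most but not always ≥80% of planted genes; the weakest planted effects
sit near the detection boundary. This is a property of marginal
screening itself, not of the implementation — worth remembering when
interpreting how many "true" genes any such published screen can catch.

## Test problem sizes

The test suite runs entirely on generated data. Module-level property
tests use scaled-down designs (2–3 cohorts of 40–150 samples, 5–30
genes, 10–20 seeds) chosen to keep each property sharply identifiable;
the end-to-end checks use the full 6 × 150 / 106-gene design over 20
seeds, and large-sample oracle comparisons use single cohorts of
2 000–5 000 samples against frozen Monte-Carlo or numeric-integration
references.

## Known limitations

* Gene identifiers are opaque strings: no probe collapsing, no symbol
  alias mapping, no batch correction — inputs are expected
  pre-processed (normalized, log2, one row per gene).
* Fixed-effects pooling only; no heterogeneity statistics (I²,
  Cochran's Q) or random-effects alternative.
* No cut-point optimization beyond the median, no penalized or
  stratified Cox, no competing-risks machinery.
* The in-sample combined-AUC is optimistic by construction; use the
  `k_fold` option when honest discrimination estimates matter.
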