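# pathresp

Grading pathological response to neoadjuvant chemotherapy (NACT) in locally
advanced cervical cancer, and linking the grades to outcome.

## The problem

After NACT and radical hysterectomy, the resection specimen carries the most
direct evidence of how well the tumor responded — but cervical cancer has no
widely adopted system for reading it. `pathresp` implements a resection-based
evaluation pipeline for pathologists and biostatisticians working with such
cohorts:

- **Tumor-bed composition.** Each tumor bed is partitioned into viable tumor,
  necrosis, inflammatory stroma and fibrotic stroma, with the four
  percentages summing to 100. Per-slide estimates are averaged per specimen
  and reported on the conventional grid (5% increments, single-digit
  percentages below 10%).
- **Response grading.** From residual viable tumor *v*:
  cPR (*v* = 0), mPR (0 < *v* ≤ 10), pPR (10 < *v* ≤ 50), nPR (*v* > 50);
  cPR∪mPR∪pPR form the *good* response group, nPR the *poor* group.
- **Stromal typing.** The three non-viable components classify the
  post-treatment stroma as inflammatory, fibrotic or necrotic when one
  component exceeds both others by more than 10 percentage points, and
  intermediate otherwise.
- **Biomarker scoring.** Stromal TILs grade (≤5 / 6–50 / >50%), the
  tumor-infiltrating lymphocyte volume
  **TILV = stroma-in-tumor (%) × stromal TILs (%)**,
  CD8/CD4/FOXP3 densities from triplicate high-power-field counts,
  CD4/CD8 and CD8/FOXP3 ratios, PD-L1 CPS/TPS/IPS with ≥1 positivity, and
  Youden-index (max sensitivity + specificity) dichotomization of any
  continuous marker.
- **Radiology.** Three-category RECIST-style response from pre/post longest
  diameters (CR = resolution, PR = >30% decrease, SD = the rest).
- **Statistics.** Fisher/chi-square association testing with the standard
  expected-count selection rule, Spearman and Kruskal–Wallis tests,
  univariate/multivariate logistic regression (odds ratios, Wald CIs),
  Kaplan–Meier/log-rank and Cox proportional-hazards models for OS and DFS,
  and a "Table 1"-style stratified cohort summary.
- **Synthetic cohorts.** `generate_cohort()` draws cohorts with the
  published statistical structure (response mixture 27/49/58/51 of 185,
  TILV→response odds ratio 2.375, stromal-type survival hazard ratios
  3.749/4.719 per ordinal step), so the whole pipeline is testable without
  access to patient data.

## Worked example

```r
library(pathresp)

# the seven-patient chemo-immunotherapy worked example
generate_fixture_suite(tempdir())
co  <- read_cohort(slides = file.path(tempdir(), "nacit_slides.csv"))
rep <- run_pipeline(co)
table(rep$cohort$grade)
#> cPR mPR pPR nPR
#>   1   4   1   1
round_half_up(100 * mean(rep$cohort$response == "good"))
#> [1] 85.7

# a full synthetic cohort
rep2 <- run_pipeline(generate_cohort(cohort_config(n = 185), seed = 7))
rep2
#> Pathological-response pipeline report
#>   patients: 185; stages run: 12
#>   response grades: cPR 25, mPR 55, pPR 49, nPR 56
#>   good response: 69.7%
#>   stromal types: inflammatory 48, fibrotic 52, necrotic 9, intermediate 76
#>   TILV Youden cutoff: 74.7
#>   DFS stromal-type HR/step: 5.502 (4.154-7.288)
```

Grades and stromal types are re-derived from the slide-level table; the
report bundles the stratified baseline table, logistic odds-ratio tables,
Kaplan–Meier curves, log-rank tests and Cox hazard-ratio tables, with a
provenance log of every stage and parameter.

Single operations work standalone:

```r
compute_tilv(30, 80)                        # 2400
classify_pathological_response(c(0, 15, 65))  # cPR pPR nPR
pearson_chi2(matrix(c(20, 17, 114, 34), 2))  # p = 0.005157
```

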