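---
title: "Grading pathological response to neoadjuvant chemotherapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading pathological response to neoadjuvant chemotherapy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathresp)
```

## The model

`pathresp` evaluates response to neoadjuvant chemotherapy (NACT) in locally
advanced cervical cancer from the resection specimen. The central object is
the **tumor bed** — the region where the pre-treatment tumor sat — modelled
as a four-part composition: viable tumor, necrosis, inflammatory stroma and
fibrotic stroma, summing to 100%. Two classification rules act on it.

**Response grading** depends only on residual viable tumor $v$:

| grade | definition | group |
|-------|------------|-------|
| cPR | $v = 0$ | good |
| mPR | $0 < v \le 10$ | good |
| pPR | $10 < v \le 50$ | good |
| nPR | $v > 50$ | poor |

Interval boundaries are closed above and compared with exact arithmetic:
inputs are rater-estimated percentages, so an epsilon would only blur the
rater's intent at exactly 10 or 50.

**Stromal typing** acts on the three non-viable components. A component
dominates when it exceeds *both* others by strictly more than 10 percentage
points (giving the inflammatory, fibrotic or necrotic type); when all three
pairwise differences are at most 10 the bed is intermediate. Two design
questions were genuinely open here:

- *Strictness at exactly 10.* We read "exceeds by 10%" as strictly greater
  than 10 points, so the dominance rule and the intermediate rule (≤ 10)
  partition cleanly at the boundary. The margin is a parameter
  (`margin = 10`) for anyone who prefers the other convention.
- *Coverage gap.* Compositions such as 45/36/19 satisfy neither rule: no
  component leads by more than 10, yet the extremes differ by more than 10.
  Since no single component dominates, these fall back to intermediate, and
  the `"fallback"` attribute flags them for audit.
- *Basis of comparison.* Typing is performed on the three non-viable
  components renormalized to 100, making it invariant to the viable
  fraction (a bed that is 70% viable can still be inflammatory-typed by its
  remaining stroma). Raw-percentage comparison is available via
  `renormalize = FALSE`. A bed that is 100% viable has no stroma to type and
  returns `NA`.

**Slide handling.** Every slide on which the tumor bed is recognizable
contributes one composition; the specimen value is the component-wise mean,
renormalized. Reporting uses the conventional grid — 5% increments for
components of 10% or more, single-digit integers below 10% — and
`round_composition_to_increments()` restores an exact 100% total by a
largest-remainder repair: the component whose rounding moved it furthest in
the needed direction is stepped by its own increment, ties broken in the
fixed order viable, necrosis, inflammatory, fibrotic. Single-digit
components are repaired first (1-point steps, kept within [0, 10]) because
only they can carry a non-multiple-of-5 residue; 5-point steps then close
the remaining gap. The output always sums to exactly 100.

## Biomarker scores

The **tumor-infiltrating lymphocyte volume** combines stromal abundance with
stromal infiltration:

$$\mathrm{TILV} = \text{stroma in tumor}\,(\%) \times \text{stromal TILs}\,(\%)
\in [0, 10000].$$

A tumor that is 30% stroma with 80% infiltrated stroma scores 2400; 50%
stroma at 5% infiltration scores 250. Stromal TILs are additionally graded
low (≤ 5%), intermediate ((5, 50]) or high (> 50%). For non-integer
estimates we place the low/intermediate boundary at 5 (i.e. (5, 50]), the
continuous reading of the "6–50%" convention for integer scores.

IHC densities are the mean of three high-power-field (HPF) counts divided by
the HPF area. The field area is a microscope property the source tables do
not state; the default 0.2376 mm² is a common 40× field and is exposed as a
parameter — absolute densities are only comparable across studies at a known
area, while the CD4/CD8 and CD8/FOXP3 ratios cancel it entirely. Ratio
cutoffs 2.17 and 5.24 and the TILV cutoff 75 ship as cohort-derived
defaults; all are recomputable from data with `youden_cutoff()`, which
maximizes sensitivity + specificity over observed values (high = predicts
good response; ties break toward the smallest cutoff; the high/low
convention on the cutoff itself is "high strictly above").

PD-L1 follows the standard scoring criteria: CPS = 100 × (positive tumor +
positive immune cells)/viable tumor cells capped at 100, TPS for tumor cells
only, IPS (also written ICS) over total immune cells; each positive at ≥ 1.
Zero denominators yield missing scores, never zero.

## Radiological response

The three-category scheme used alongside the grading collapses RECIST v1.1:
CR for complete resolution, PR for a strictly-greater-than-30% decrease in
the longest diameter, SD for everything else, *including* increases (the
source scheme has no progressive-disease category; `strict = TRUE` restores
one at > 20% growth). A reduction of exactly 30% is SD. "Pathological
reduction", paired with the radiological reduction in correlation analyses,
is not given a formula in the source; the default is $100 - v$, with a
biopsy-delta alternative (pre-treatment tumor content minus residual
viable).

## The statistics battery

Contingency tests follow the usual selection rule — Fisher's exact test when
any expected count is below 5 (2×2 only), Pearson chi-square otherwise.
The chi-square is computed **without** continuity correction: the published
association p-values for this grading system (lymph-node metastasis
p = 0.005, vascular invasion p = 0.017) are reproduced only without the
Yates correction (with it, the lymph-node table gives ≈ 0.010). The
correction remains available as a flag. Fisher's two-sided p-value sums all
hypergeometric probabilities not exceeding the observed table's (relative
tie tolerance 1e-7), with degenerate margins returning p = 1.

Logistic and Cox models report exponentiated coefficients with Wald 95%
intervals, matching the `OR (CI)` reporting style of clinical tables.
Multivariate models admit covariates that are univariately significant at
p < 0.05 by default (the exact published covariate sets live in
supplementary material we do not reproduce; the rule and an explicit
`include =` list are both exposed). Cox ties use the Efron approximation.
Stromal type enters Cox as a single ordinal term (inflammatory = 0,
intermediate = 1, fibrotic = 2, necrotic = 3): the published tables report
*one* hazard ratio for the four-level factor, which implies per-step coding;
per-level dummy coding is available by passing the factor itself. OS is time
to death from any cause and DFS time to recurrence or death, in months,
censored at last follow-up (the source does not define them; these are the
standard definitions).

## The synthetic cohort generator

No patient-level data are deposited, so `generate_cohort()` stands in for
the cohort wherever the pipeline needs realistic input. Its defaults *are*
the published study conditions:

- response mixture 27/49/58/51 over 185 (the published running-text count
  for pPR is internally inconsistent with the table totals; 58 is the count
  implied by good = 134 with cPR 27 and mPR 49);
- stromal-type mixture 53/59/5/67 — these sum to 184, a discrepancy the
  source leaves unresolved; we normalize over 184;
- TILV link: P(TILV > 75 | good) = 114/134 and P(TILV > 75 | poor) = 36/51,
  whose cross-product odds ratio is exactly the published multivariate
  OR 2.375. The generator parameterizes this as the poor-group prevalence
  plus the odds ratio on the logit scale, so `tilv_or` is directly the
  estimand that logistic recovery targets;
- immune densities Poisson around the published group means (e.g. CD8
  450.3 vs 356.7 cells/mm²) at the configured HPF area; PD-L1 positive-cell
  totals Poisson with rate matched to the published CPS positivity per
  group;
- survival: exponential baseline (the simplest proportional-hazards-
  consistent choice) with per-step hazard ratios 3.749 (OS) and 4.719
  (DFS). Baselines of 0.0015 and 0.0025 events/month give multi-year
  survival for inflammatory-type patients and poor outcomes for the
  necrotic type, in line with the published curves. DFS is generated as
  min(recurrence, death) with the recurrence hazard set to the DFS-OS
  hazard difference, so `dfs_time <= os_time` holds exactly *and* DFS
  remains exactly exponential with the configured per-step ratio;
- censoring: independent exponential, with the rate calibrated numerically
  so the expected OS censored fraction over the realized hazards equals the
  target (default 30%);
- radiology: `post = pre × (1 − 0.85 × pathological reduction/100)` plus
  4 mm Gaussian noise, yielding a positive pathological–radiological rank
  correlation (the sign, not the published magnitude, is the design
  target).

Internal consistency is enforced by *re-deriving* every label from the
generated slides: per-slide compositions are Dirichlet noise around the
patient-level composition, the recorded composition is the slide average,
and the grade, group and stromal type that drive the marker and survival
links are the realized classifications. Slide noise can move a patient
across a grading boundary — as inter-slide variation does in practice — so
realized category frequencies carry slightly more than multinomial
variation, but every link (odds ratio, hazard ratios) holds exactly for the
labels the pipeline will actually see.

What the generator does **not** emulate: correlations among
clinicopathological covariates beyond their per-group prevalences, joint
marker correlations (CD8 and FOXP3 are drawn independently), inter-rater
disagreement, or non-proportional hazards. Passing tests therefore
demonstrate that the estimators recover the structure they assume — not that
real cohorts satisfy those assumptions.

## Numerical choices and degenerate inputs

- Compositions must be nonnegative with a positive total; all-zero beds are
  rejected ("empty tumor bed"). Normalization rescales exactly to 100.
- Ratio markers: x/0 reports `Inf` (a real excess against an absent
  denominator population), 0/0 is missing.
- `youden_cutoff` requires both classes; `spearman_correlation` returns a
  missing coefficient for constant vectors; `kruskal_wallis` defines H = 0,
  p = 1 when all observations are identical (the tie-corrected statistic is
  0/0 there).
- Separation in logistic models and monotone likelihood in Cox models are
  detected (glm's fitted-probability warning, |coef| > 15) and flagged, not
  silently reported.
- All randomness flows through a single seed recorded in the cohort's
  provenance attribute; identical config + seed reproduce cohorts
  byte-identically.

## Problem sizes used in the test suite

Property suites use 10,000 random compositions for typing totality, 200
random small datasets for the Youden oracle, full enumeration of all 2×2
tables with n ≤ 40 for the Fisher oracle, and 50 synthetic cohorts of
n = 2000 for odds-ratio/hazard-ratio recovery (median within 10% of the
generating values). Coverage checks use 100 simulations of n = 400 (wider
Wald intervals at small n are a known feature, not a defect of the check).

## Known limitations

- The grading inputs are pathologist-estimated percentages; no image
  analysis or inter-rater reconciliation is modelled.
- The published cohort's fitted multivariate CIs, Table-2 density means and
  the pathological–radiological correlation magnitude (R = 0.355) require
  the undeposited patient-level data; they are covered indirectly by the
  parameter-recovery suites on synthetic cohorts.
- The multivariate covariate entry rule (univariate p < 0.05) is a
  documented convention, not a claim about the exact published model.
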