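---
title: "Deriving a cumulative risk-factor decision tool for postpartum running-related pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a cumulative risk-factor decision tool for postpartum running-related pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postrun)
```

## The problem and the model

About one in three women running after childbirth reports running-related
pain. With cross-sectional survey data — demographics, postpartum factors
(delivery type, incontinence, fatigue, depression, sleep), and running
history — a screening question is: which factors are associated with pain,
and how does risk compound when several are present at once?

`postrun` implements the classic clinical-prediction-rule derivation for
this setting. The statistical model at its core is ordinary logistic
regression of the binary outcome (current pain with running) on binary
risk indicators; the clinical deliverable is deliberately simpler than the
regression: an **unweighted count** of K final risk factors, evaluated at
every threshold "k or more of K" for sensitivity, specificity, likelihood
ratios, and Bayes post-test probabilities. Counting rules discard the
coefficient weights on purpose — they are what a clinician can apply at
the bedside, and the accuracy table makes the cost of that simplification
visible.

The derivation order is: descriptive comparisons → Little's MCAR test →
pooled regression imputation → ROC dichotomization → one representative
per latent construct → bivariate screen (retain at p < 0.15) →
Phi/Cramér's V collinearity filter (|r| < 0.6 admits) → backward
elimination (LR removal test, p ≥ 0.10 removes) → rule table.
`derive_cdt()` runs the chain on one dataset and returns a classed model
object; `run_pipeline()` additionally writes every artifact as plain
CSV/JSON.

## The synthetic cohort generator

No individual-level survey data ship with the package. Instead
`default_cohort_spec()` defines a data-generating model with the published
cohort's structure, and `generate_cohort()` draws from it:

* **Marginals.** Every covariate is drawn from the published descriptive
  table: binary items by their sample proportions (e.g. any incontinence
  42.8%, previous running injury 54.3%), categorical items by their level
  frequencies (delivery 68.2/24.5/7.3% vaginal/cesarean/other), and
  continuous items from truncated normals with the published mean (SD) —
  sleep 6.67 (1.17) h on (0.5, 14), PAFS 10.54 (8.07) on 0–30 (integer),
  EPDS 6.70 (4.84) on 0–30 (integer). The reported scales give only means
  and SDs, so truncated normals are the minimal assumption; PAFS is
  truncated to 0–30 (the instrument's range is not stated with the
  summary table; the bound is configurable).
* **Coding rule.** Respondents reporting no fatigue are coded PAFS = 0,
  as in the survey itself. The published PAFS mean is the overall mean
  including those zeros; we apply the marginal to the fatigued subgroup,
  which leaves the overall mean slightly below 10.54 (~9.7). No test
  depends on the PAFS mean.
* **Outcome.** Pain is Bernoulli(logit⁻¹(β₀ + Σ βⱼIⱼ)) where the Iⱼ are
  the six final-model indicators and the βⱼ the published adjusted odds
  ratios (novice 3.51, PAFS ≥ 19 2.48, previous injury 1.95, vaginal
  delivery 1.63, incontinence 1.93, sleep ≤ 6.84 h 1.89; where the
  abstract and the model table disagree on a second decimal the model
  table is used). `calibrate_intercept()` solves
  E[logit⁻¹(β₀ + Σ βⱼIⱼ)] = 0.327 by root-finding over a Monte-Carlo
  covariate sample (default 50 000), so simulated prevalence matches the
  32.7% of the analysed sample.
* **Independence.** Covariates are drawn independently — consistent with
  the published finding that no pairwise association approached the 0.6
  collinearity bound. An optional Gaussian copula induces correlation
  between named covariates for collinearity tests.
* **Missingness.** The default deletes 0.10% of data cells completely at
  random, confined to ≈1.1% of rows (the published footprint: 12 cells in
  6 of 538 cases), never touching the outcome. `mar`/`mnar` modes delete
  the target column deterministically in rows with the shortest observed
  sleep (MAR) or with the highest values of the column itself (MNAR);
  these exist to study the MCAR test's power, and are flagged in the
  returned metadata.

What the generator does **not** emulate: recruitment and self-selection,
correlation among risk factors (beyond the optional copula), measurement
error in self-report scales, and any effect of the unlisted covariates.
Passing tests therefore demonstrate that the pipeline recovers the model
it assumes — they cannot validate the rule on real postpartum runners.

## Parameter defaults and the reasoning behind them

| parameter | default | why |
|---|---|---|
| retention α (screen) | 0.15 | deliberately permissive bivariate gate, standard in CPR derivation |
| collinearity cutoff | 0.6 | published inclusion rule on Phi / Cramér's V |
| removal α (elimination) | 0.10 | the customary backward-elimination POUT; the source does not state one |
| imputations pooled | 5 | published count of regression-imputation draws |
| pre-test probability | sample prevalence | 32.7% in the replication setting; overridable per report |
| calibration sample | 50 000 | makes intercept Monte-Carlo error negligible (< 0.002 on prevalence) |
| rule-in policy | smallest k with LR+ ≥ 3 and CI ratio ≤ 10 | LR+ ≥ 3 is the conventional "moderate" rule-in bound; the CI-width guard reproduces the preference for a threshold whose interval is usable, not just whose point estimate is large |

## Interpretive decisions where the source was ambiguous

* **"Midpoint of the ROC-generated discrimination threshold"** is read as
  the midpoint between the two consecutive observed values straddling the
  optimal ROC operating point. This is the only reading that yields the
  published half-integer thresholds (EPDS 12.5, first run 24.5 weeks,
  mileage 15.25 miles), and it guarantees an estimated threshold never
  equals an observed value. The optimality criterion is not named in the
  source; Youden's J is the default (`criterion = "closest01"` is the
  alternative), and ties break toward the cut nearest the median of the
  outcome-positive values.
* **PAFS ≥ 19 vs > 19** and **sleep 6.83 vs 6.84 h**: the printed tables
  disagree across locations. The screening table's ≥ 19 and ≤ 6.83 are
  shipped as the replication defaults; the generator's sleep effect uses
  6.84 as printed with the final model. For integer PAFS scores ≥ 19 and
  > 18.5 are the same rule.
* **"Pooled the results of five iterations"** could mean Rubin's rules on
  five analyses or one pooled dataset. Since every downstream analysis is
  stated to run "on the pooled imputed dataset", the package averages the
  five predictive draws into a single dataset (majority vote with a
  seeded tie-break for binary/categorical cells). Imputation is a single
  pass in increasing-missingness order using only completely observed
  covariates — regression imputation, not chained equations.
* **Backward "conditional" elimination**: the conditional variant
  approximates the likelihood-ratio test only to avoid refitting; refits
  are cheap here, so the exact LR removal test is used. Final-model
  significance is judged by Wald 95% CIs excluding 1.0, as stated.
* **Collinearity drops**: the source never had to drop a variable, so no
  rule is stated; flagged pairs drop the member with the larger bivariate
  p. Dummies of the same categorical variable (delivery, runner type) are
  structurally negatively associated and exempt; if every level of a
  group survives screening, the weakest becomes the reference level so
  the design stays full rank.
* **Proportion CIs** are Wilson score intervals. The published
  sensitivity/specificity intervals match no standard method we could
  identify (e.g. "5.0 (3.70, 5.40)"); the discrepancy is documented
  rather than imitated. Likelihood-ratio CIs use the standard log method.
* **Zero cells**: a rule level with no false positives keeps its infinite
  point LR+; only the CI is computed on the Haldane–Anscombe (+0.5)
  corrected table, reproducing the published "infinite estimate, finite
  lower bound" shape. Bivariate odds ratios apply +0.5 to all cells when
  any cell is zero, flagged in the result.
* **Negative post-test column**: the published values reproduce exactly
  when Bayes updating is applied to the LR− values at their printed
  two-decimal precision; the unrounded column is self-consistent with the
  unrounded LR−. The test suite pins both facts.

## Numerical choices

* Logistic fits use iteratively reweighted least squares (relative
  log-likelihood tolerance 1e-12, 25 iterations). Quasi-complete
  separation is detected from the fitted-probability diagnostic or from
  divergent coefficients without convergence, and flagged rather than
  silently reported; rank-deficient designs are an error naming the
  aliased columns.
* Nagelkerke R² = [1 − e^{2(LL₀−LL₁)/n}] / [1 − e^{2LL₀/n}], clamped to
  [0, 1] against floating-point underrun.
* Little's test uses EM estimates of the mean and covariance (ML, divisor
  n; convergence 1e-8), with rows grouped by missingness pattern and
  df = Σⱼ pⱼ − p. Binary items enter as 0/1 numerics and categorical items
  as treatment dummies — a documented approximation. Because a handful of
  incomplete rows cannot carry the normal approximation for a nearly
  constant indicator, 0/1 columns with minority share below 10% are
  excluded by default (`min_minority_share`); with the guard the test
  holds its nominal size on simulated cohorts, without it the size
  roughly triples. A singular pattern covariance falls back to a
  pseudo-inverse with a warning.
* Truncated-normal draws use the inverse-CDF transform (exact, no
  rejection loop). All generator stages derive their RNG seeds from the
  master seed through a multiplicative hash, so consecutive master seeds
  give unrelated streams and a fixed seed gives byte-identical report
  bundles (the JSON-lines run log, which records wall-clock durations, is
  the one file outside the checksum manifest).

## Monte-Carlo design of the verification suite

Simulation sizes in the test suite are chosen as the smallest that make
the checked property sharp: type-I error of the MCAR test over 500
cohorts of n = 538; null calibration of backward elimination (six
independent null predictors, 500 reps — mean final model size ≈ 6 × 0.10);
parameter recovery as the mean fitted OR over 8 cohorts of n = 50 000,
asserted within 5% of each generating OR (averaging replicates keeps the
Monte-Carlo error of the smallest effects well inside the band);
rule-table monotonicity of sensitivity/specificity in k over 1 000
simulated cohorts. Power studies for the MAR/MNAR modes run at a 0.5%
cell rate: at the replication footprint of ~11 cells Little's test is
nearly blind to self-censoring deletion — a structural property of the
test, which only sees observed-variable shifts — and the elevated rate is
what makes the power contrast informative.

## Known limitations

* The pipeline reproduces a cross-sectional, correlational derivation;
  nothing here estimates predictive performance on future pain-free
  runners. Selection stability at n = 538 is modest by construction — at
  that sample size the factor set genuinely varies run to run.
* The bivariate screen applies no multiplicity adjustment, matching the
  source procedure; this is documented, not "fixed".
* Little's test on coded binaries is an approximation even with the skew
  guard, and the test has essentially no power against purely
  self-censoring missingness at realistic missingness levels.
* The unweighted count treats a 3.5-fold and a 1.6-fold factor alike;
  the per-threshold logistic ORs in the rule table quantify what the
  simplification costs.
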