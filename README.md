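# postrun

Derivation pipeline for a **clinical decision tool for running-related pain
in postpartum runners**, written for biostatisticians and clinician
researchers who want the whole chain — from raw survey records to a
bedside "count the risk factors" rule — as tested, reproducible code.

Running-related pain affects roughly a third of women returning to running
after childbirth. From a cross-sectional survey of 538 postpartum runners
(32.7% reporting current pain with running), a six-factor rule was derived:
novice runner, Postpartum Accumulated Fatigue Scale (PAFS) score ≥ 19,
previous running-related injury, vaginal delivery, any incontinence, and
average sleep ≤ 6.8 h/night. `postrun` implements that derivation end to
end and ships a synthetic-cohort generator with the same statistical
structure, so every stage is exercised without the original data.

## The method

Given survey records with a binary outcome *y* (pain with running) the
pipeline runs, in order:

1. **Descriptives** — pooled-variance t-tests / Pearson chi-square by group.
2. **Missing data** — Little's MCAR chi-square
   *d²* = Σⱼ mⱼ (x̄ⱼ − μ̂ⱼ)ᵀ Σ̂ⱼ⁻¹ (x̄ⱼ − μ̂ⱼ) on EM estimates, then
   regression-based multiple imputation pooled across five draws into one
   analysis dataset.
3. **Dichotomization** — each continuous predictor is cut at the midpoint
   of the two observed values straddling the Youden-optimal ROC operating
   point (max sens + spec − 1).
4. **Bivariate screen** — 19 single-predictor logistic fits; OR with Wald
   95% CI, Nagelkerke R², retention at *p* < 0.15.
5. **Collinearity** — pairwise Phi / Cramér's V; pairs with |r| ≥ 0.6
   drop their weaker member (none, under independent marginals).
6. **Multivariable model** — backward elimination by exact 1-df
   likelihood-ratio removal tests (removal at *p* ≥ 0.10).
7. **Decision tool** — respondents scored by their count of the K final
   risk factors; for every threshold "k or more of K" a 2×2 table yields
   sensitivity/specificity (Wilson CIs), LR± (log-method CIs), and Bayes
   post-test probabilities
   *post = (pre/(1−pre))·LR / (1 + (pre/(1−pre))·LR)*.

## Worked example

```r
library(postrun)
spec   <- default_cohort_spec(seed = 7)          # 538 respondents, 32.7% prevalence
cohort <- inject_missingness(generate_cohort(spec), spec)
tool   <- derive_cdt(cohort, cutpoints = "replication", seed = 7)
print(tool)
#> Clinical decision tool for postpartum running-related pain
#>   n = 538 respondents, outcome prevalence 33.1%
#>   screened 19 candidates; 9 retained (p < 0.15); 8 in final model
#>   final risk factors (OR):
#>     race_caucasian             0.35
#>     incontinence_any           2.77
#>     pafs_score_bin             2.09
#>     epds_score_bin             1.67
#>     sleep_hours_avg_bin        1.59
#>     weekly_mileage_bin         1.40
#>     runner_novice              2.65
#>     previous_rri               2.09
#>   rule-in threshold: >= 6 of 8 factors (LR+ 4.45, post-test 68.8%)
```

At n = 538 the selected factor set varies around the six generating
factors run to run — exactly the selection noise the original sample size
implies; at larger n the derivation recovers the generating set (see the
test suite). Each printed OR is the factor's adjusted odds ratio in the
final logistic model; the rule-in line gives the smallest factor count
whose positive likelihood ratio is ≥ 3 with a usably narrow CI, and the
post-test probability of pain for a respondent at or above it.

The published arithmetic itself is exact and deterministic:

```r
odds_ratio_2x2(two_by_two(95, 135, 81, 227))$odds_ratio   # 1.97 (incontinence)
lr4 <- diagnostic_accuracy(two_by_two(41, 26, 135, 336))$lr_pos$estimate  # 3.24
100 * post_test_probability(0.327, lr4)                   # 61.2%
```

`run_pipeline(pipeline_config(...))` writes the full report bundle
(descriptives, missingness report, cutpoints, screening table,
collinearity matrix, elimination trace, final model, rule table, rule
descriptor, checksums) as plain CSV/JSON — byte-identical for identical
config and seed.

## Package layout

- `R/` — cohort simulation, survey I/O and eligibility, missingness,
  thresholding, bivariate screen, collinearity, multivariable model,
  decision rule, `derive_cdt()` and `run_pipeline()`.
- `inst/extdata/` — data dictionary, replication cutpoints, default
  cohort spec (all plain text).
- `vignettes/decision-tool-derivation.Rmd` — the methods vignette: model,
  assumptions, tunables, numerical choices, limitations.
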