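# Replication cohort specification: marginals of the published survey of
# 538 postpartum runners, the six final-model odds ratios on the outcome,
# 32.7% target prevalence, and 0.10%-of-cells missingness in ~1.1% of rows.
n_respondents: 538
target_prevalence: 0.327
missing_value_rate: 0.001
missing_case_rate: 0.0111
seed: 1
covariate_marginals:
  age: {type: continuous, mean: 33.62, sd: 4.04, lower: 18, upper: 55}
  parity_primiparous: {type: binary, p: 0.441}
  race_caucasian: {type: binary, p: 0.935}
  education_hs_or_more: {type: binary, p: 0.935}
  married: {type: binary, p: 0.977}
  diastasis_recti: {type: binary, p: 0.214}
  breastfeeding: {type: binary, p: 0.468}
  incontinence_any: {type: binary, p: 0.428}
  delivery:
    type: categorical
    levels: [vaginal, cesarean, other]
    probs: [0.682, 0.245, 0.073]
  fatigue_present: {type: binary, p: 0.857}
  pafs_score: {type: continuous, mean: 10.54, sd: 8.07, lower: 0, upper: 30, integer: yes}
  epds_score: {type: continuous, mean: 6.70, sd: 4.84, lower: 0, upper: 30, integer: yes}
  sleep_hours_avg: {type: continuous, mean: 6.67, sd: 1.17, lower: 0.5, upper: 14}
  sleep_interruptions:
    type: categorical
    levels: ["0", "1", "2", "3", "4", "5", ">5"]
    probs: [0.08550186, 0.28996283, 0.31226766, 0.17472119, 0.06877323, 0.02788104, 0.04089219]
  weekly_mileage: {type: continuous, mean: 13.07, sd: 12.37, lower: 0, upper: 120}
  weeks_to_first_run: {type: continuous, mean: 12.72, sd: 14.31, lower: 0, upper: 156}
  runner_type:
    type: categorical
    levels: [novice, recreational, elite]
    probs: [0.06691450, 0.74535316, 0.18773234]
  stroller_running: {type: binary, p: 0.542}
  previous_rri: {type: binary, p: 0.543}
  covid_mileage_change:
    type: categorical
    levels: [increased, decreased, no_change, not_asked]
    probs: [0.11895911, 0.05762082, 0.12825279, 0.69516728]
log_odds_effects:
  runner_novice: {variable: runner_type, level: novice, log_or: 1.25561603747777}
  pafs_high: {variable: pafs_score, threshold: 19, direction: ge, log_or: 0.908258560176891}
  previous_rri: {variable: previous_rri, log_or: 0.667829372575655}
  delivery_vaginal: {variable: delivery, level: vaginal, log_or: 0.488580014818671}
  incontinence_any: {variable: incontinence_any, log_or: 0.657520002916794}
  sleep_low: {variable: sleep_hours_avg, threshold: 6.84, direction: le, log_or: 0.636576829071551}
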