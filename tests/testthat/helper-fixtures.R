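# Fixtures built in code: published 2x2 counts and the score distribution
# implied by the printed rule table.

# Expand a 2x2 count table (a = exposed/outcome+, b = exposed/outcome-,
# c = unexposed/outcome+, d = unexposed/outcome-) to respondent vectors.
expand_2x2 <- function(a, b, c, d) {
  list(exposure = rep(c(1, 1, 0, 0), c(a, b, c, d)),
       outcome = rep(c(1, 0, 1, 0), c(a, b, c, d)))
}

# Published descriptive counts (pain n = 176, no pain n = 362) for the
# binary predictors whose screening rows reproduce exactly, with the
# printed odds ratios.
published_2x2 <- list(
  incontinence  = list(counts = c(95, 135, 81, 227), or = 1.97),
  previous_rri  = list(counts = c(108, 184, 68, 178), or = 1.54),
  breastfeeding = list(counts = c(85, 167, 91, 195), or = 1.09),
  education     = list(counts = c(158, 345, 18, 17), or = 0.43),
  vaginal       = list(counts = c(130, 237, 46, 125), or = 1.49),
  cesarean      = list(counts = c(37, 95, 139, 267), or = 0.75),
  diastasis     = list(counts = c(46, 69, 130, 293), or = 1.50),
  race          = list(counts = c(163, 340, 13, 22), or = 0.81),
  married       = list(counts = c(170, 356, 6, 6), or = 0.48)
)

# Rule-table 2x2 tables reconstructed from the printed sensitivity and
# specificity at group sizes 176 / 362.
published_rule_tables <- function() {
  sens <- c(98.9, 87.5, 63.60, 23.30, 5.10, 0.60)
  spec <- c(5.0, 30.10, 67.4, 92.80, 99.7, 100.0)
  lapply(1:6, function(k) {
    tp <- round(sens[k] * 176 / 100)
    tn <- round(spec[k] * 362 / 100)
    two_by_two(tp, 362 - tn, 176 - tp, tn)
  })
}

# Score / outcome vectors whose nested ">= k" tables equal the
# reconstructed rule tables above.
published_rule_scores <- function() {
  tabs <- published_rule_tables()
  tp <- vapply(tabs, function(t) t$a, numeric(1))
  fp <- vapply(tabs, function(t) t$b, numeric(1))
  case_counts <- c(176 - tp[1], -diff(tp), tp[6])
  ctrl_counts <- c(362 - fp[1], -diff(fp), fp[6])
  list(
    score = c(rep(0:6, case_counts), rep(0:6, ctrl_counts)),
    outcome = rep(c(1L, 0L), c(176L, 362L))
  )
}

# Small complete synthetic cohort for quick tests.
quick_cohort <- function(n = 200, seed = 1) {
  spec <- default_cohort_spec(n_respondents = n, seed = seed,
                              missing_value_rate = 0)
  generate_cohort(spec)
}
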