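test_that("intercept calibration solves the closed form with no effects", {
  null_spec <- function(prev) {
    cohort_spec(100, list(x = list(type = "binary", p = 0.5)),
                list(), target_prevalence = prev)
  }
  expect_equal(calibrate_intercept(null_spec(0.5)), 0, tolerance = 1e-10)
  expect_equal(calibrate_intercept(null_spec(0.327)), log(0.327 / 0.673),
               tolerance = 1e-10)
})

test_that("calibrated intercept is strictly increasing in target prevalence", {
  b0 <- vapply(c(0.1, 0.2, 0.327, 0.5, 0.7), function(prev) {
    spec <- default_cohort_spec(seed = 5, missing_value_rate = 0)
    spec$target_prevalence <- prev
    calibrate_intercept(spec, 5000)
  }, numeric(1))
  expect_true(all(diff(b0) > 0))
})

test_that("degenerate effect specifications are rejected at validation", {
  expect_error(
    cohort_spec(100, list(x = list(type = "binary", p = 1)),
                list(e = list(variable = "x", log_or = Inf)),
                target_prevalence = 0.3),
    "finite log_or"
  )
})

test_that("simulated prevalence matches the calibration target at large n", {
  spec <- default_cohort_spec(n_respondents = 50000, seed = 11,
                              missing_value_rate = 0)
  cohort <- generate_cohort(spec)
  expect_lt(abs(mean(cohort$pain_with_running) - 0.327), 0.01)
})

test_that("cohort generation is deterministic and matches its marginals", {
  spec <- default_cohort_spec(seed = 3, missing_value_rate = 0)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  attr(a, "spec") <- attr(b, "spec") <- NULL
  expect_identical(a, b)

  expect_equal(nrow(a), 538L)
  # sample incontinence proportion within 3 SE of the 42.8% marginal
  se <- sqrt(0.428 * 0.572 / 538)
  expect_lt(abs(mean(a$incontinence_any) - 0.428), 3 * se)
  # delivery type takes exactly one level per respondent
  dummies <- postrun:::add_indicator_columns(a)
  expect_true(all(dummies$delivery_vaginal + dummies$delivery_cesarean +
                    dummies$delivery_other == 1L))
  # no-fatigue respondents carry PAFS 0, EPDS within instrument range
  expect_true(all(a$pafs_score[a$fatigue_present == 0] == 0))
  expect_true(all(a$epds_score >= 0 & a$epds_score <= 30))
  expect_true(all(a$sleep_hours_avg > 0))
})

test_that("with all effects zero the outcome is uncorrelated with covariates", {
  spec <- default_cohort_spec(n_respondents = 5000, seed = 21,
                              missing_value_rate = 0)
  spec$log_odds_effects <- list()
  cohort <- generate_cohort(spec)
  for (v in c("incontinence_any", "previous_rri", "sleep_hours_avg")) {
    r <- cor(cohort$pain_with_running, as.numeric(cohort[[v]]))
    expect_lt(abs(r), 3 / sqrt(5000))
  }
})

test_that("invalid specs are rejected with the offending fields named", {
  expect_error(
    cohort_spec(10, list(d = list(type = "categorical",
                                  levels = c("a", "b"), probs = c(0.6, 0.5))),
                list(), 0.3),
    "sum to 1"
  )
  expect_error(
    cohort_spec(10, list(x = list(type = "binary", p = 0.5)), list(), 1.2),
    "target_prevalence"
  )
  expect_error(
    cohort_spec(10, list(x = list(type = "binary", p = 0.5)),
                list(e = list(variable = "zz", log_or = 0.1)), 0.3),
    "unknown variable"
  )
})

test_that("the packaged YAML spec equals the in-code default", {
  disk <- read_cohort_spec(
    system.file("extdata", "default_cohort_spec.yaml", package = "postrun")
  )
  code <- default_cohort_spec()
  expect_equal(disk$target_prevalence, code$target_prevalence)
  expect_equal(names(disk$covariate_marginals), names(code$covariate_marginals))
  for (v in names(code$covariate_marginals)) {
    dm <- disk$covariate_marginals[[v]]
    cm <- code$covariate_marginals[[v]]
    expect_equal(dm[order(names(dm))], cm[order(names(cm))], tolerance = 1e-6)
  }
  for (e in names(code$log_odds_effects)) {
    expect_equal(disk$log_odds_effects[[e]]$log_or,
                 code$log_odds_effects[[e]]$log_or, tolerance = 1e-10)
  }
})

test_that("missingness injection honours rates and never touches the outcome", {
  spec <- default_cohort_spec(seed = 13)
  cohort <- generate_cohort(spec)

  none <- inject_missingness(cohort, default_cohort_spec(seed = 13, missing_value_rate = 0))
  expect_identical(as.list(none)[names(cohort)], as.list(cohort)[names(cohort)])
  expect_false(anyNA(none))

  holed <- inject_missingness(cohort, spec)
  cells <- attr(holed, "missing_cells")
  expect_true(nrow(cells) >= 10 && nrow(cells) <= 12)
  expect_equal(sum(is.na(holed)), nrow(cells))
  expect_lte(length(unique(cells$row)), max(1, round(538 * spec$missing_case_rate)))
  expect_false(anyNA(holed$pain_with_running))
  # deterministic for a fixed seed
  again <- inject_missingness(cohort, spec)
  expect_identical(as.list(holed), as.list(again))

  tight <- default_cohort_spec(seed = 13, missing_value_rate = 0.2,
                               missing_case_rate = 0.001)
  expect_error(inject_missingness(cohort, tight), "cannot place")
})
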