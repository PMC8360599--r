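test_that("eligibility screening applies all four inclusion criteria", {
  expect_true(screen_eligibility(30, 12, 3, FALSE)$eligible)
  # not running weekly but limited by pain is included
  expect_true(screen_eligibility(30, 12, 0, FALSE, "pain")$eligible)
  r <- screen_eligibility(30, 12, 0, FALSE, "time")
  expect_false(r$eligible)
  expect_equal(r$reasons, "running_frequency")
  r <- screen_eligibility(17, 12, 3, FALSE)
  expect_false(r$eligible)
  expect_equal(r$reasons, "age")
  r <- screen_eligibility(17, 40, 0, TRUE, "other")
  expect_setequal(r$reasons,
                  c("age", "postpartum_window", "pregnant", "running_frequency"))
  expect_error(screen_eligibility(-1, 12, 3, FALSE), "non-negative")
  expect_error(screen_eligibility(30, 12, 0, FALSE), "limitation_reason")
})

test_that("relaxing any single criterion never turns eligible into ineligible", {
  set.seed(4)
  for (i in 1:50) {
    age <- sample(15:45, 1); mo <- sample(0:60, 1)
    runs <- sample(0:5, 1); preg <- sample(c(TRUE, FALSE), 1)
    base <- screen_eligibility(age, mo, runs, preg, "pain")
    relaxed <- list(
      screen_eligibility(age + 5, mo, runs, preg, "pain"),
      screen_eligibility(age, max(0, mo - 10), runs, preg, "pain"),
      screen_eligibility(age, mo, runs + 1, preg, "pain"),
      screen_eligibility(age, mo, runs, FALSE, "pain")
    )
    if (base$eligible) {
      for (r in relaxed) expect_true(r$eligible)
    }
  }
})

test_that("flow accounting reproduces the study flow and conserves respondents", {
  flow <- account_flow(study_flow_fixture())
  expect_equal(flow, list(initiated = 826L, ineligible = 262L,
                          eligible_noncompleters = 26L, analyzed = 538L))

  empty <- account_flow(data.frame(eligible = logical(0), completed = logical(0)))
  expect_true(all(unlist(empty) == 0L))

  set.seed(8)
  for (i in 1:20) {
    el <- sample(c(TRUE, FALSE), 10, replace = TRUE)
    co <- el & sample(c(TRUE, FALSE), 10, replace = TRUE)
    f <- account_flow(data.frame(eligible = el, completed = co))
    expect_equal(f$initiated,
                 f$ineligible + f$eligible_noncompleters + f$analyzed)
  }

  expect_error(
    account_flow(data.frame(eligible = FALSE, completed = TRUE)),
    "inconsistent"
  )
  expect_error(
    account_flow(data.frame(eligible = NA, completed = TRUE)),
    "tags"
  )
})

test_that("cohort CSV round-trip is the identity, including missing cells", {
  spec <- default_cohort_spec(n_respondents = 120, seed = 17,
                              missing_value_rate = 0.005,
                              missing_case_rate = 0.1)
  cohort <- inject_missingness(generate_cohort(spec), spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), nrow(cohort))
  for (v in names(cohort)) {
    expect_equal(as.character(back[[v]]), as.character(cohort[[v]]),
                 info = v)
  }
  # factor columns regain their dictionary levels
  expect_s3_class(back$delivery, "factor")
  expect_equal(levels(back$sleep_interruptions),
               c("0", "1", "2", "3", "4", "5", ">5"))
})

test_that("reader validates ranges, levels, and the PAFS coding rule", {
  co <- quick_cohort(20, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- co; bad$epds_score[3] <- 35
  write_cohort(bad, path)
  expect_error(read_cohort(path), "0-30 instrument range at row 3")

  bad <- co; bad$delivery <- as.character(bad$delivery); bad$delivery[2] <- "home"
  write_cohort(bad, path)
  expect_error(read_cohort(path), "unknown level 'home'")

  bad <- co
  bad$fatigue_present[5] <- 0L; bad$pafs_score[5] <- 7
  write_cohort(bad, path)
  expect_warning(fixed <- read_cohort(path), "coerced to 0")
  expect_equal(fixed$pafs_score[5], 0)

  noout <- co[, setdiff(names(co), "pain_with_running")]
  write_cohort(noout, path)
  expect_error(read_cohort(path), "outcome column")
})
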