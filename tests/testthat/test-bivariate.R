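test_that("cross-product odds ratios reproduce the published screening rows", {
  for (nm in names(published_2x2)) {
    cc <- published_2x2[[nm]]$counts
    o <- odds_ratio_2x2(two_by_two(cc[1], cc[2], cc[3], cc[4]))
    expect_equal(round(o$odds_ratio, 2), published_2x2[[nm]]$or, info = nm)
  }
  inc <- odds_ratio_2x2(two_by_two(95, 135, 81, 227))
  expect_equal(round(inc$ci95, 2), c(1.37, 2.84))
})

test_that("odds ratio symmetry and zero-cell correction behave", {
  o <- odds_ratio_2x2(two_by_two(25, 25, 25, 25))
  expect_equal(o$odds_ratio, 1)
  expect_false(o$corrected)
  z <- odds_ratio_2x2(two_by_two(10, 0, 5, 20))
  expect_true(z$corrected)
  expect_true(is.finite(z$odds_ratio) && all(is.finite(z$ci95)))
  expect_error(two_by_two(-1, 2, 3, 4), "non-negative")
  expect_error(two_by_two(0, 0, 0, 0), "empty")
})

test_that("the logistic OR equals the cross-product OR for binary predictors", {
  set.seed(2)
  for (i in 1:50) {
    cc <- sample(1:60, 4, replace = TRUE)
    d <- expand_2x2(cc[1], cc[2], cc[3], cc[4])
    b <- bivariate_logistic(d$exposure, d$outcome)
    expect_equal(b$odds_ratio, (cc[1] * cc[4]) / (cc[2] * cc[3]),
                 tolerance = 1e-6)
  }
})

test_that("the fitted deviance matches the saturated 2x2 closed form", {
  cell_ll <- function(cc) {
    n1 <- cc[1] + cc[2]; n0 <- cc[3] + cc[4]
    ll <- 0
    if (cc[1] > 0) ll <- ll + cc[1] * log(cc[1] / n1)
    if (cc[2] > 0) ll <- ll + cc[2] * log(cc[2] / n1)
    if (cc[3] > 0) ll <- ll + cc[3] * log(cc[3] / n0)
    if (cc[4] > 0) ll <- ll + cc[4] * log(cc[4] / n0)
    ll
  }
  set.seed(6)
  for (i in 1:20) {
    cc <- sample(5:80, 4, replace = TRUE)
    d <- expand_2x2(cc[1], cc[2], cc[3], cc[4])
    f <- fit_logistic(data.frame(x = d$exposure), d$outcome)
    expect_equal(f$log_likelihood, cell_ll(cc), tolerance = 1e-8)
  }
})

test_that("Nagelkerke R2 reproduces the published incontinence value", {
  d <- expand_2x2(95, 135, 81, 227)
  b <- bivariate_logistic(d$exposure, d$outcome, variable = "incontinence_any")
  expect_equal(round(b$nagelkerke_r2, 3), 0.034)
  expect_lt(b$p_value, 0.001)
  expect_true(b$retained)
})

test_that("Nagelkerke R2 is bounded and zero for a null predictor", {
  d <- expand_2x2(50, 100, 50, 100)  # identical outcome rates
  b <- bivariate_logistic(d$exposure, d$outcome)
  expect_equal(b$nagelkerke_r2, 0, tolerance = 1e-10)
  expect_equal(b$odds_ratio, 1, tolerance = 1e-8)
  set.seed(9)
  for (i in 1:20) {
    cc <- sample(1:50, 4, replace = TRUE)
    d <- expand_2x2(cc[1], cc[2], cc[3], cc[4])
    r2 <- bivariate_logistic(d$exposure, d$outcome)$nagelkerke_r2
    expect_true(r2 >= 0 && r2 <= 1)
  }
})

test_that("retention follows the p < 0.15 screening rule", {
  d <- expand_2x2(60, 100, 40, 100)
  b <- bivariate_logistic(d$exposure, d$outcome)
  expect_equal(b$retained, b$p_value < 0.15)
  strict <- bivariate_logistic(d$exposure, d$outcome, retention_alpha = 1e-9)
  expect_false(strict$retained)
})

test_that("perfect separation is flagged with an unbounded interval", {
  x <- rep(c(1, 0), each = 20)
  y <- x
  b <- suppressWarnings(bivariate_logistic(x, y))
  expect_true(b$separated)
  expect_equal(b$ci95, c(0, Inf))
})

test_that("descriptive comparisons pick the right test and summaries", {
  co <- quick_cohort(300, seed = 5)
  tab <- descriptive_compare(co)
  inc <- tab[tab$variable == "incontinence_any", ]
  expect_equal(inc$type, "categorical")
  slp <- tab[tab$variable == "sleep_hours_avg", ]
  expect_equal(slp$type, "continuous")
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))

  # identical group proportions at equal n give chi-square p = 1
  eq <- data.frame(x = rep(c(1, 0), 50),
                   pain_with_running = rep(c(1, 0), each = 50))
  expect_equal(descriptive_compare(eq, "x")$p_value, 1)

  # published incontinence proportions: 95/176 = 54.0%, 135/362 = 37.3%
  d <- expand_2x2(95, 135, 81, 227)
  df <- data.frame(incontinence_any = d$exposure, pain_with_running = d$outcome)
  row <- descriptive_compare(df, "incontinence_any")
  expect_match(row$pain, "95 \\(54.0\\)")
  expect_match(row$no_pain, "135 \\(37.3\\)")

  cz <- data.frame(x = rep(2.5, 40), pain_with_running = rep(c(0, 1), 20))
  expect_error(descriptive_compare(cz, "x"), "zero-variance")
})

test_that("construct selection keeps one representative per construct", {
  out <- select_constructs(c("fatigue_present", "pafs_score", "incontinence_any"))
  expect_setequal(out, c("pafs_score", "incontinence_any"))
  out <- select_constructs(c("sleep_hours_avg", "sleep_interruptions"))
  expect_equal(as.character(out), "sleep_hours_avg")
  plain <- c("incontinence_any", "previous_rri")
  expect_setequal(select_constructs(plain), plain)
  expect_error(
    select_constructs(c("fatigue_present"),
                      list(f = list(members = c("fatigue_present"),
                                    keep = "pafs_score"))),
    "no mapped representative"
  )
})
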