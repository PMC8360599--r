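test_that("risk scores count positive factors and demand complete data", {
  df <- data.frame(a = c(1, 0, 1), b = c(1, 0, 0), c = c(1, 0, 1))
  expect_equal(score_respondents(df, c("a", "b", "c")), c(3L, 0L, 2L))
  df$a[2] <- NA
  expect_error(score_respondents(df, c("a", "b", "c")), "missing")
  df2 <- data.frame(a = c(1, 2, 0))
  expect_error(score_respondents(df2, "a"), "binary")
})

test_that("the score distribution is Poisson-binomial", {
  set.seed(30)
  p <- c(0.07, 0.15, 0.43, 0.54, 0.56, 0.68)
  n <- 10000
  X <- sapply(p, function(pi) rbinom(n, 1, pi))
  score <- score_respondents(as.data.frame(X), colnames(as.data.frame(X)))
  # exact Poisson-binomial pmf by convolution
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  obs <- tabulate(score + 1L, nbins = 7)
  gof <- chisq.test(obs, p = pmf / sum(pmf))
  expect_gt(gof$p.value, 0.001)
})

test_that("diagnostic accuracy reproduces the published likelihood ratios", {
  a4 <- diagnostic_accuracy(two_by_two(41, 26, 135, 336))
  expect_equal(round(a4$lr_pos$estimate, 2), 3.24)
  expect_equal(round(100 * a4$sensitivity$estimate, 1), 23.3)
  expect_equal(round(100 * a4$specificity$estimate, 1), 92.8)
  a5 <- diagnostic_accuracy(two_by_two(9, 1, 167, 361))
  expect_equal(round(a5$lr_pos$estimate, 2), 18.51)
  # uninformative rule: sens = 1 - spec gives LR+ = LR- = 1
  u <- diagnostic_accuracy(two_by_two(30, 30, 70, 70))
  expect_equal(u$lr_pos$estimate, 1)
  expect_equal(u$lr_neg$estimate, 1)
  expect_error(diagnostic_accuracy(two_by_two(0, 5, 0, 5)), "non-empty")
})

test_that("zero false positives give an infinite LR+ with a finite lower bound", {
  acc <- diagnostic_accuracy(two_by_two(1, 0, 175, 362))
  expect_true(is.infinite(acc$lr_pos$estimate))
  expect_true(is.finite(acc$lr_pos$ci95[1]) && acc$lr_pos$ci95[1] > 0)
  expect_true(is.infinite(acc$lr_pos$ci95[2]))
})

test_that("post-test probability follows Bayes' rule on the odds scale", {
  expect_equal(round(100 * post_test_probability(0.327, 3.24), 1), 61.2)
  expect_equal(post_test_probability(0.4, 1), 0.4)
  expect_equal(post_test_probability(0.2, Inf), 1)
  expect_error(post_test_probability(1, 2), "strictly")
  expect_error(post_test_probability(0.3, -1), "non-negative")
  # LR route identical to direct conditioning when pre-test = prevalence
  set.seed(31)
  for (i in 1:25) {
    cc <- sample(5:100, 4, replace = TRUE)
    t <- two_by_two(cc[1], cc[2], cc[3], cc[4])
    acc <- diagnostic_accuracy(t)
    pre <- (t$a + t$c) / sum(cc)
    expect_equal(post_test_probability(pre, acc$lr_pos$estimate),
                 t$a / (t$a + t$b), tolerance = 1e-12)
    expect_equal(post_test_probability(pre, acc$lr_neg$estimate),
                 t$c / (t$c + t$d), tolerance = 1e-12)
  }
})

test_that("the replication rule table reproduces the published columns", {
  fx <- published_rule_scores()
  rt <- postrun:::rule_table_from_scores(fx$score, fx$outcome, pre_test = 0.327, K = 6)
  df <- as.data.frame(rt)
  expect_equal(round(df$post_prob_pos[1:5], 1), c(33.6, 37.8, 48.7, 61.2, 90.0))
  expect_gte(df$post_prob_pos[6], 99.9)
  expect_equal(round(df$lr_pos[1:5], 2), c(1.04, 1.25, 1.95, 3.24, 18.51))
  expect_true(is.infinite(df$lr_pos[6]))
  # the published negative post-test column derives from the LR- values at
  # their printed two-decimal precision
  expect_equal(round(df$lr_neg, 2), c(0.23, 0.42, 0.54, 0.83, 0.95, 0.99))
  expect_equal(round(100 * post_test_probability(0.327, round(df$lr_neg, 2)), 1),
               c(10.1, 16.9, 20.8, 28.7, 31.6, 32.5))
  # internal Bayes consistency of the unrounded column
  expect_equal(df$post_prob_neg / 100,
               post_test_probability(0.327, df$lr_neg), tolerance = 1e-12)
  # the recommended rule-in threshold is 4 or more of 6
  expect_equal(rt$recommended_k, 4L)
  # sensitivity non-increasing, specificity non-decreasing in k
  expect_true(all(diff(df$sensitivity) <= 0))
  expect_true(all(diff(df$specificity) >= 0))
})

test_that("a single perfect factor yields a perfect one-row rule", {
  df <- data.frame(f = rep(c(1, 0), each = 30),
                   pain_with_running = rep(c(1, 0), each = 30))
  rt <- suppressWarnings(build_rule_table(df, "f"))
  row <- rt$rows[[1]]
  expect_equal(row$sensitivity$estimate, 1)
  expect_equal(row$specificity$estimate, 1)
  expect_true(is.infinite(row$lr_pos$estimate))
  expect_equal(row$post_prob_pos, 1)
})

test_that("rule monotonicity holds on every simulated cohort", {
  spec <- default_cohort_spec(seed = 33, missing_value_rate = 0)
  b0 <- calibrate_intercept(spec)
  factors <- c("incontinence_any", "previous_rri", "runner_novice",
               "delivery_vaginal", "pafs_score_bin", "sleep_hours_avg_bin")
  for (i in 1:30) {
    spec$seed <- 33 + i
    co <- generate_cohort(spec, intercept = b0)
    co <- apply_cutpoints(co, replication_cutpoints()[c("pafs_score", "sleep_hours_avg")])
    co <- postrun:::add_indicator_columns(co)
    rt <- build_rule_table(co, factors, fit_or = FALSE)
    df <- as.data.frame(rt)
    expect_true(all(diff(df$sensitivity) <= 1e-12))
    expect_true(all(diff(df$specificity) >= -1e-12))
  }
})
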