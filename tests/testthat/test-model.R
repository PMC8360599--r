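test_that("a single-predictor fit agrees with the bivariate screen", {
  d <- expand_2x2(60, 90, 55, 140)
  f <- fit_logistic(data.frame(x = d$exposure), d$outcome)
  b <- bivariate_logistic(d$exposure, d$outcome)
  expect_equal(unname(f$or["x"]), b$odds_ratio, tolerance = 1e-10)
  expect_equal(f$nagelkerke_r2, b$nagelkerke_r2, tolerance = 1e-10)
})

test_that("rank deficiency and separation are diagnosed", {
  set.seed(20)
  X <- data.frame(a = rbinom(100, 1, 0.5))
  X$b <- X$a
  y <- rbinom(100, 1, 0.4)
  expect_error(fit_logistic(X, y), "aliased column\\(s\\): b")
  sep <- data.frame(x = rep(c(0, 1), each = 25))
  f <- fit_logistic(sep, sep$x)
  expect_true(f$separated)
  expect_false(f$converged)
  expect_error(fit_logistic(data.frame(x = 1:3, z = c(1, 0, 1)), c(0, 1, 1)),
               "more observations")
})

test_that("elimination traces are exact: LR identity and refit reproducibility", {
  set.seed(22)
  co <- postrun:::add_indicator_columns(quick_cohort(538, seed = 9))
  vars <- c("incontinence_any", "previous_rri", "runner_novice",
            "diastasis_recti", "breastfeeding", "parity_primiparous")
  X <- co[, vars]
  y <- co$pain_with_running
  tr <- backward_eliminate(X, y, removal_alpha = 0.5)
  # each removal drops the log-likelihood by exactly LR/2
  cur <- vars
  ll <- fit_logistic(X[, cur, drop = FALSE], y)$log_likelihood
  for (i in seq_len(nrow(tr$steps))) {
    cur <- setdiff(cur, tr$steps$removed[i])
    ll_next <- if (length(cur)) fit_logistic(X[, cur, drop = FALSE], y)$log_likelihood
               else postrun:::ll_null_binary(sum(y), sum(1 - y))
    expect_equal(ll - ll_next, tr$steps$lr_statistic[i] / 2, tolerance = 1e-8)
    ll <- ll_next
  }
  # refitting the final set from scratch reproduces the trace's final fit
  if (length(tr$final_variables)) {
    refit <- fit_logistic(X[, tr$final_variables, drop = FALSE], y)
    expect_equal(refit$coefficients, tr$final_fit$coefficients, tolerance = 1e-8)
    expect_equal(refit$log_likelihood, tr$final_fit$log_likelihood, tolerance = 1e-8)
  }
})

test_that("removal threshold extremes keep the full model or empty it", {
  set.seed(23)
  X <- as.data.frame(matrix(rbinom(538 * 4, 1, 0.4), 538))
  y <- rbinom(538, 1, 0.33)
  full <- backward_eliminate(X, y, removal_alpha = 0.999999)
  expect_setequal(full$final_variables, names(X))
  none <- backward_eliminate(X, y, removal_alpha = 1e-12)
  expect_length(none$final_variables, 0)
  expect_null(none$final_fit)
})

test_that("null predictors are retained at roughly the removal-alpha rate", {
  set.seed(24)
  sizes <- replicate(60, {
    X <- as.data.frame(matrix(rbinom(538 * 6, 1, 0.4), 538))
    y <- rbinom(538, 1, 0.33)
    length(backward_eliminate(X, y, removal_alpha = 0.10)$final_variables)
  })
  expect_lt(abs(mean(sizes) - 0.6), 0.35)
})

test_that("a strong predictor survives elimination among nulls", {
  set.seed(25)
  kept <- replicate(30, {
    x1 <- rbinom(538, 1, 0.4)
    X <- data.frame(x1 = x1, matrix(rbinom(538 * 5, 1, 0.4), 538))
    y <- rbinom(538, 1, plogis(-1.2 + log(3) * x1))
    "x1" %in% backward_eliminate(X, y)$final_variables
  })
  expect_gte(mean(kept), 0.9)
})

test_that("multivariable fits recover their generating odds ratios at scale", {
  spec <- default_cohort_spec(n_respondents = 20000, seed = 26,
                              missing_value_rate = 0)
  co <- generate_cohort(spec)
  ind <- as.data.frame(
    sapply(spec$log_odds_effects, function(e) postrun:::effect_indicator(co, e))
  )
  f <- fit_logistic(ind, co$pain_with_running)
  gen <- vapply(spec$log_odds_effects, `[[`, numeric(1), "log_or")
  for (v in names(gen)) {
    expect_lt(abs(f$coefficients[[v]] - gen[[v]]),
              3 * f$se[[v]], label = v)
  }
  # permuting the outcome kills every effect
  set.seed(27)
  fp <- fit_logistic(ind, sample(co$pain_with_running))
  expect_true(all(abs(fp$coefficients[names(gen)]) < 0.15))
  expect_lt(fp$nagelkerke_r2, 0.005)
})
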