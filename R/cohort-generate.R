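# Cohort simulation: covariates by inverse-CDF transform of (possibly
# copula-coupled) uniforms, outcome from a calibrated logistic model.

# Quantile transform of uniforms u for one marginal definition.
marginal_quantile <- function(u, m) {
  switch(m$type,
    binary = as.integer(u > 1 - m$p),
    categorical = {
      idx <- findInterval(u, cumsum(m$probs), left.open = TRUE) + 1L
      factor(m$levels[pmin(idx, length(m$levels))], levels = m$levels)
    },
    continuous = {
      lo <- m$lower %||% -Inf
      hi <- m$upper %||% Inf
      plo <- stats::pnorm(lo, m$mean, m$sd)
      phi <- stats::pnorm(hi, m$mean, m$sd)
      x <- stats::qnorm(plo + u * (phi - plo), m$mean, m$sd)
      if (isTRUE(m$integer)) round(x) else x
    },
    stop("unknown marginal type: ", m$type)
  )
}

# Draw the covariate block of a cohort (no outcome, no missingness).
draw_covariates <- function(spec, n) {
  vars <- names(spec$covariate_marginals)
  u <- matrix(stats::runif(n * length(vars)), nrow = n,
              dimnames = list(NULL, vars))
  if (!is.null(spec$copula)) {
    cv <- rownames(spec$copula)
    z <- matrix(stats::rnorm(n * length(cv)), nrow = n) %*% chol(spec$copula)
    u[, cv] <- stats::pnorm(z)
  }
  out <- lapply(vars, function(v) marginal_quantile(u[, v], spec$covariate_marginals[[v]]))
  names(out) <- vars
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  # coding rule: respondents reporting no fatigue carry a PAFS score of 0
  if (all(c("fatigue_present", "pafs_score") %in% vars)) {
    df$pafs_score[df$fatigue_present == 0L] <- 0
  }
  df
}

# 0/1 indicator for one risk-factor effect definition evaluated on a cohort.
effect_indicator <- function(df, e) {
  x <- df[[e$variable]]
  if (!is.null(e$level)) {
    as.integer(x == e$level)
  } else if (!is.null(e$threshold)) {
    if (identical(e$direction, "le")) as.integer(x <= e$threshold)
    else as.integer(x >= e$threshold)
  } else {
    as.integer(x == 1L)
  }
}

# Linear predictor (without intercept) of the outcome model.
effect_lp <- function(df, effects) {
  lp <- numeric(nrow(df))
  for (e in effects) lp <- lp + e$log_or * effect_indicator(df, e)
  lp
}

#' Calibrate the outcome-model intercept to the target prevalence
#'
#' Finds the log-odds intercept \eqn{\beta_0} such that the mean simulated
#' outcome probability over a large covariate sample equals the spec's
#' target prevalence: root of
#' \eqn{E[\mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j I_j)] - \pi^*}.
#' With all effects zero this reduces to the closed form
#' \eqn{\beta_0 = \log(\pi^*/(1-\pi^*))}.
#'
#' @param spec a [cohort_spec()].
#' @param sample_size_for_calibration Monte-Carlo sample size for the
#'   expectation (>= 1000; default 50000).
#' @return the calibrated intercept (log-odds scale), deterministic for a
#'   fixed `spec$seed`.
#' @export
calibrate_intercept <- function(spec, sample_size_for_calibration = 50000L) {
  validate_cohort_spec(spec)
  stopifnot(sample_size_for_calibration >= 1000)
  if (length(spec$log_odds_effects) == 0L) {
    return(stats::qlogis(spec$target_prevalence))
  }
  lp <- with_seed(stage_seed(spec$seed, "calibration"), {
    cov <- draw_covariates(spec, sample_size_for_calibration)
    effect_lp(cov, spec$log_odds_effects)
  })
  f <- function(b0) mean(stats::plogis(b0 + lp)) - spec$target_prevalence
  lo <- stats::qlogis(spec$target_prevalence) - max(abs(lp)) - 1
  hi <- stats::qlogis(spec$target_prevalence) + max(abs(lp)) + 1
  if (!is.finite(f(lo)) || !is.finite(f(hi)) || f(lo) * f(hi) > 0) {
    stop("intercept calibration failed: effects force degenerate outcome probabilities",
         call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a synthetic survey cohort
#'
#' Draws `spec$n_respondents` survey records: covariates from their
#' marginals (independently, unless the spec carries a copula), the
#' pain-with-running outcome from
#' \eqn{\mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j I_j))}
#' with the intercept calibrated by [calibrate_intercept()]. Respondents
#' reporting no fatigue are coded PAFS = 0.
#'
#' @param spec a [cohort_spec()].
#' @param intercept optional pre-calibrated intercept; computed when `NULL`.
#' @return a data.frame of survey records (one row per respondent) with the
#'   calibrated intercept in `attr(, "intercept")`.
#' @export
generate_cohort <- function(spec, intercept = NULL) {
  validate_cohort_spec(spec)
  if (is.null(intercept)) intercept <- calibrate_intercept(spec)
  n <- spec$n_respondents
  df <- with_seed(stage_seed(spec$seed, "covariates"),
                  draw_covariates(spec, n))
  pr <- stats::plogis(intercept + effect_lp(df, spec$log_odds_effects))
  df$pain_with_running <- with_seed(stage_seed(spec$seed, "outcome"),
                                    stats::rbinom(n, 1L, pr))
  df <- cbind(id = sprintf("R%05d", seq_len(n)), df, stringsAsFactors = FALSE)
  attr(df, "intercept") <- intercept
  attr(df, "spec") <- spec
  df
}

#' Delete cells from a complete cohort
#'
#' The default (`mode = "mcar"`) deletes cells completely at random,
#' honouring the spec's cell-level rate and confining deletions to at most
#' `missing_case_rate` of rows. The outcome and `id` columns are never
#' deleted. The `"mar"` and `"mnar"` modes exist to exercise the power of
#' the MCAR test: `"mar"` concentrates deletions of `target_column` in rows
#' with low average sleep (an always-observed covariate); `"mnar"` deletes
#' preferentially the highest values of `target_column` itself.
#'
#' @param cohort complete cohort data.frame from [generate_cohort()].
#' @param spec the [cohort_spec()] providing the rates and seed.
#' @param mode `"mcar"` (default), `"mar"`, or `"mnar"`.
#' @param target_column column whose values drive the `"mar"`/`"mnar"`
#'   deletion mechanism (default `"pafs_score"`).
#' @return the cohort with `NA` cells; deleted positions are recorded in
#'   `attr(, "missing_cells")` (row/column data.frame) and the mechanism in
#'   `attr(, "missingness_mode")`.
#' @export
inject_missingness <- function(cohort, spec, mode = c("mcar", "mar", "mnar"),
                               target_column = "pafs_score") {
  mode <- match.arg(mode)
  if (anyNA(cohort)) stop("cohort must be complete before injection", call. = FALSE)
  eligible <- setdiff(names(cohort), c("id", "pain_with_running"))
  n <- nrow(cohort)
  n_cells <- round(n * length(eligible) * spec$missing_value_rate)
  if (n_cells == 0L) {
    attr(cohort, "missing_cells") <- data.frame(row = integer(0), column = character(0))
    attr(cohort, "missingness_mode") <- mode
    return(cohort)
  }
  n_cases <- max(1L, round(n * spec$missing_case_rate))
  if (n_cells > n_cases * length(eligible)) {
    stop(sprintf("cannot place %d missing cells within %d allowed rows", n_cells, n_cases),
         call. = FALSE)
  }
  cells <- with_seed(stage_seed(spec$seed, paste0("missingness_", mode)), {
    if (mode == "mcar") {
      rows <- sample.int(n, n_cases)
      slots <- expand.grid(row = rows, column = eligible,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      slots[sample.int(nrow(slots), n_cells), ]
    } else {
      # power-testing modes: deterministic extreme-value deletion of the
      # target column -- the highest values of the column itself (MNAR) or
      # the rows with the shortest always-observed sleep (MAR)
      drv <- if (mode == "mnar") as.numeric(cohort[[target_column]])
             else -as.numeric(cohort[["sleep_hours_avg"]])
      rows <- order(drv, decreasing = TRUE)[seq_len(min(n_cells, n))]
      data.frame(row = rows, column = target_column, stringsAsFactors = FALSE)
    }
  })
  for (i in seq_len(nrow(cells))) {
    cohort[cells$row[i], cells$column[i]] <- NA
  }
  rownames(cells) <- NULL
  attr(cohort, "missing_cells") <- cells
  attr(cohort, "missingness_mode") <- mode
  cohort
}
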