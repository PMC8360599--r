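# Multivariable logistic modelling: maximum-likelihood fits and backward
# elimination on exact likelihood-ratio removal tests.

#' Maximum-likelihood logistic fit
#'
#' Fits the binomial GLM of the outcome on the supplied predictor columns
#' by iteratively reweighted least squares (convergence at relative
#' log-likelihood change < 1e-10 or 25 iterations), returning coefficients,
#' Wald standard errors and 95% CIs on the odds-ratio scale, the
#' log-likelihood, and Nagelkerke's pseudo R-squared
#' \eqn{[1 - e^{2(LL_0 - LL_1)/n}]/[1 - e^{2 LL_0/n}]}. Quasi-complete
#' separation is detected from the usual fitted-probability diagnostic and
#' flagged; rank-deficient designs are an error naming the aliased
#' columns.
#'
#' @param design data.frame (or matrix) of predictor columns.
#' @param outcome binary (0/1) outcome vector.
#' @return list of class `logistic_fit`: `coefficients` (named, incl.
#'   `(Intercept)`), `se`, `or`, `or_ci` (matrix), `p_values` (Wald),
#'   `log_likelihood`, `ll_null`, `n`, `converged`, `separated`,
#'   `nagelkerke_r2`, and the underlying `glm` object.
#' @export
fit_logistic <- function(design, outcome) {
  design <- as.data.frame(design)
  y <- as.integer(outcome)
  n <- length(y)
  if (n <= ncol(design) + 1L) {
    stop("need more observations than parameters", call. = FALSE)
  }
  if (anyDuplicated(names(design))) stop("duplicate design columns", call. = FALSE)
  X <- stats::model.matrix(~ ., data = design)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(.y = y, design, check.names = TRUE)
  separated <- FALSE
  nonconv <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 25L)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      } else if (grepl("did not converge", msg)) {
        nonconv <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)
  beta <- stats::coef(fit)
  # coefficients running away without convergence is the separation signature
  if (nonconv && max(abs(beta)) > 10) separated <- TRUE
  se <- sm$coefficients[, "Std. Error"]
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- ll_null_binary(sum(y == 1L), sum(y == 0L))
  or_ci <- exp(cbind(beta - stats::qnorm(0.975) * se,
                     beta + stats::qnorm(0.975) * se))
  colnames(or_ci) <- c("low", "high")
  structure(
    list(coefficients = beta, se = se, or = exp(beta), or_ci = or_ci,
         p_values = 2 * stats::pnorm(-abs(beta / se)),
         log_likelihood = ll1, ll_null = ll0, n = n,
         converged = fit$converged && !nonconv && !separated,
         separated = separated,
         nagelkerke_r2 = nagelkerke_r2(ll0, ll1, n),
         glm = fit),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d, logLik = %.3f, Nagelkerke R2 = %.3f)%s\n",
              x$n, x$log_likelihood, x$nagelkerke_r2,
              if (x$separated) "  [separation detected]" else ""))
  tab <- data.frame(OR = x$or, ci_low = x$or_ci[, 1], ci_high = x$or_ci[, 2],
                    p = x$p_values)
  print(round(tab[-1L, , drop = FALSE], 4))
  invisible(x)
}

#' Backward elimination by exact likelihood-ratio tests
#'
#' Starts from the model containing every admitted predictor and
#' repeatedly removes the predictor whose likelihood-ratio removal test
#' (full model vs the model without it, 1 df) has the largest p-value, as
#' long as that p-value is at or above `removal_alpha`. Ties are broken
#' toward the later-entered predictor. Each removal refits the reduced
#' model exactly (no conditional-estimate approximation).
#'
#' @param design data.frame of admitted predictor columns.
#' @param outcome binary (0/1) outcome.
#' @param removal_alpha removal threshold on the LR p-value (default 0.10).
#' @return list of class `elimination_trace`: `steps` (data.frame of
#'   removed variable, LR statistic, p per step), `final_variables`,
#'   `final_fit` (a [fit_logistic()] result; `NULL` only if every variable
#'   is removed, in which case the intercept-only fit is reported in
#'   `null_fit`).
#' @export
backward_eliminate <- function(design, outcome, removal_alpha = 0.10) {
  design <- as.data.frame(design)
  vars <- names(design)
  steps <- data.frame(removed = character(0), lr_statistic = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  fit <- fit_logistic(design[, vars, drop = FALSE], outcome)
  repeat {
    if (length(vars) == 0L) break
    if (!is.null(fit$glm) && !fit$glm$converged) {
      warning("non-convergence during elimination; returning partial trace",
              call. = FALSE)
      break
    }
    lr <- vapply(vars, function(v) {
      reduced <- setdiff(vars, v)
      ll_red <- if (length(reduced)) {
        fit_logistic(design[, reduced, drop = FALSE], outcome)$log_likelihood
      } else {
        fit$ll_null
      }
      stat <- 2 * (fit$log_likelihood - ll_red)
      c(stat = stat, p = stats::pchisq(stat, 1L, lower.tail = FALSE))
    }, numeric(2))
    pmax_ <- max(lr["p", ])
    if (pmax_ < removal_alpha) break
    # tie-break: largest p, then the latest-entered (right-most) variable
    cand <- which(lr["p", ] == pmax_)
    worst <- cand[length(cand)]
    steps <- rbind(steps, data.frame(
      removed = vars[worst], lr_statistic = lr["stat", worst],
      p_value = lr["p", worst], stringsAsFactors = FALSE
    ))
    vars <- vars[-worst]
    fit <- if (length(vars)) fit_logistic(design[, vars, drop = FALSE], outcome)
           else NULL
    if (is.null(fit)) break
  }
  structure(
    list(steps = steps, final_variables = vars, final_fit = fit,
         removal_alpha = removal_alpha),
    class = "elimination_trace"
  )
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("Backward elimination (removal alpha = %.2f)\n", x$removal_alpha))
  if (nrow(x$steps)) {
    for (i in seq_len(nrow(x$steps))) {
      cat(sprintf("  removed %-24s LR = %6.3f, p = %.3f\n",
                  x$steps$removed[i], x$steps$lr_statistic[i], x$steps$p_value[i]))
    }
  } else {
    cat("  no variables removed\n")
  }
  cat("Final model:", if (length(x$final_variables))
    paste(x$final_variables, collapse = ", ") else "(intercept only)", "\n")
  invisible(x)
}
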