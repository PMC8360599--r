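# derive_cdt(): the end-to-end derivation of the cumulative risk-factor
# clinical decision tool from a survey cohort, returned as a classed model
# object.

# Add the one-hot dummies for delivery type and runner type that the
# screening stage analyses as separate binary predictors.
add_indicator_columns <- function(dataset) {
  if ("delivery" %in% names(dataset)) {
    for (l in c("vaginal", "cesarean", "other")) {
      dataset[[paste0("delivery_", l)]] <- as.integer(dataset$delivery == l)
    }
  }
  if ("runner_type" %in% names(dataset)) {
    for (l in c("novice", "recreational", "elite")) {
      dataset[[paste0("runner_", l)]] <- as.integer(dataset$runner_type == l)
    }
  }
  dataset
}

# Continuous predictors dichotomized before screening.
continuous_predictors <- function() {
  c("pafs_score", "epds_score", "sleep_hours_avg", "weekly_mileage",
    "weeks_to_first_run")
}

# The candidate pool entering construct selection (built from whichever
# survey columns are present).
candidate_pool <- function(dataset) {
  pool <- c(
    "parity_primiparous", "race_caucasian", "education_hs_or_more", "married",
    "diastasis_recti", "breastfeeding", "incontinence_any",
    "delivery_vaginal", "delivery_cesarean", "delivery_other",
    "fatigue_present", "pafs_score_bin", "epds_score_bin",
    "sleep_hours_avg_bin", "sleep_interruptions",
    "weekly_mileage_bin", "weeks_to_first_run_bin",
    "runner_novice", "runner_recreational", "runner_elite", "previous_rri"
  )
  intersect(pool, names(dataset))
}

#' Derive the clinical decision tool from a survey cohort
#'
#' Runs the published derivation pipeline end to end on one analysis
#' dataset: descriptive group comparisons, Little's MCAR test, pooled
#' regression imputation, ROC-midpoint dichotomization of the continuous
#' predictors, one-representative-per-construct selection, bivariate
#' logistic screening (retention at p < `retention_alpha`), Phi / Cramer's
#' V multicollinearity filtering at `collinearity_cutoff`, backward
#' elimination at `removal_alpha`, and the cumulative risk-factor rule
#' table over the final factors.
#'
#' @param data survey cohort data.frame (may contain missing cells).
#' @param outcome outcome column name (binary 0/1).
#' @param retention_alpha bivariate retention threshold (default 0.15).
#' @param collinearity_cutoff pairwise association cutoff (default 0.6).
#' @param removal_alpha backward-elimination removal threshold (default 0.10).
#' @param n_imputations pooled imputation draws (default 5).
#' @param pre_test pre-test probability for the rule table; default is the
#'   sample outcome prevalence.
#' @param cutpoints `"estimated"` (ROC midpoints from this dataset, the
#'   default) or `"replication"` (the packaged published thresholds), or a
#'   list of [roc_cutpoint()]-style cutpoint objects.
#' @param construct_map see [select_constructs()].
#' @param seed seed for the imputation draws.
#' @return an object of class `cdt` with components `descriptives`,
#'   `missingness`, `cutpoints`, `screen` (bivariate table), `candidates`,
#'   `collinearity`, `trace` (elimination), `final_fit`, `factors`,
#'   `rule_table`, `pre_test`, `n`, `call`, and the completed analysis
#'   `data`.
#' @seealso [run_pipeline()] to additionally write the report bundle.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(seed = 7))
#' tool <- derive_cdt(cohort, cutpoints = "replication")
#' print(tool)
#' @export
derive_cdt <- function(data, outcome = "pain_with_running",
                       retention_alpha = 0.15, collinearity_cutoff = 0.6,
                       removal_alpha = 0.10, n_imputations = 5L,
                       pre_test = NULL, cutpoints = "estimated",
                       construct_map = default_construct_map(), seed = 1L) {
  cl <- match.call()
  stopifnot(outcome %in% names(data))
  descriptives <- descriptive_compare(data, outcome = outcome)
  missingness <- little_mcar_test(data)
  completed <- impute_pooled(data, n_imputations = n_imputations, seed = seed)
  cont <- intersect(continuous_predictors(), names(completed))
  cps <- if (is.list(cutpoints)) {
    cutpoints
  } else if (identical(cutpoints, "replication")) {
    replication_cutpoints()[cont]
  } else {
    lapply(cont, function(v)
      roc_cutpoint(completed[[v]], completed[[outcome]], variable = v))
  }
  completed <- apply_cutpoints(completed, cps)
  completed <- add_indicator_columns(completed)
  candidates <- select_constructs(candidate_pool(completed), construct_map)
  screen <- screen_bivariate(completed, candidates, outcome = outcome,
                             retention_alpha = retention_alpha)
  retained <- screen$variable[screen$retained]
  if (length(retained) < 2L) {
    stop("fewer than two predictors retained at the screening stage; ",
         "no multivariable model can be built", call. = FALSE)
  }
  pv <- stats::setNames(screen$p_value, screen$variable)
  assoc <- collinearity_filter(completed, retained,
                               cutoff = collinearity_cutoff, p_values = pv)
  admitted <- assoc$admitted
  # when every level of a one-hot group survives screening, the dummies sum
  # to the intercept; the weakest level becomes the reference
  reference_dropped <- character(0)
  for (g in default_exempt_groups()) {
    if (all(g %in% admitted)) {
      ref <- g[which.max(pv[g])]
      admitted <- setdiff(admitted, ref)
      reference_dropped <- c(reference_dropped, ref)
    }
  }
  assoc$admitted <- admitted
  assoc$reference_dropped <- reference_dropped
  trace <- backward_eliminate(completed[, assoc$admitted, drop = FALSE],
                              completed[[outcome]],
                              removal_alpha = removal_alpha)
  factors <- trace$final_variables
  if (is.null(pre_test)) pre_test <- mean(completed[[outcome]])
  rule <- if (length(factors)) {
    build_rule_table(completed, factors, pre_test = pre_test, outcome = outcome)
  } else {
    NULL
  }
  structure(
    list(descriptives = descriptives, missingness = missingness,
         cutpoints = cps, candidates = candidates, screen = screen,
         collinearity = assoc, trace = trace, final_fit = trace$final_fit,
         factors = factors, rule_table = rule, pre_test = pre_test,
         n = nrow(data), outcome = outcome, data = completed, call = cl,
         config = list(retention_alpha = retention_alpha,
                       collinearity_cutoff = collinearity_cutoff,
                       removal_alpha = removal_alpha,
                       n_imputations = n_imputations, seed = seed)),
    class = "cdt"
  )
}

#' @export
print.cdt <- function(x, ...) {
  cat("Clinical decision tool for postpartum running-related pain\n")
  cat(sprintf("  n = %d respondents, outcome prevalence %.1f%%\n",
              x$n, 100 * x$pre_test))
  cat(sprintf("  screened %d candidates; %d retained (p < %.2f); %d in final model\n",
              nrow(x$screen), sum(x$screen$retained),
              x$config$retention_alpha, length(x$factors)))
  if (length(x$factors)) {
    ors <- x$final_fit$or[x$factors]
    cat("  final risk factors (OR):\n")
    for (v in x$factors) cat(sprintf("    %-26s %.2f\n", v, ors[[v]]))
  }
  if (!is.null(x$rule_table) && !is.na(x$rule_table$recommended_k)) {
    k <- x$rule_table$recommended_k
    row <- x$rule_table$rows[[k]]
    cat(sprintf("  rule-in threshold: >= %d of %d factors (LR+ %.2f, post-test %.1f%%)\n",
                k, x$rule_table$K, row$lr_pos$estimate, 100 * row$post_prob_pos))
  }
  invisible(x)
}

#' @export
summary.cdt <- function(object, ...) {
  structure(list(cdt = object), class = "summary.cdt")
}

#' @export
print.summary.cdt <- function(x, ...) {
  obj <- x$cdt
  print(obj)
  cat("\nMissingness:\n"); print(obj$missingness)
  cat("\nBivariate screen:\n")
  scr <- obj$screen
  scr[2:6] <- lapply(scr[2:6], round, 3)
  print(scr, row.names = FALSE)
  cat("\n"); print(obj$collinearity)
  cat("\n"); print(obj$trace)
  if (!is.null(obj$final_fit)) { cat("\n"); print(obj$final_fit) }
  if (!is.null(obj$rule_table)) { cat("\n"); print(obj$rule_table) }
  invisible(x)
}

#' @export
coef.cdt <- function(object, ...) {
  if (is.null(object$final_fit)) return(numeric(0))
  object$final_fit$coefficients
}

#' Predict from a derived clinical decision tool
#'
#' @param object a `cdt`.
#' @param newdata survey records; raw columns are passed through the
#'   tool's stored cutpoints and indicator coding. Defaults to the
#'   derivation data.
#' @param type `"score"` (count of positive risk factors), `"response"`
#'   (fitted outcome probability from the final logistic model), or
#'   `"posttest"` (Bayes post-test probability at the tool's recommended
#'   rule-in threshold).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.cdt <- function(object, newdata = NULL,
                        type = c("score", "response", "posttest"), ...) {
  type <- match.arg(type)
  df <- if (is.null(newdata)) object$data else {
    nd <- newdata
    have <- all(object$factors %in% names(nd))
    if (!have) {
      nd <- apply_cutpoints(nd, object$cutpoints)
      nd <- add_indicator_columns(nd)
    }
    nd
  }
  score <- score_respondents(df, object$factors)
  switch(type,
    score = score,
    response = {
      beta <- object$final_fit$coefficients
      lp <- beta[["(Intercept)"]] +
        as.matrix(df[, object$factors, drop = FALSE]) %*% beta[object$factors]
      stats::plogis(drop(lp))
    },
    posttest = {
      k <- object$rule_table$recommended_k
      if (is.na(k)) stop("no recommended threshold available", call. = FALSE)
      row <- object$rule_table$rows[[k]]
      ifelse(score >= k, row$post_prob_pos, row$post_prob_neg)
    }
  )
}

#' @export
residuals.cdt <- function(object, ...) {
  if (is.null(object$final_fit)) return(numeric(0))
  stats::residuals(object$final_fit$glm, ...)
}

#' Plot the cumulative-rule operating profile
#'
#' Post-test probabilities of a positive and a negative finding at each
#' "k or more of K" threshold, against the pre-test prevalence.
#'
#' @param x a `cdt`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cdt <- function(x, ...) {
  rt <- x$rule_table
  if (is.null(rt)) stop("no rule table to plot", call. = FALSE)
  df <- as.data.frame(rt)
  graphics::plot(df$k, df$post_prob_pos, type = "b", pch = 19,
                 ylim = c(0, 100), xlab = "risk factors present (k or more)",
                 ylab = "post-test probability of pain (%)", ...)
  graphics::lines(df$k, df$post_prob_neg, type = "b", pch = 1, lty = 2)
  graphics::abline(h = 100 * rt$pre_test, col = "grey50", lty = 3)
  if (!is.na(rt$recommended_k)) graphics::abline(v = rt$recommended_k, col = "red3", lty = 3)
  graphics::legend("topleft", bty = "n", lty = c(1, 2, 3),
                   pch = c(19, 1, NA),
                   legend = c("positive finding", "negative finding", "pre-test"))
  invisible(x)
}
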