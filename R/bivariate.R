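# Descriptive group comparisons and single-predictor logistic screening
# with the p < 0.15 retention rule.

#' 2x2 contingency table of exposure by outcome
#'
#' @param a exposed with the outcome (true positives when the exposure is a
#'   rule threshold).
#' @param b exposed without the outcome.
#' @param c_ unexposed with the outcome.
#' @param d unexposed without the outcome.
#' @return an object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c_, d) {
  cells <- c(a = a, b = b, c = c_, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty 2x2 table", call. = FALSE)
  structure(as.list(cells), class = "two_by_two")
}

# Coerce a two_by_two (or a length-4 numeric a,b,c,d) to a named list.
as_two_by_two <- function(t) {
  if (inherits(t, "two_by_two")) return(t)
  if (is.numeric(t) && length(t) == 4L) return(two_by_two(t[1], t[2], t[3], t[4]))
  stop("expected a two_by_two or a length-4 count vector (a, b, c, d)", call. = FALSE)
}

# Tabulate a binary exposure against a binary outcome.
tabulate_2x2 <- function(exposure, outcome) {
  keep <- !is.na(exposure) & !is.na(outcome)
  e <- as.integer(exposure[keep]); y <- as.integer(outcome[keep])
  two_by_two(sum(e == 1L & y == 1L), sum(e == 1L & y == 0L),
             sum(e == 0L & y == 1L), sum(e == 0L & y == 0L))
}

#' Cross-product odds ratio with Wald confidence interval
#'
#' `OR = ad/bc`; 95% CI `exp(log OR +/- 1.96 se)` with
#' `se = sqrt(1/a + 1/b + 1/c + 1/d)`. Any zero cell triggers the
#' Haldane-Anscombe correction (+0.5 to all four cells) for both the
#' estimate and the interval, flagged in the result.
#'
#' @param t a [two_by_two()] (or counts `c(a, b, c, d)`).
#' @return list with `odds_ratio`, `ci95` (length-2), `corrected` flag.
#' @export
odds_ratio_2x2 <- function(t) {
  t <- as_two_by_two(t)
  cells <- c(t$a, t$b, t$c, t$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(odds_ratio = or, ci95 = ci, corrected = corrected)
}

# Nagelkerke pseudo R-squared from null and fitted log-likelihoods.
nagelkerke_r2 <- function(ll0, ll1, n) {
  cs <- 1 - exp(2 * (ll0 - ll1) / n)
  cs_max <- 1 - exp(2 * ll0 / n)
  if (cs_max <= 0) return(0)
  max(0, min(1, cs / cs_max))
}

#' Single-predictor logistic screen
#'
#' Fits the one-predictor logistic model of the outcome on a binary risk
#' indicator by iteratively reweighted least squares, reporting the odds
#' ratio with its Wald 95% CI and p-value, Nagelkerke's pseudo
#' R-squared, and the retention flag of the screening rule
#' (retained iff p < `retention_alpha`). For a binary predictor the
#' fitted odds ratio equals the 2x2 cross-product ratio.
#'
#' @param predictor binary (0/1) risk indicator.
#' @param outcome binary (0/1) outcome, both classes present.
#' @param variable name recorded in the result.
#' @param retention_alpha screening threshold (default 0.15).
#' @return list of class `bivariate_result`: `variable`, `odds_ratio`,
#'   `ci95`, `p_value`, `nagelkerke_r2`, `retained`, `separated`.
#' @export
bivariate_logistic <- function(predictor, outcome,
                               variable = deparse(substitute(predictor)),
                               retention_alpha = 0.15) {
  keep <- !is.na(predictor) & !is.na(outcome)
  x <- as.numeric(predictor[keep]); y <- as.integer(outcome[keep])
  if (length(unique(y)) < 2L) stop("both outcome classes must be present", call. = FALSE)
  fit <- fit_logistic(data.frame(x = x), y)
  beta <- fit$coefficients[["x"]]
  se <- fit$se[["x"]]
  p <- 2 * stats::pnorm(-abs(beta / se))
  ci <- if (fit$separated) c(0, Inf) else exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
  structure(
    list(variable = variable,
         odds_ratio = exp(beta),
         ci95 = ci,
         p_value = p,
         nagelkerke_r2 = fit$nagelkerke_r2,
         retained = p < retention_alpha,
         separated = fit$separated),
    class = "bivariate_result"
  )
}

#' @export
print.bivariate_result <- function(x, ...) {
  cat(sprintf("%s: OR %.2f (%.2f, %.2f), p = %.4g, Nagelkerke R2 = %.3f%s\n",
              x$variable, x$odds_ratio, x$ci95[1], x$ci95[2], x$p_value,
              x$nagelkerke_r2, if (x$retained) "  [retained]" else ""))
  invisible(x)
}

#' Screen a set of candidate predictors against the outcome
#'
#' Runs [bivariate_logistic()] for every candidate column and assembles the
#' screening table (one row per candidate).
#'
#' @param dataset data.frame containing binary candidate columns and the
#'   outcome.
#' @param candidates character vector of candidate column names.
#' @param outcome outcome column name.
#' @param retention_alpha retention threshold (default 0.15).
#' @return data.frame: variable, odds_ratio, ci_low, ci_high, p_value,
#'   nagelkerke_r2, retained.
#' @export
screen_bivariate <- function(dataset, candidates,
                             outcome = "pain_with_running",
                             retention_alpha = 0.15) {
  rows <- lapply(candidates, function(v) {
    r <- bivariate_logistic(dataset[[v]], dataset[[outcome]], variable = v,
                            retention_alpha = retention_alpha)
    data.frame(variable = v, odds_ratio = r$odds_ratio,
               ci_low = r$ci95[1], ci_high = r$ci95[2],
               p_value = r$p_value, nagelkerke_r2 = r$nagelkerke_r2,
               retained = r$retained, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Descriptive comparison of respondents with and without pain
#'
#' Continuous variables are compared by pooled-variance two-sample t-tests,
#' binary/categorical variables by Pearson chi-square tests (no continuity
#' correction), and summarised as mean (SD) or n (%) per outcome group.
#'
#' @param dataset survey cohort data.frame.
#' @param variables columns to compare (default: all except `id` and the
#'   outcome).
#' @param outcome outcome column name.
#' @return data.frame: variable, type, summary in each group, test
#'   statistic, p-value.
#' @export
descriptive_compare <- function(dataset, variables = NULL,
                                outcome = "pain_with_running") {
  stopifnot(outcome %in% names(dataset))
  y <- dataset[[outcome]]
  if (is.null(variables)) variables <- setdiff(names(dataset), c("id", outcome))
  rows <- lapply(variables, function(v) {
    x <- dataset[[v]]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; g <- y[keep]
    if (is.numeric(x) && !is_binary01(x)) {
      if (stats::var(x) == 0) {
        stop(sprintf("t-test undefined for zero-variance variable '%s'", v),
             call. = FALSE)
      }
      tt <- stats::t.test(x[g == 1], x[g == 0], var.equal = TRUE)
      data.frame(
        variable = v, type = "continuous",
        pain = sprintf("%.2f (%.2f)", mean(x[g == 1]), stats::sd(x[g == 1])),
        no_pain = sprintf("%.2f (%.2f)", mean(x[g == 0]), stats::sd(x[g == 0])),
        statistic = unname(tt$statistic), p_value = tt$p.value,
        stringsAsFactors = FALSE
      )
    } else {
      tab <- table(factor(x), factor(g, levels = c(1, 0)))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      lab <- function(col) {
        shown <- if (nrow(tab) == 2L) 2L else seq_len(nrow(tab))
        paste(sprintf("%d (%.1f)", tab[shown, col],
                      100 * tab[shown, col] / sum(tab[, col])), collapse = "; ")
      }
      data.frame(
        variable = v, type = "categorical",
        pain = lab("1"), no_pain = lab("0"),
        statistic = unname(ct$statistic), p_value = ct$p.value,
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Choose one representative per latent construct
#'
#' When several candidate variables measure the same construct (e.g. the
#' fatigue yes/no item and the PAFS total score, or average sleep hours and
#' nightly interruptions), exactly one representative enters screening.
#'
#' @param candidates character vector of candidate variable names.
#' @param construct_map named list: construct -> list(members = members,
#'   keep = representatives in order of preference; the first one present
#'   among the candidates is kept). Defaults to the survey's fatigue and
#'   sleep constructs (PAFS score and average sleep hours kept).
#' @return the screened candidate list, with the choices in
#'   `attr(, "construct_choices")`.
#' @export
select_constructs <- function(candidates, construct_map = default_construct_map()) {
  choices <- list()
  for (cn in names(construct_map)) {
    cm <- construct_map[[cn]]
    present <- intersect(cm$members, candidates)
    if (length(present) == 0L) next
    keep <- intersect(cm$keep, candidates)[1L]
    if (is.na(keep)) {
      stop(sprintf("construct '%s' has no mapped representative among the candidates", cn),
           call. = FALSE)
    }
    drop <- setdiff(present, keep)
    candidates <- setdiff(candidates, drop)
    choices[[cn]] <- keep
  }
  attr(candidates, "construct_choices") <- choices
  candidates
}

#' @rdname select_constructs
#' @export
default_construct_map <- function() {
  list(
    fatigue = list(members = c("fatigue_present", "pafs_score", "pafs_score_bin"),
                   keep = c("pafs_score_bin", "pafs_score")),
    sleep = list(members = c("sleep_hours_avg", "sleep_interruptions",
                             "sleep_hours_avg_bin"),
                 keep = c("sleep_hours_avg_bin", "sleep_hours_avg"))
  )
}
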