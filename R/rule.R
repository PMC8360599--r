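# The cumulative risk-factor-count decision tool: scoring, diagnostic
# accuracy, likelihood ratios, and Bayes post-test probabilities.

# Wilson score 95% interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Count positive risk factors per respondent
#'
#' @param dataset data.frame of complete (post-imputation) records.
#' @param factors character vector of binary (0/1) risk-factor columns.
#' @return integer vector of risk scores in `0..length(factors)`.
#' @export
score_respondents <- function(dataset, factors) {
  block <- dataset[, factors, drop = FALSE]
  if (anyNA(block)) {
    stop("risk-factor columns contain missing values; impute before scoring",
         call. = FALSE)
  }
  if (!all(vapply(block, is_binary01, logical(1)))) {
    stop("all risk-factor columns must be binary 0/1", call. = FALSE)
  }
  as.integer(rowSums(block))
}

#' Diagnostic accuracy of a 2x2 rule table
#'
#' With `a` = true positives, `b` = false positives, `c` = false negatives
#' and `d` = true negatives: sensitivity `a/(a+c)` and specificity
#' `d/(b+d)` with Wilson score 95% CIs; `LR+ = sens/(1-spec)` and
#' `LR- = (1-sens)/spec` with log-method CIs,
#' `se(log LR+) = sqrt(1/a - 1/(a+c) + 1/b - 1/(b+d))` (and analogously
#' for LR-). A zero cell leaves the point likelihood ratio infinite (or
#' zero) and computes the CI on the Haldane-Anscombe (+0.5) corrected
#' table, so an infinite point estimate still carries a finite lower
#' bound.
#'
#' @param t a [two_by_two()] or counts `c(a, b, c, d)`.
#' @return list with `sensitivity`, `specificity`, `lr_pos`, `lr_neg`,
#'   each a list of `estimate` and `ci95`, plus the input `table`.
#' @export
diagnostic_accuracy <- function(t) {
  t <- as_two_by_two(t)
  a <- t$a; b <- t$b; c_ <- t$c; d <- t$d
  if (a + c_ == 0 || b + d == 0) {
    stop("both outcome groups must be non-empty", call. = FALSE)
  }
  sens <- a / (a + c_)
  spec <- d / (b + d)
  lr_pos <- if (spec == 1) { if (sens == 0) NaN else Inf } else sens / (1 - spec)
  lr_neg <- if (spec == 0) { if (sens == 1) NaN else Inf } else (1 - sens) / spec
  lr_ci <- function(pos) {
    cc <- c(a, b, c_, d)
    if (any(cc == 0)) cc <- cc + 0.5
    sn <- cc[1] / (cc[1] + cc[3]); sp <- cc[4] / (cc[2] + cc[4])
    if (pos) {
      est <- sn / (1 - sp)
      se <- sqrt(1 / cc[1] - 1 / (cc[1] + cc[3]) + 1 / cc[2] - 1 / (cc[2] + cc[4]))
    } else {
      est <- (1 - sn) / sp
      se <- sqrt(1 / cc[3] - 1 / (cc[1] + cc[3]) + 1 / cc[4] - 1 / (cc[2] + cc[4]))
    }
    ci <- exp(log(est) + c(-1, 1) * stats::qnorm(0.975) * se)
    # an infinite/zero point estimate keeps its degenerate bound
    if (pos && is.infinite(lr_pos)) ci[2] <- Inf
    if (!pos && is.infinite(lr_neg)) ci[2] <- Inf
    if (pos && !is.nan(lr_pos) && lr_pos == 0) ci[1] <- 0
    if (!pos && !is.nan(lr_neg) && lr_neg == 0) ci[1] <- 0
    ci
  }
  list(
    table = t,
    sensitivity = list(estimate = sens, ci95 = wilson_ci(a, a + c_)),
    specificity = list(estimate = spec, ci95 = wilson_ci(d, b + d)),
    lr_pos = list(estimate = lr_pos, ci95 = lr_ci(TRUE)),
    lr_neg = list(estimate = lr_neg, ci95 = lr_ci(FALSE))
  )
}

#' Bayes post-test probability
#'
#' Converts a pre-test probability to post-test via the odds form of
#' Bayes' theorem: `post = (pre/(1-pre)) * LR / (1 + (pre/(1-pre)) * LR)`.
#' An infinite likelihood ratio gives 1.
#'
#' @param pre_test pre-test probability, strictly in (0, 1).
#' @param lr likelihood ratio (>= 0; may be `Inf`).
#' @return the post-test probability.
#' @export
post_test_probability <- function(pre_test, lr) {
  if (any(pre_test <= 0 | pre_test >= 1)) {
    stop("pre-test probability must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(lr < 0, na.rm = TRUE)) stop("likelihood ratio must be non-negative", call. = FALSE)
  odds <- pre_test / (1 - pre_test) * lr
  ifelse(is.infinite(lr), 1, odds / (1 + odds))
}

# One rule row (threshold "score >= k") from a score/outcome pair.
rule_row <- function(score, outcome, k, pre_test, fit_or = TRUE) {
  pos <- as.integer(score >= k)
  t <- tabulate_2x2(pos, outcome)
  acc <- diagnostic_accuracy(t)
  or <- r2 <- p <- NA_real_
  ci <- c(NA_real_, NA_real_)
  degenerate <- t$a + t$b == 0 || t$c + t$d == 0
  if (fit_or && !degenerate) {
    bl <- bivariate_logistic(pos, outcome, variable = sprintf("score_ge_%d", k))
    or <- bl$odds_ratio; ci <- bl$ci95; p <- bl$p_value; r2 <- bl$nagelkerke_r2
  }
  list(
    k = k, table = t,
    sensitivity = acc$sensitivity, specificity = acc$specificity,
    lr_pos = acc$lr_pos, lr_neg = acc$lr_neg,
    post_prob_pos = post_test_probability(pre_test, acc$lr_pos$estimate),
    post_prob_neg = post_test_probability(pre_test, acc$lr_neg$estimate),
    odds_ratio = or, or_ci95 = ci, p_value = p, nagelkerke_r2 = r2,
    degenerate = degenerate
  )
}

# Assemble the k = 1..K rule table from a score vector.
rule_table_from_scores <- function(score, outcome, pre_test, K = max(score),
                                   fit_or = TRUE,
                                   recommend_lr = 3, recommend_ci_ratio = 10) {
  rows <- lapply(seq_len(K), function(k)
    rule_row(score, outcome, k, pre_test, fit_or = fit_or))
  rec <- NA_integer_
  for (r in rows) {
    lr <- r$lr_pos
    if (is.finite(lr$estimate) && lr$estimate >= recommend_lr &&
        all(is.finite(lr$ci95)) && lr$ci95[1] > 0 &&
        lr$ci95[2] / lr$ci95[1] <= recommend_ci_ratio) {
      rec <- r$k
      break
    }
  }
  structure(
    list(rows = rows, K = K, pre_test = pre_test, recommended_k = rec,
         score_distribution = tabulate(score + 1L, nbins = K + 1L)),
    class = "rule_table"
  )
}

#' Build the cumulative risk-factor rule table
#'
#' Scores every respondent by their count of positive risk factors and,
#' for each threshold k = 1..K ("k or more of K factors"), computes the
#' 2x2 table against the outcome, sensitivity/specificity with Wilson CIs,
#' likelihood ratios with log-method CIs, Bayes post-test probabilities of
#' a positive and a negative finding, and the per-threshold logistic odds
#' ratio and Nagelkerke R-squared. The recommended "rule-in" threshold is
#' the smallest k whose LR+ is at least `recommend_lr` with a finite CI
#' whose upper/lower ratio is below `recommend_ci_ratio`.
#'
#' @param dataset complete data.frame of records.
#' @param factors binary risk-factor column names (K = their number).
#' @param pre_test pre-test probability; default is the sample outcome
#'   prevalence.
#' @param outcome outcome column name.
#' @param fit_or fit the per-threshold logistic model (default TRUE).
#' @param recommend_lr,recommend_ci_ratio recommendation policy knobs.
#' @return object of class `rule_table` (list of rows, one per k).
#' @export
build_rule_table <- function(dataset, factors, pre_test = NULL,
                             outcome = "pain_with_running", fit_or = TRUE,
                             recommend_lr = 3, recommend_ci_ratio = 10) {
  score <- score_respondents(dataset, factors)
  y <- dataset[[outcome]]
  if (is.null(pre_test)) pre_test <- mean(y)
  out <- rule_table_from_scores(score, y, pre_test, K = length(factors),
                                fit_or = fit_or, recommend_lr = recommend_lr,
                                recommend_ci_ratio = recommend_ci_ratio)
  out$factors <- factors
  out
}

#' Turn a rule table into a printable data.frame
#'
#' @param x a `rule_table`.
#' @param ... unused.
#' @param percent report sensitivity/specificity/post-test probabilities
#'   as percentages (default TRUE).
#' @return data.frame, one row per threshold k.
#' @export
as.data.frame.rule_table <- function(x, ..., percent = TRUE) {
  f <- if (percent) 100 else 1
  rows <- lapply(x$rows, function(r) {
    data.frame(
      k = r$k,
      tp = r$table$a, fp = r$table$b, fn = r$table$c, tn = r$table$d,
      sensitivity = f * r$sensitivity$estimate,
      sens_low = f * r$sensitivity$ci95[1], sens_high = f * r$sensitivity$ci95[2],
      specificity = f * r$specificity$estimate,
      spec_low = f * r$specificity$ci95[1], spec_high = f * r$specificity$ci95[2],
      lr_pos = r$lr_pos$estimate,
      lr_pos_low = r$lr_pos$ci95[1], lr_pos_high = r$lr_pos$ci95[2],
      lr_neg = r$lr_neg$estimate,
      lr_neg_low = r$lr_neg$ci95[1], lr_neg_high = r$lr_neg$ci95[2],
      post_prob_pos = f * r$post_prob_pos, post_prob_neg = f * r$post_prob_neg,
      odds_ratio = r$odds_ratio, or_low = r$or_ci95[1], or_high = r$or_ci95[2],
      p_value = r$p_value, nagelkerke_r2 = r$nagelkerke_r2,
      recommended = identical(r$k, x$recommended_k)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.rule_table <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Cumulative risk-factor rule (K = %d, pre-test %.1f%%)\n",
              x$K, 100 * x$pre_test))
  show <- df[, c("k", "sensitivity", "specificity", "lr_pos", "lr_neg",
                 "post_prob_pos", "post_prob_neg")]
  show[-1] <- lapply(show[-1], function(v) ifelse(is.finite(v), round(v, 2), v))
  print(show, row.names = FALSE)
  if (!is.na(x$recommended_k)) {
    cat(sprintf("Recommended rule-in threshold: %d or more factors\n", x$recommended_k))
  }
  invisible(x)
}
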