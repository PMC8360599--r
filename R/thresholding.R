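# ROC-derived dichotomization of continuous predictors: the discrimination
# threshold is the midpoint between the two consecutive observed unique
# values straddling the Youden-optimal operating point.

#' ROC midpoint cutpoint for a continuous predictor
#'
#' Scans every cut between consecutive observed unique values, computes
#' sensitivity and specificity for flagging each side, and selects the
#' operating point maximising Youden's J (`sens + spec - 1`;
#' `criterion = "closest01"` minimises the distance to the (0,1) ROC
#' corner instead). The returned threshold is the midpoint of the two
#' unique values straddling that operating point, so an estimated
#' threshold never equals an observed value. The flagged direction is the
#' side with the higher outcome rate; ties in the criterion are broken
#' toward the cut closest to the median of the outcome-positive values.
#'
#' @param values continuous predictor.
#' @param outcome binary outcome (0/1), both classes present.
#' @param variable name recorded on the cutpoint.
#' @param criterion `"youden"` (default) or `"closest01"`.
#' @return a list of class `cutpoint`: `variable`, `threshold`,
#'   `direction` (`"ge"` or `"le"`, the flagged side), `youden_j`,
#'   `source = "estimated"`.
#' @export
roc_cutpoint <- function(values, outcome, variable = deparse(substitute(values)),
                         criterion = c("youden", "closest01")) {
  criterion <- match.arg(criterion)
  keep <- !is.na(values) & !is.na(outcome)
  x <- as.numeric(values[keep]); y <- as.integer(outcome[keep])
  if (length(unique(y)) < 2L) stop("both outcome classes must be present", call. = FALSE)
  u <- sort(unique(x))
  if (length(u) < 2L) stop("predictor is constant; no discrimination threshold exists",
                           call. = FALSE)
  cuts <- (u[-length(u)] + u[-1L]) / 2
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  # sens/spec of the rule "x >= cut flags risk" at every candidate cut
  sens_ge <- vapply(cuts, function(cc) sum(x >= cc & y == 1L) / n1, numeric(1))
  spec_ge <- vapply(cuts, function(cc) sum(x < cc & y == 0L) / n0, numeric(1))
  j_ge <- sens_ge + spec_ge - 1
  score <- if (criterion == "youden") {
    abs(j_ge)  # the "le" rule at the same cut has J = -j_ge
  } else {
    # distance to the (0,1) corner of whichever direction is informative
    d_ge <- sqrt((1 - sens_ge)^2 + (1 - spec_ge)^2)
    d_le <- sqrt(sens_ge^2 + spec_ge^2)  # = distance for the flipped rule
    -pmin(d_ge, d_le)
  }
  best <- which(score == max(score))
  if (length(best) > 1L) {
    med1 <- stats::median(x[y == 1L])
    best <- best[which.min(abs(cuts[best] - med1))]
  }
  dir <- if (j_ge[best] >= 0) "ge" else "le"
  structure(
    list(variable = variable, threshold = cuts[best], direction = dir,
         youden_j = abs(j_ge[best]), source = "estimated"),
    class = "cutpoint"
  )
}

#' @export
print.cutpoint <- function(x, ...) {
  cat(sprintf("%s %s %s  (J = %.3f, %s)\n", x$variable,
              if (x$direction == "ge") ">=" else "<=",
              format(x$threshold), x$youden_j, x$source))
  invisible(x)
}

#' Published replication cutpoints
#'
#' The dichotomization thresholds reported for the five continuous survey
#' predictors: PAFS >= 19, EPDS >= 12.5, sleep <= 6.83 h, weekly mileage
#' >= 15.25 miles, first postpartum run >= 24.5 weeks. Shipped as a
#' packaged JSON file and returned as `cutpoint` objects with
#' `source = "replication_default"`.
#'
#' @return named list of `cutpoint` objects.
#' @export
replication_cutpoints <- function() {
  raw <- jsonlite::read_json(
    system.file("extdata", "replication_cutpoints.json", package = "postrun"),
    simplifyVector = TRUE, simplifyDataFrame = FALSE
  )
  lapply(raw, function(cp) {
    structure(
      list(variable = cp$variable, threshold = cp$threshold,
           direction = cp$direction, youden_j = NA_real_,
           source = "replication_default"),
      class = "cutpoint"
    )
  })
}

#' Add binary risk-indicator columns for a set of cutpoints
#'
#' Each cutpoint contributes one 0/1 column named `<variable>_bin`
#' (1 = flagged side per the cutpoint's direction, boundary values flagged
#' by `>=` / `<=`). Original columns are preserved; missing values stay
#' missing.
#'
#' @param dataset survey cohort data.frame.
#' @param cutpoints list of `cutpoint` objects.
#' @return the dataset with the added binary columns.
#' @export
apply_cutpoints <- function(dataset, cutpoints) {
  for (cp in cutpoints) {
    if (!cp$variable %in% names(dataset)) {
      stop("cutpoint refers to absent variable: ", cp$variable, call. = FALSE)
    }
    x <- dataset[[cp$variable]]
    flag <- if (cp$direction == "ge") x >= cp$threshold else x <= cp$threshold
    dataset[[paste0(cp$variable, "_bin")]] <- as.integer(flag)
  }
  dataset
}
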