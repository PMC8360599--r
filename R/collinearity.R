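# Pairwise association among retained nominal predictors with the
# |r| < 0.6 inclusion rule.

#' Phi coefficient of a 2x2 table
#'
#' `Phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`, signed in \[-1, 1\].
#'
#' @param t a [two_by_two()] or counts `c(a, b, c, d)`.
#' @return the signed Phi coefficient.
#' @export
phi_coefficient <- function(t) {
  t <- as_two_by_two(t)
  a <- t$a; b <- t$b; c_ <- t$c; d <- t$d
  den <- sqrt((a + b)) * sqrt((c_ + d)) * sqrt((a + c_)) * sqrt((b + d))
  if (den == 0) stop("Phi is undefined for a table with a zero margin", call. = FALSE)
  (a * d - b * c_) / den
}

#' Cramer's V of an r x c contingency table
#'
#' `V = sqrt(chi2 / (n (min(r, c) - 1)))`, in \[0, 1\]; for a 2x2 table V
#' equals |Phi|. Rows or columns with zero margins are dropped with a
#' warning.
#'
#' @param tab contingency table (matrix of counts).
#' @return Cramer's V.
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping zero-margin rows/columns from the contingency table",
            call. = FALSE)
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L || sum(tab) == 0) {
    stop("Cramer's V needs at least a 2x2 table with positive total", call. = FALSE)
  }
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  sqrt(unname(chi2) / (sum(tab) * (min(dim(tab)) - 1)))
}

#' Multicollinearity screen of retained predictors
#'
#' Computes every pairwise association among the retained predictors --
#' signed Phi for binary pairs, Cramer's V otherwise -- and flags pairs at
#' or above the cutoff. Of a flagged pair, the member with the larger
#' bivariate screening p-value is dropped (second-listed member when no
#' p-values are supplied). Pairs of dummies from the same one-hot group
#' (e.g. the delivery-type levels) are structurally negatively associated
#' and exempt from flagging.
#'
#' @param dataset data.frame holding the predictor columns.
#' @param variables retained predictor names (>= 2).
#' @param cutoff flagging threshold on |association| (default 0.6).
#' @param p_values optional named vector of bivariate p-values used to pick
#'   the dropped member of a flagged pair.
#' @param exempt_groups list of character vectors; pairs within a group are
#'   never flagged. Defaults to the delivery and runner-type dummy groups.
#' @return list of class `association_matrix`: `variables`, `coefficients`
#'   (symmetric, unit diagonal), `flagged_pairs` (data.frame), `admitted`
#'   (variables surviving the filter), `dropped`.
#' @export
collinearity_filter <- function(dataset, variables, cutoff = 0.6,
                                p_values = NULL,
                                exempt_groups = default_exempt_groups()) {
  stopifnot(length(variables) >= 2L)
  k <- length(variables)
  m <- diag(1, k)
  dimnames(m) <- list(variables, variables)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      xi <- dataset[[variables[i]]]
      xj <- dataset[[variables[j]]]
      keep <- !is.na(xi) & !is.na(xj)
      if (is_binary01(xi) && is_binary01(xj)) {
        tab <- tabulate_2x2(xi[keep], xj[keep])
        v <- tryCatch(phi_coefficient(tab), error = function(e) NA_real_)
      } else {
        v <- tryCatch(cramers_v(table(xi[keep], xj[keep])), error = function(e) NA_real_)
      }
      m[i, j] <- m[j, i] <- v
    }
  }
  same_group <- function(a, b) {
    any(vapply(exempt_groups, function(g) a %in% g && b %in% g, logical(1)))
  }
  flagged <- data.frame(var1 = character(0), var2 = character(0),
                        coefficient = numeric(0), stringsAsFactors = FALSE)
  dropped <- character(0)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (is.na(m[i, j]) || abs(m[i, j]) < cutoff) next
      if (same_group(variables[i], variables[j])) next
      flagged <- rbind(flagged, data.frame(
        var1 = variables[i], var2 = variables[j], coefficient = m[i, j],
        stringsAsFactors = FALSE
      ))
      pair <- c(variables[i], variables[j])
      alive <- setdiff(pair, dropped)
      if (length(alive) == 2L) {
        drop <- if (!is.null(p_values) && all(pair %in% names(p_values))) {
          pair[which.max(p_values[pair])]
        } else {
          pair[2L]
        }
        dropped <- c(dropped, drop)
      }
    }
  }
  structure(
    list(variables = variables, coefficients = m, flagged_pairs = flagged,
         admitted = setdiff(variables, dropped), dropped = dropped,
         cutoff = cutoff),
    class = "association_matrix"
  )
}

#' @rdname collinearity_filter
#' @export
default_exempt_groups <- function() {
  list(
    c("delivery_vaginal", "delivery_cesarean", "delivery_other"),
    c("runner_novice", "runner_recreational", "runner_elite")
  )
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("Pairwise Phi / Cramer's V among %d predictors (cutoff %.2f)\n",
              length(x$variables), x$cutoff))
  if (nrow(x$flagged_pairs) == 0L) {
    cat("No pairs flagged; all predictors admitted.\n")
  } else {
    cat(sprintf("%d pair(s) flagged; dropped: %s\n", nrow(x$flagged_pairs),
                paste(x$dropped, collapse = ", ")))
  }
  invisible(x)
}
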