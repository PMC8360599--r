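# Missing-data handling: Little's MCAR chi-square test on EM estimates of
# the mean and covariance, and single-pass regression-based multiple
# imputation pooled to one analysis dataset.

# Numeric coding of a survey cohort for the MCAR test: binaries stay 0/1,
# factors become k-1 treatment dummies, the ordinal sleep-interruption
# scale becomes its integer code. `id` is dropped.
cohort_numeric_block <- function(df, variables = NULL) {
  df <- df[, setdiff(names(df), "id"), drop = FALSE]
  if (!is.null(variables)) df <- df[, variables, drop = FALSE]
  cols <- list()
  for (v in names(df)) {
    x <- df[[v]]
    if (is.factor(x)) {
      lv <- levels(x)
      if (identical(v, "sleep_interruptions")) {
        cols[[v]] <- as.numeric(x) - 1
      } else {
        for (l in lv[-1L]) cols[[paste(v, l, sep = "_")]] <- as.numeric(x == l)
      }
    } else if (is.character(x)) {
      lv <- sort(unique(x[!is.na(x)]))
      for (l in lv[-1L]) cols[[paste(v, l, sep = "_")]] <- as.numeric(x == l)
    } else {
      cols[[v]] <- as.numeric(x)
    }
  }
  X <- do.call(cbind, cols)
  keep <- apply(X, 2L, function(col) stats::var(col, na.rm = TRUE) > 0)
  keep[is.na(keep)] <- FALSE
  if (!all(keep)) {
    warning("dropping zero-variance column(s) from the MCAR test: ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
  }
  X[, keep, drop = FALSE]
}

# EM estimates (ML, divisor n) of mean and covariance of a numeric matrix
# with missing values. Rows grouped by missingness pattern; standard
# conditional-normal E-step.
em_norm <- function(X, max_iter = 500L, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  miss <- is.na(X)
  X0 <- X
  for (j in seq_len(p)) X0[miss[, j], j] <- mean(X[, j], na.rm = TRUE)
  mu <- colMeans(X0)
  Sigma <- crossprod(sweep(X0, 2L, mu)) / n
  pat <- apply(miss, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)
  for (iter in seq_len(max_iter)) {
    s1 <- numeric(p)
    s2 <- matrix(0, p, p)
    for (rows in groups) {
      m <- miss[rows[1L], ]
      Xg <- X[rows, , drop = FALSE]
      if (!any(m)) {
        s1 <- s1 + colSums(Xg)
        s2 <- s2 + crossprod(Xg)
      } else {
        o <- !m
        B <- Sigma[m, o, drop = FALSE] %*% solve(Sigma[o, o, drop = FALSE])
        Xm <- matrix(mu[m], nrow = length(rows), ncol = sum(m), byrow = TRUE) +
          sweep(Xg[, o, drop = FALSE], 2L, mu[o]) %*% t(B)
        C <- Sigma[m, m, drop = FALSE] - B %*% Sigma[o, m, drop = FALSE]
        Xfill <- Xg
        Xfill[, m] <- Xm
        s1 <- s1 + colSums(Xfill)
        s2 <- s2 + crossprod(Xfill)
        s2[m, m] <- s2[m, m] + length(rows) * C
      }
    }
    mu_new <- s1 / n
    Sigma_new <- s2 / n - tcrossprod(mu_new)
    delta <- max(abs(mu_new - mu), abs(Sigma_new - Sigma))
    mu <- mu_new; Sigma <- Sigma_new
    if (delta < tol) break
  }
  list(mu = mu, Sigma = Sigma, iterations = iter)
}

#' Little's test of missing completely at random
#'
#' Computes Little's chi-square statistic
#' \eqn{d^2 = \sum_j m_j (\bar x_j - \hat\mu_j)' \hat\Sigma_j^{-1} (\bar x_j - \hat\mu_j)}
#' over the observed missingness patterns \eqn{j}, where \eqn{\bar x_j} is
#' the pattern mean over its observed variables and \eqn{\hat\mu},
#' \eqn{\hat\Sigma} are the EM (maximum-likelihood) grand estimates
#' restricted to those variables. Degrees of freedom are
#' \eqn{\sum_j p_j - p}. Binary survey items enter as 0/1 numerics and
#' factors as treatment dummies, a standard (and documented) approximation.
#'
#' The chi-square reference distribution assumes pattern means are
#' approximately normal. A handful of incomplete rows cannot carry that
#' approximation for a nearly constant indicator (a single row showing the
#' rare class of, say, a 97% item contributes an enormous Mahalanobis
#' term), which badly inflates the test's size. Indicator columns whose
#' minority share falls below `min_minority_share` are therefore excluded
#' by default and listed in the report.
#'
#' @param dataset survey cohort data.frame (may contain `NA` cells).
#' @param variables optional subset of columns to test.
#' @param min_minority_share skew guard for 0/1 columns (default 0.1; set
#'   to 0 to test every numeric-codeable column).
#' @return a list of class `missingness_report`: cell and case counts and
#'   percentages, `little_statistic`, `little_df`, `little_p`,
#'   `excluded_variables`, and `applicable` (FALSE for complete data,
#'   where the test degenerates to statistic 0 on 0 df).
#' @export
little_mcar_test <- function(dataset, variables = NULL,
                             min_minority_share = 0.1) {
  X <- cohort_numeric_block(dataset, variables)
  skewed <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    u <- unique(x[!is.na(x)])
    if (length(u) > 2L || !all(u %in% c(0, 1))) return(FALSE)
    p <- mean(x, na.rm = TRUE)
    min(p, 1 - p) < min_minority_share
  }, logical(1))
  excluded <- colnames(X)[skewed]
  X <- X[, !skewed, drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (p < 2L) stop("the MCAR test needs at least two numeric-codeable variables", call. = FALSE)
  miss <- is.na(X)
  body_cols <- setdiff(names(dataset), "id")
  n_cells <- sum(is.na(dataset[, body_cols, drop = FALSE]))
  n_cases <- sum(apply(is.na(dataset[, body_cols, drop = FALSE]), 1L, any))
  report <- list(
    n_missing_cells = n_cells,
    pct_missing_cells = 100 * n_cells / (n * length(body_cols)),
    n_incomplete_cases = n_cases,
    pct_incomplete_cases = 100 * n_cases / n
  )
  report$excluded_variables <- excluded
  if (!any(miss)) {
    report <- c(report, list(little_statistic = 0, little_df = 0L,
                             little_p = NA_real_, applicable = FALSE))
    return(structure(report, class = "missingness_report"))
  }
  if (all(rowSums(!miss) == 0L)) {
    stop("every row is completely missing; the MCAR test is undefined", call. = FALSE)
  }
  if (!any(colSums(miss) == 0L)) {
    stop("the MCAR test needs at least one completely observed variable", call. = FALSE)
  }
  est <- em_norm(X)
  pat <- apply(miss, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)
  d2 <- 0
  df <- 0L
  for (rows in groups) {
    o <- !miss[rows[1L], ]
    if (!any(o)) next
    xbar <- colMeans(X[rows, o, drop = FALSE])
    dev <- xbar - est$mu[o]
    So <- est$Sigma[o, o, drop = FALSE]
    quad <- tryCatch(
      drop(crossprod(dev, solve(So, dev))),
      error = function(e) {
        warning("singular pattern covariance; pattern pooled via pseudo-inverse",
                call. = FALSE)
        sv <- svd(So)
        pos <- sv$d > max(sv$d) * 1e-10
        drop(crossprod(dev, sv$v[, pos, drop = FALSE] %*%
                         ((t(sv$u[, pos, drop = FALSE]) %*% dev) / sv$d[pos])))
      }
    )
    d2 <- d2 + length(rows) * quad
    df <- df + sum(o)
  }
  df <- df - p
  report <- c(report, list(
    little_statistic = d2,
    little_df = as.integer(df),
    little_p = if (df > 0) stats::pchisq(d2, df, lower.tail = FALSE) else NA_real_,
    applicable = df > 0
  ))
  structure(report, class = "missingness_report")
}

#' @export
print.missingness_report <- function(x, ...) {
  cat(sprintf("Missing cells: %d (%.2f%%) in %d case(s) (%.2f%%)\n",
              x$n_missing_cells, x$pct_missing_cells,
              x$n_incomplete_cases, x$pct_incomplete_cases))
  if (!x$applicable) {
    cat("Little's MCAR test: not applicable (complete data)\n")
  } else {
    cat(sprintf("Little's MCAR test: chi-square %.3f on %d df, p = %.4f\n",
                x$little_statistic, x$little_df, x$little_p))
  }
  invisible(x)
}

#' Regression-based multiple imputation pooled to one dataset
#'
#' For each incomplete variable (in increasing order of missingness) a
#' regression on the completely observed covariates is fitted -- linear for
#' continuous, logistic for binary, multinomial for categorical -- and
#' imputations are drawn from the predictive distribution. The
#' `n_imputations` draws are pooled to a single dataset: continuous cells
#' by averaging (rounded when the observed column is integer-valued, and
#' clamped to the 0-30 instrument range for PAFS/EPDS), binary and
#' categorical cells by majority vote with a seeded tie-break.
#'
#' @param dataset survey cohort data.frame with `NA` cells.
#' @param n_imputations number of predictive draws pooled (default 5).
#' @param seed RNG seed for the draws and tie-breaks.
#' @param noise set `FALSE` to impute the predictive mean / most probable
#'   class instead of drawing (deterministic regression imputation).
#' @return the completed data.frame; imputed cells are listed in
#'   `attr(, "imputation_provenance")` (row, column, pooled value, and the
#'   individual draws).
#' @export
impute_pooled <- function(dataset, n_imputations = 5L, seed = 1L, noise = TRUE) {
  body_cols <- setdiff(names(dataset), "id")
  n_na <- vapply(dataset[body_cols], function(x) sum(is.na(x)), integer(1))
  if (all(n_na == 0L)) {
    attr(dataset, "imputation_provenance") <-
      data.frame(row = integer(0), column = character(0), value = character(0),
                 draws = character(0), stringsAsFactors = FALSE)
    return(dataset)
  }
  if (any(n_na > 0.5 * nrow(dataset))) {
    stop("refusing to impute variables missing in more than half the rows: ",
         paste(body_cols[n_na > 0.5 * nrow(dataset)], collapse = ", "), call. = FALSE)
  }
  incomplete <- body_cols[n_na > 0L]
  incomplete <- incomplete[order(n_na[incomplete])]
  complete <- setdiff(body_cols, incomplete)
  out <- dataset
  prov <- list()
  with_seed(stage_seed(seed, "imputation"), {
    for (v in incomplete) {
      idx <- which(is.na(dataset[[v]]))
      y <- dataset[[v]]
      draws <- impute_draws(y, dataset[complete], idx, n_imputations, noise)
      pooled <- pool_draws(y, draws)
      if (v %in% c("pafs_score", "epds_score")) {
        pooled <- pmin(pmax(pooled, 0), 30)
      } else if (v %in% c("age", "sleep_hours_avg", "weekly_mileage",
                          "weeks_to_first_run")) {
        pooled <- pmax(pooled, 0)
      }
      out[[v]][idx] <- pooled
      prov[[v]] <- data.frame(
        row = idx, column = v,
        value = as.character(pooled),
        draws = apply(matrix(as.character(draws), nrow = length(idx)), 1L,
                      paste, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  })
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(row = integer(0), column = character(0), value = character(0),
               draws = character(0), stringsAsFactors = FALSE)
  rownames(prov) <- NULL
  attr(out, "imputation_provenance") <- prov
  out
}

# Predictive draws (matrix: missing cells x imputations) for one variable.
impute_draws <- function(y, covars, idx, m, noise) {
  covars <- covars[, vapply(covars, function(x) length(unique(x)) > 1L, logical(1)),
                   drop = FALSE]
  k_idx <- length(idx)
  if (ncol(covars) == 0L) {
    warning("no complete covariates available; falling back to marginal draws",
            call. = FALSE)
    obs <- y[!is.na(y)]
    return(matrix(sample(obs, k_idx * m, replace = TRUE), nrow = k_idx))
  }
  fit_rows <- which(!is.na(y))
  dat <- data.frame(.y = if (is.character(y)) factor(y) else y, covars)
  new <- dat[idx, , drop = FALSE]
  if (is.factor(dat$.y)) {
    fit <- nnet::multinom(.y ~ ., data = dat[fit_rows, , drop = FALSE], trace = FALSE)
    pr <- stats::predict(fit, newdata = new, type = "probs")
    lv <- levels(dat$.y)
    pr <- matrix(pr, nrow = k_idx)
    if (ncol(pr) == 1L) pr <- cbind(1 - pr, pr)  # two-class multinom returns P(level 2)
    draws <- sapply(seq_len(m), function(k) {
      if (noise) {
        lv[apply(pr, 1L, function(p) sample.int(length(p), 1L, prob = p))]
      } else {
        lv[max.col(pr, ties.method = "first")]
      }
    })
  } else if (is_binary01(y)) {
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = dat[fit_rows, , drop = FALSE],
                 family = stats::binomial())
    )
    p <- stats::predict(fit, newdata = new, type = "response")
    draws <- sapply(seq_len(m), function(k) {
      if (noise) stats::rbinom(k_idx, 1L, p) else as.integer(p > 0.5)
    })
  } else {
    fit <- stats::lm(.y ~ ., data = dat[fit_rows, , drop = FALSE])
    mu <- stats::predict(fit, newdata = new)
    s <- summary(fit)$sigma
    if (!is.finite(s)) s <- 0
    draws <- sapply(seq_len(m), function(k) {
      if (noise) stats::rnorm(k_idx, mu, s) else mu
    })
  }
  matrix(draws, nrow = k_idx)
}

# Pool a draws matrix to one value per missing cell.
pool_draws <- function(y, draws) {
  draws <- matrix(draws, nrow = NROW(draws))
  if (is.factor(y) || is.character(y) || is_binary01(y)) {
    pooled <- apply(draws, 1L, function(d) {
      tab <- table(d)
      top <- names(tab)[tab == max(tab)]
      if (length(top) > 1L) top <- sample(top, 1L)  # seeded tie-break
      top
    })
    if (is.factor(y)) factor(pooled, levels = levels(y))
    else if (is_binary01(y)) as.integer(pooled)
    else pooled
  } else {
    pooled <- rowMeans(matrix(as.numeric(draws), nrow = nrow(draws)))
    obs <- y[!is.na(y)]
    if (all(obs == round(obs))) pooled <- round(pooled)
    pooled
  }
}
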