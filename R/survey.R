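# Survey data model: eligibility screening, respondent-flow accounting,
# CSV round-trip with a machine-readable data dictionary.

survey_levels <- list(
  delivery = c("vaginal", "cesarean", "other"),
  runner_type = c("novice", "recreational", "elite"),
  sleep_interruptions = c("0", "1", "2", "3", "4", "5", ">5"),
  covid_mileage_change = c("increased", "decreased", "no_change", "not_asked")
)

#' Screen one respondent against the survey inclusion criteria
#'
#' Inclusion requires age 18 or older, youngest child born within the past
#' 36 months, not currently pregnant, and running at least once per week --
#' or, for respondents not running weekly, pain as the reported limiting
#' factor.
#'
#' @param age years.
#' @param months_since_birth months since the youngest child's birth.
#' @param runs_per_week weekly running frequency (0 allowed).
#' @param currently_pregnant logical.
#' @param limitation_reason one of `"pain"`, `"time"`, `"other"`; required
#'   (and only consulted) when `runs_per_week` is 0.
#' @return a list of class `eligibility_result` with `eligible` (logical),
#'   `reasons` (character vector of every failed criterion, empty iff
#'   eligible) and `limited_by`.
#' @export
screen_eligibility <- function(age, months_since_birth, runs_per_week,
                               currently_pregnant, limitation_reason = NULL) {
  if (age < 0 || months_since_birth < 0 || runs_per_week < 0) {
    stop("age, months_since_birth and runs_per_week must be non-negative", call. = FALSE)
  }
  if (runs_per_week == 0 && is.null(limitation_reason)) {
    stop("limitation_reason is required when runs_per_week = 0", call. = FALSE)
  }
  reasons <- character(0)
  if (age < 18) reasons <- c(reasons, "age")
  if (months_since_birth > 36) reasons <- c(reasons, "postpartum_window")
  if (isTRUE(currently_pregnant)) reasons <- c(reasons, "pregnant")
  if (runs_per_week < 1 && !identical(limitation_reason, "pain")) {
    reasons <- c(reasons, "running_frequency")
  }
  structure(
    list(eligible = length(reasons) == 0L, reasons = reasons,
         limited_by = if (runs_per_week == 0) limitation_reason else NULL),
    class = "eligibility_result"
  )
}

#' @export
print.eligibility_result <- function(x, ...) {
  if (x$eligible) cat("eligible\n")
  else cat("ineligible:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Account for respondent flow through the survey
#'
#' Partitions initiated responses into ineligible, eligible non-completers,
#' and analysed (eligible completers), and checks conservation.
#'
#' @param responses data.frame with logical columns `eligible` and
#'   `completed`.
#' @return named list `initiated`, `ineligible`, `eligible_noncompleters`,
#'   `analyzed`.
#' @export
account_flow <- function(responses) {
  if (nrow(responses) == 0L) {
    return(list(initiated = 0L, ineligible = 0L,
                eligible_noncompleters = 0L, analyzed = 0L))
  }
  stopifnot(all(c("eligible", "completed") %in% names(responses)))
  if (anyNA(responses$eligible) || anyNA(responses$completed)) {
    stop("every response must carry eligibility and completion tags", call. = FALSE)
  }
  if (any(!responses$eligible & responses$completed)) {
    stop("inconsistent tags: ineligible respondents cannot complete the survey",
         call. = FALSE)
  }
  out <- list(
    initiated = nrow(responses),
    ineligible = sum(!responses$eligible),
    eligible_noncompleters = sum(responses$eligible & !responses$completed),
    analyzed = sum(responses$eligible & responses$completed)
  )
  stopifnot(out$initiated == out$ineligible + out$eligible_noncompleters + out$analyzed)
  lapply(out, as.integer)
}

#' Respondent flow fixture matching the published study
#'
#' Builds in code the tagged response table whose flow accounting
#' reproduces the published participant flow: 826 initiated, 262
#' ineligible, 26 eligible non-completers, 538 analysed.
#' @return data.frame with `eligible` and `completed` columns.
#' @export
study_flow_fixture <- function() {
  data.frame(
    eligible = rep(c(FALSE, TRUE, TRUE), c(262L, 26L, 538L)),
    completed = rep(c(FALSE, FALSE, TRUE), c(262L, 26L, 538L))
  )
}

#' The packaged survey data dictionary
#'
#' @return a list (parsed from the packaged JSON) defining every survey
#'   column: type, unit, levels, and instrument bounds.
#' @export
data_dictionary <- function() {
  jsonlite::read_json(
    system.file("extdata", "data_dictionary.json", package = "postrun"),
    simplifyVector = TRUE, simplifyDataFrame = FALSE
  )
}

validate_cohort_frame <- function(df) {
  if (!"pain_with_running" %in% names(df)) {
    stop("mandatory outcome column 'pain_with_running' is missing", call. = FALSE)
  }
  for (v in names(survey_levels)) {
    if (!v %in% names(df)) next
    x <- df[[v]]
    lv <- if (is.factor(x)) levels(x) else unique(as.character(x[!is.na(x)]))
    bad <- setdiff(lv, survey_levels[[v]])
    if (length(bad)) {
      rows <- which(as.character(df[[v]]) %in% bad)[1L]
      stop(sprintf("unknown level '%s' in column '%s' (first at row %d)",
                   bad[1L], v, rows), call. = FALSE)
    }
    df[[v]] <- factor(as.character(x), levels = survey_levels[[v]])
  }
  if ("epds_score" %in% names(df)) {
    bad <- which(!is.na(df$epds_score) & (df$epds_score < 0 | df$epds_score > 30))
    if (length(bad)) {
      stop(sprintf("epds_score outside the 0-30 instrument range at row %d", bad[1L]),
           call. = FALSE)
    }
  }
  for (v in c("age", "pafs_score", "sleep_hours_avg", "weekly_mileage",
              "weeks_to_first_run")) {
    if (!v %in% names(df)) next
    bad <- which(!is.na(df[[v]]) & df[[v]] < 0)
    if (length(bad)) {
      stop(sprintf("negative %s at row %d", v, bad[1L]), call. = FALSE)
    }
  }
  # coding rule: no reported fatigue implies PAFS 0
  if (all(c("pafs_score", "fatigue_present") %in% names(df))) {
    inc <- which(!is.na(df$fatigue_present) & df$fatigue_present == 0L &
                   !is.na(df$pafs_score) & df$pafs_score != 0)
    if (length(inc)) {
      warning(sprintf("%d row(s) report no fatigue but a nonzero PAFS score; coerced to 0",
                      length(inc)), call. = FALSE)
      df$pafs_score[inc] <- 0
    }
  }
  df
}

#' Read / write survey cohorts as CSV
#'
#' CSV I/O conforming to the packaged data dictionary: UTF-8, header row,
#' empty string as the missing-value token. `read_cohort()` validates
#' categorical levels, the EPDS instrument range, non-negativity of
#' continuous fields, and the PAFS/fatigue coding rule (incoherent PAFS
#' values are coerced to 0 with a warning). Unknown columns are preserved.
#'
#' @param path CSV file path.
#' @param records cohort data.frame.
#' @return `read_cohort()`: validated data.frame; `write_cohort()`: the
#'   path, invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        check.names = FALSE)
  validate_cohort_frame(df)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(records, path) {
  out <- records
  for (v in names(out)) if (is.factor(out[[v]])) out[[v]] <- as.character(out[[v]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
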