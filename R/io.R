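# CSV readers/writers for waiting lists, calendars and schedules, plus run
# configuration loading. Dates are integer day offsets from the horizon
# start (day 1); no calendar-date arithmetic is performed.

WAITLIST_REQUIRED <- c("id", "sex", "age_band", "bmi_band", "priority",
                       "comorbidity_score", "respiratory", "cardiovascular",
                       "diabetes", "prior_pelvic_surgery",
                       "past_failed_colonoscopy", "failed_reason",
                       "procedure_type", "indication", "endoscopist_type",
                       "admission_date", "due_date")

check_categories <- function(values, allowed, column) {
  bad <- which(!values %in% allowed)
  if (length(bad)) {
    stop(sprintf("invalid %s value(s) %s at row(s) %s", column,
                 paste(unique(values[bad]), collapse = ", "),
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
}

#' Read a waiting list from CSV
#'
#' Validates the schema and every categorical value, reporting offending
#' row numbers. A blank or missing BMI band is mapped to the explicit
#' `"missing"` category; optional columns (designated endoscopist, actual
#' and predicted minutes) are filled with `NA` when absent.
#'
#' @param path CSV file path.
#' @return A waiting-list data frame.
#' @export
read_waitlist <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(WAITLIST_REQUIRED, names(df))
  if (length(missing_cols)) {
    stop(sprintf("waitlist file is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$bmi_band[is.na(df$bmi_band) | df$bmi_band == ""] <- "missing"
  check_categories(df$sex, c("male", "female"), "sex")
  check_categories(df$age_band, AGE_BANDS, "age_band")
  check_categories(df$bmi_band, BMI_BANDS, "bmi_band")
  check_categories(df$priority, PRIORITY_LEVELS, "priority")
  check_categories(df$failed_reason, FAILED_REASONS, "failed_reason")
  check_categories(df$procedure_type, PROCEDURE_TYPES, "procedure_type")
  check_categories(df$indication, INDICATIONS, "indication")
  check_categories(df$endoscopist_type, ENDOSCOPIST_TYPES, "endoscopist_type")
  if (any(df$admission_date > df$due_date, na.rm = TRUE)) {
    stop("admission_date later than due_date at row(s): ",
         paste(which(df$admission_date > df$due_date), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("respiratory", "cardiovascular", "diabetes",
                "prior_pelvic_surgery", "past_failed_colonoscopy")) {
    df[[col]] <- as.logical(df[[col]])
  }
  if (is.null(df$designated_endoscopist)) {
    df$designated_endoscopist <- NA_character_
  } else {
    df$designated_endoscopist[df$designated_endoscopist == ""] <- NA_character_
  }
  for (col in c("actual_minutes", "predicted_minutes", "appointment_minutes")) {
    df[[col]] <- if (is.null(df[[col]])) NA_real_ else as.numeric(df[[col]])
  }
  bad_reason <- xor(df$past_failed_colonoscopy, df$failed_reason != "none")
  if (any(bad_reason)) {
    stop("failed_reason must be 'none' exactly when past_failed_colonoscopy is FALSE; row(s): ",
         paste(which(bad_reason), collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a waiting list to CSV
#'
#' @param cohort waiting-list data frame.
#' @param path output file.
#' @param seed optional seed echoed as a header comment.
#' @return Invisibly, `path`.
#' @export
write_waitlist <- function(cohort, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' Read a capacity calendar from CSV
#'
#' Expects columns `endoscopist_id`, `day`, `block_minutes`; a missing
#' (endoscopist, day) pair means zero minutes.
#'
#' @param path CSV file path.
#' @return Calendar data frame.
#' @export
read_calendar <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("endoscopist_id", "day", "block_minutes")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("calendar file is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (any(df$block_minutes < 0)) {
    stop("block_minutes must be nonnegative", call. = FALSE)
  }
  df$day <- as.integer(df$day)
  df
}

#' Write a capacity calendar to CSV
#' @param calendar calendar data frame.
#' @inheritParams write_waitlist
#' @export
write_calendar <- function(calendar, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  write.csv(calendar, con, row.names = FALSE)
  invisible(path)
}

#' Read an endoscopist roster from CSV
#'
#' Expects columns `id`, `accepts_non_nominative` and
#' `compatible_procedures` (semicolon-separated procedure types); a
#' `specialty` column is optional.
#'
#' @param path CSV file path.
#' @return Roster data frame.
#' @export
read_roster <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "accepts_non_nominative", "compatible_procedures")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("roster file is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$accepts_non_nominative <- as.logical(df$accepts_non_nominative)
  procs <- unique(unlist(strsplit(df$compatible_procedures, ";", fixed = TRUE)))
  check_categories(procs, PROCEDURE_TYPES, "compatible_procedures")
  if (is.null(df$specialty)) df$specialty <- "gastrointestinal"
  df
}

#' Write an endoscopist roster to CSV
#' @param roster roster data frame.
#' @inheritParams write_waitlist
#' @export
write_roster <- function(roster, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  write.csv(roster, con, row.names = FALSE)
  invisible(path)
}

#' Write a schedule to CSV
#' @param schedule an `endo_schedule`.
#' @inheritParams write_waitlist
#' @export
write_schedule <- function(schedule, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# policy: %s", attr(schedule, "policy_label")), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  write.csv(as.data.frame(schedule), con, row.names = FALSE)
  invisible(path)
}

#' Read a schedule from CSV
#' @param path CSV file path.
#' @return An `endo_schedule`.
#' @export
read_schedule <- function(path) {
  first <- readLines(path, n = 1L)
  policy <- if (startsWith(first, "# policy:")) {
    trimws(sub("# policy:", "", first, fixed = TRUE))
  } else "unknown"
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  df$day <- as.integer(df$day)
  new_schedule(df, policy_label = policy)
}

#' Load a run configuration from JSON or YAML
#'
#' @param path configuration file; format chosen by extension
#'   (`.json`, `.yml`/`.yaml`).
#' @return Named list of configuration values.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write a metrics report to JSON
#' @param report a `metrics_report`.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
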