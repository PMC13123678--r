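#' Construct a schedule object
#'
#' A schedule is a data frame of assignments, one row per scheduled patient,
#' with columns `patient_id`, `endoscopist_id`, `day`, `start_minute` and
#' `planned_minutes`, carrying the producing policy as an attribute.
#'
#' @param assignments data frame with the five assignment columns.
#' @param policy_label character scalar naming the policy that produced it.
#' @return An object of class `endo_schedule`.
#' @export
new_schedule <- function(assignments, policy_label = "unknown") {
  cols <- c("patient_id", "endoscopist_id", "day", "start_minute",
            "planned_minutes")
  if (nrow(assignments) == 0L) {
    assignments <- data.frame(patient_id = character(),
                              endoscopist_id = character(),
                              day = integer(), start_minute = numeric(),
                              planned_minutes = numeric())
  }
  stopifnot(all(cols %in% names(assignments)))
  if (anyDuplicated(assignments$patient_id)) {
    stop("a patient appears more than once in the schedule", call. = FALSE)
  }
  assignments <- assignments[cols]
  rownames(assignments) <- NULL
  structure(assignments,
            policy_label = policy_label,
            class = c("endo_schedule", "data.frame"))
}

#' @export
print.endo_schedule <- function(x, ...) {
  cat(sprintf("<endo_schedule> policy = %s, %d assignments\n",
              attr(x, "policy_label"), nrow(x)))
  print(as.data.frame(head(x, 10L)))
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Days a scheduled patient is past the recommended due date
#'
#' Lateness (overdue time) is the number of days between the scheduled day
#' and the patient's due date, clamped at zero: being seen early never counts
#' as negative lateness.
#'
#' @param schedule an `endo_schedule`.
#' @param cohort the waiting-list data frame the schedule was built from.
#' @param patient_id one or more patient identifiers; all must be scheduled.
#' @return Integer vector of nonnegative overdue days.
#' @export
lateness_days <- function(schedule, cohort, patient_id) {
  idx <- match(patient_id, schedule$patient_id)
  if (anyNA(idx)) {
    stop(sprintf("patient(s) not in schedule: %s",
                 paste(patient_id[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  due <- cohort$due_date[match(patient_id, cohort$id)]
  if (anyNA(due)) stop("patient(s) missing from cohort", call. = FALSE)
  pmax(0L, as.integer(schedule$day[idx] - due))
}

#' Overtime and earliness of one endoscopist room-day
#'
#' Evaluation is against realized appointment lengths (actual procedure
#' minutes plus the buffer), not the planned minutes used to build the
#' schedule: the planning policy may over- or under-book a day relative to
#' its operational time budget.
#'
#' @param schedule an `endo_schedule`.
#' @param cohort waiting-list data frame with `actual_minutes`.
#' @param endoscopist_id,day the room-day to evaluate.
#' @param budget_minutes daily operational time budget (default 390).
#' @param buffer_minutes turnover buffer added to each procedure.
#' @return Named numeric vector `c(overtime, earliness)`; at most one of the
#'   two components is positive.
#' @export
room_day_balance <- function(schedule, cohort, endoscopist_id, day,
                             budget_minutes = DEFAULT_BUDGET_MINUTES,
                             buffer_minutes = DEFAULT_BUFFER_MINUTES) {
  stopifnot(budget_minutes > 0)
  sel <- schedule$endoscopist_id == endoscopist_id & schedule$day == day
  ids <- schedule$patient_id[sel]
  actual <- cohort$actual_minutes[match(ids, cohort$id)]
  if (anyNA(actual)) {
    stop("scheduled patient(s) lack actual procedure minutes", call. = FALSE)
  }
  s <- sum(actual + buffer_minutes)
  c(overtime = max(0, s - budget_minutes),
    earliness = max(0, budget_minutes - s))
}

#' Aggregate a schedule into a metrics report
#'
#' Computes scheduled counts (overall and per priority class), average
#' overdue days among scheduled patients, average waiting days (scheduled
#' day minus admission date, an alternative delay metric), and total and
#' per-day-per-room overtime and earliness against the daily time budget.
#' One "room" is one endoscopist's daily block stream, so the number of
#' room-days equals the number of calendar entries with positive minutes.
#'
#' @inheritParams room_day_balance
#' @param calendar capacity calendar data frame
#'   (`endoscopist_id`, `day`, `block_minutes`).
#' @return A `metrics_report` list.
#' @export
build_report <- function(schedule, cohort, calendar,
                         budget_minutes = DEFAULT_BUDGET_MINUTES,
                         buffer_minutes = DEFAULT_BUFFER_MINUTES) {
  cal <- calendar[calendar$block_minutes > 0, , drop = FALSE]
  n_room_days <- nrow(cal)
  if (n_room_days == 0L) {
    stop("degenerate configuration: calendar has no room-days", call. = FALSE)
  }
  sched_ids <- schedule$patient_id
  pri <- factor(cohort$priority[match(sched_ids, cohort$id)],
                levels = PRIORITY_LEVELS)
  late <- if (length(sched_ids)) {
    lateness_days(schedule, cohort, sched_ids)
  } else integer()
  adm <- cohort$admission_date[match(sched_ids, cohort$id)]
  wait <- if (length(sched_ids)) as.integer(schedule$day - adm) else integer()

  n_by_class <- as.integer(table(pri))
  names(n_by_class) <- PRIORITY_LEVELS
  avg_by_class <- vapply(PRIORITY_LEVELS, function(cl) {
    v <- late[which(pri == cl)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))

  ot <- numeric(n_room_days)
  ea <- numeric(n_room_days)
  for (i in seq_len(n_room_days)) {
    b <- room_day_balance(schedule, cohort, cal$endoscopist_id[i], cal$day[i],
                          budget_minutes, buffer_minutes)
    ot[i] <- b[["overtime"]]
    ea[i] <- b[["earliness"]]
  }

  structure(list(
    policy = attr(schedule, "policy_label") %||% "unknown",
    n_scheduled_total = length(sched_ids),
    n_scheduled_by_class = n_by_class,
    n_unscheduled = nrow(cohort) - length(sched_ids),
    avg_late_days_total = if (length(late)) mean(late) else NA_real_,
    avg_late_days_by_class = avg_by_class,
    avg_wait_days_total = if (length(wait)) mean(wait) else NA_real_,
    total_overtime_minutes = sum(ot),
    avg_overtime_per_day_room = sum(ot) / n_room_days,
    total_earliness_minutes = sum(ea),
    avg_earliness_per_day_room = sum(ea) / n_room_days,
    n_room_days = n_room_days,
    budget_minutes = budget_minutes
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> policy = %s\n", x$policy))
  cat(sprintf("  scheduled %d (unscheduled %d); avg late %.2f d; avg wait %.2f d\n",
              x$n_scheduled_total, x$n_unscheduled,
              x$avg_late_days_total, x$avg_wait_days_total))
  cat(sprintf("  overtime %.0f min (%.2f/day/room); earliness %.0f min (%.2f/day/room)\n",
              x$total_overtime_minutes, x$avg_overtime_per_day_room,
              x$total_earliness_minutes, x$avg_earliness_per_day_room))
  invisible(x)
}

#' Check a schedule against the structural feasibility rules
#'
#' Verifies that every patient appears at most once, every assignment uses a
#' compatible (and, for non-nominative patients, accepting) endoscopist,
#' planned minutes per room-day respect the calendar block, and planned
#' appointments of one endoscopist never overlap within a day.
#'
#' @inheritParams build_report
#' @param roster endoscopist roster data frame.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_schedule <- function(schedule, cohort, roster, calendar) {
  if (anyDuplicated(schedule$patient_id)) {
    stop("patient assigned more than once", call. = FALSE)
  }
  if (nrow(schedule) == 0L) return(invisible(TRUE))
  ci <- match(schedule$patient_id, cohort$id)
  if (anyNA(ci)) stop("scheduled patient not in cohort", call. = FALSE)
  ri <- match(schedule$endoscopist_id, roster$id)
  if (anyNA(ri)) stop("assignment to unknown endoscopist", call. = FALSE)
  proc <- cohort$procedure_type[ci]
  for (k in seq_len(nrow(schedule))) {
    allowed <- eligible_endoscopists(cohort[ci[k], , drop = FALSE], roster)
    if (!schedule$endoscopist_id[k] %in% allowed) {
      stop(sprintf("patient %s assigned outside its eligible endoscopist set",
                   schedule$patient_id[k]), call. = FALSE)
    }
  }
  key <- paste(schedule$endoscopist_id, schedule$day)
  cal_key <- paste(calendar$endoscopist_id, calendar$day)
  cap <- calendar$block_minutes[match(key, cal_key)]
  cap[is.na(cap)] <- 0
  load <- tapply(schedule$planned_minutes, key, sum)
  capk <- tapply(cap, key, max)
  if (any(load > capk[names(load)] + 1e-9)) {
    stop("planned minutes exceed a room-day capacity block", call. = FALSE)
  }
  # no planned-time overlap within a room-day
  for (k in unique(key)) {
    rows <- schedule[key == k, , drop = FALSE]
    rows <- rows[order(rows$start_minute), , drop = FALSE]
    if (nrow(rows) > 1L) {
      ends <- rows$start_minute + rows$planned_minutes
      if (any(rows$start_minute[-1L] < ends[-nrow(rows)] - 1e-9)) {
        stop("overlapping planned appointments in a room-day", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# Endoscopists allowed for one patient: the designated endoscopist when the
# request is nominative, otherwise every accepting provider whose procedure
# set covers the request.
eligible_endoscopists <- function(patient, roster) {
  proc <- as.character(patient$procedure_type)
  compat <- vapply(strsplit(roster$compatible_procedures, ";", fixed = TRUE),
                   function(s) proc %in% s, logical(1))
  des <- patient$designated_endoscopist
  if (!is.null(des) && !is.na(des) && nzchar(des)) {
    return(roster$id[compat & roster$id == des])
  }
  roster$id[compat & roster$accepts_non_nominative]
}
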