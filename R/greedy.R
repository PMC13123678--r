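#' Sort a waiting list by priority, urgency and duration
#'
#' Produces the global waiting list order used by the greedy policy:
#' (1) descending priority (P2 before P3 ... before SURV), (2) ascending
#' remaining time to the due date, (3) descending planned appointment
#' length, with admission date then patient id as deterministic final
#' tie-breaks. Planned appointment minutes are filled from the mode first:
#' a flat slot in fixed mode, prediction plus buffer in predictive mode.
#'
#' @param cohort waiting-list data frame; predictive mode requires
#'   `predicted_minutes` to be populated.
#' @param mode `"fixed"` or `"predictive"`.
#' @param buffer_minutes,fixed_minutes appointment-length conventions.
#' @return The cohort reordered, with `appointment_minutes` filled and the
#'   mode recorded as an attribute.
#' @export
sort_waiting_list <- function(cohort, mode = c("fixed", "predictive"),
                              buffer_minutes = DEFAULT_BUFFER_MINUTES,
                              fixed_minutes = DEFAULT_FIXED_SLOT_MINUTES) {
  mode <- match.arg(mode)
  cohort$appointment_minutes <- appointment_duration(
    if (mode == "fixed") rep(1, nrow(cohort)) else cohort$predicted_minutes,
    mode = if (mode == "fixed") "fixed" else "predictive",
    buffer_minutes = buffer_minutes, fixed_minutes = fixed_minutes)
  ord <- order(match(cohort$priority, PRIORITY_LEVELS),
               cohort$due_date,
               -cohort$appointment_minutes,
               cohort$admission_date,
               cohort$id)
  out <- cohort[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

#' Greedy list scheduling over the sorted waiting list
#'
#' Patients are processed in waiting-list order. A nominative patient goes
#' to the earliest feasible day of their designated endoscopist; a
#' non-nominative patient goes to the accepting, compatible endoscopist
#' with the earliest feasible opening (ties: most remaining minutes on that
#' day, then roster order). Appointments are packed back-to-back from
#' minute 0, so in fixed mode the schedule falls on the conventional
#' 30-minute grid as a consequence of the flat durations. A patient who
#' fits in no remaining room-day is left unscheduled and processing
#' continues; planned minutes never exceed a room-day's block.
#'
#' @param waitlist output of [sort_waiting_list()].
#' @param roster,calendar provider roster and capacity calendar.
#' @return An `endo_schedule`; unscheduled patient ids are attached as the
#'   `unscheduled` attribute.
#' @export
schedule_greedy <- function(waitlist, roster, calendar) {
  mode <- attr(waitlist, "mode")
  if (is.null(mode) || anyNA(waitlist$appointment_minutes)) {
    stop("waitlist must come from sort_waiting_list()", call. = FALSE)
  }
  days <- sort(unique(calendar$day))
  res <- matrix(0, nrow = nrow(roster), ncol = length(days),
                dimnames = list(roster$id, days))
  block <- res
  idx <- cbind(match(calendar$endoscopist_id, roster$id),
               match(calendar$day, days))
  res[idx] <- calendar$block_minutes
  block[idx] <- calendar$block_minutes

  non_nom <- is.na(waitlist$designated_endoscopist)
  if (any(non_nom) && !any(roster$accepts_non_nominative)) {
    warning("no endoscopist accepts non-nominative patients; ",
            "those patients are left unscheduled", call. = FALSE)
  }

  n <- nrow(waitlist)
  out_p <- character(n); out_e <- character(n)
  out_d <- integer(n); out_s <- numeric(n); out_m <- numeric(n)
  k <- 0L
  for (i in seq_len(n)) {
    planned <- waitlist$appointment_minutes[i]
    cand <- eligible_endoscopists(waitlist[i, , drop = FALSE], roster)
    if (!length(cand)) next
    ci <- match(cand, roster$id)
    # earliest feasible day per candidate (0 = none)
    first_day <- vapply(ci, function(e) {
      d <- which(res[e, ] >= planned - 1e-9)
      if (length(d)) d[1L] else 0L
    }, integer(1))
    ok <- first_day > 0L
    if (!any(ok)) next
    dmin <- min(first_day[ok])
    pool <- ci[ok & first_day == dmin]
    e <- pool[which.max(res[pool, dmin])]
    k <- k + 1L
    out_p[k] <- waitlist$id[i]
    out_e[k] <- roster$id[e]
    out_d[k] <- days[dmin]
    out_s[k] <- block[e, dmin] - res[e, dmin]
    out_m[k] <- planned
    res[e, dmin] <- res[e, dmin] - planned
  }
  assigned <- seq_len(k)
  sched <- new_schedule(
    data.frame(patient_id = out_p[assigned], endoscopist_id = out_e[assigned],
               day = out_d[assigned], start_minute = out_s[assigned],
               planned_minutes = out_m[assigned], stringsAsFactors = FALSE),
    policy_label = if (mode == "fixed") "fixed30-greedy" else "predictive-greedy")
  attr(sched, "unscheduled") <- setdiff(waitlist$id, out_p[assigned])
  sched
}
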