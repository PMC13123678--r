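test_that("lateness is scheduled day minus due date, clamped at zero", {
  cohort <- make_patients(3, due_date = c(5L, 2L, 10L))
  sched <- new_schedule(data.frame(
    patient_id = cohort$id, endoscopist_id = "E01",
    day = c(5L, 9L, 3L), start_minute = c(0, 30, 60), planned_minutes = 30))
  expect_identical(lateness_days(sched, cohort, "P001"), 0L)
  expect_identical(lateness_days(sched, cohort, "P002"), 7L)
  expect_identical(lateness_days(sched, cohort, "P003"), 0L)
  expect_error(lateness_days(sched, cohort, "P999"), "not in schedule")
})

test_that("lateness is monotone nondecreasing in the scheduled day", {
  cohort <- make_patients(1, due_date = 4L)
  vals <- vapply(1:12, function(d) {
    sched <- new_schedule(data.frame(patient_id = "P001",
                                     endoscopist_id = "E01", day = d,
                                     start_minute = 0, planned_minutes = 30))
    lateness_days(sched, cohort, "P001")
  }, integer(1))
  expect_true(all(diff(vals) >= 0L))
})

test_that("room-day balance splits budget deviation into overtime xor earliness", {
  budget <- 390
  cases <- list(list(actual = rep(15, 13), expect = c(0, 0)),       # s = 390
                list(actual = c(rep(15, 12), 35), expect = c(20, 0)))# s = 410
  for (cs in cases) {
    n <- length(cs$actual)
    cohort <- make_patients(n, actual_minutes = cs$actual)
    sched <- new_schedule(data.frame(
      patient_id = cohort$id, endoscopist_id = "E01", day = 1L,
      start_minute = cumsum(c(0, cs$actual[-n] + 15)),
      planned_minutes = cs$actual + 15))
    b <- room_day_balance(sched, cohort, "E01", 1L, budget)
    expect_equal(unname(b), cs$expect)
  }
  # 13 appointments whose realized minutes sum to 366: direct summation
  set.seed(4)
  proc <- runif(13, 5, 30)
  proc <- proc * (366 - 13 * 15) / sum(proc)   # appointment = proc + 15
  stopifnot(abs(sum(proc + 15) - 366) < 1e-9)
  cohort <- make_patients(13, actual_minutes = proc)
  sched <- new_schedule(data.frame(
    patient_id = cohort$id, endoscopist_id = "E01", day = 1L,
    start_minute = cumsum(c(0, proc[-13] + 15)), planned_minutes = proc + 15))
  expect_equal(unname(room_day_balance(sched, cohort, "E01", 1L, budget)),
               c(0, 24))
  # empty room-day
  empty <- new_schedule(data.frame(patient_id = character(),
                                   endoscopist_id = character(),
                                   day = integer(), start_minute = numeric(),
                                   planned_minutes = numeric()))
  expect_equal(unname(room_day_balance(empty, cohort, "E01", 1L, budget)),
               c(0, budget))
})

test_that("report aggregation matches direct arithmetic and flags degenerate calendars", {
  unit <- make_unit(2, 4)
  set.seed(11)
  cohort <- make_patients(40,
                          priority = sample(c("P2", "P3", "SURV"), 40, TRUE),
                          due_date = sample(-3:8, 40, TRUE),
                          actual_minutes = runif(40, 5, 40))
  cohort$predicted_minutes <- cohort$actual_minutes
  wl <- sort_waiting_list(cohort, "predictive")
  sched <- schedule_greedy(wl, unit$roster, unit$calendar)
  rep <- build_report(sched, cohort, unit$calendar)

  expect_equal(sum(rep$n_scheduled_by_class), rep$n_scheduled_total)
  expect_equal(rep$n_scheduled_total + rep$n_unscheduled, nrow(cohort))
  expect_equal(rep$avg_overtime_per_day_room,
               rep$total_overtime_minutes / rep$n_room_days)
  expect_equal(rep$avg_earliness_per_day_room,
               rep$total_earliness_minutes / rep$n_room_days)
  # per room-day: overtime x earliness = 0 and their difference is the
  # budget shortfall, exactly
  for (i in seq_len(nrow(unit$calendar))) {
    b <- room_day_balance(sched, cohort, unit$calendar$endoscopist_id[i],
                          unit$calendar$day[i])
    ids <- sched$patient_id[sched$endoscopist_id ==
                              unit$calendar$endoscopist_id[i] &
                              sched$day == unit$calendar$day[i]]
    s <- sum(cohort$actual_minutes[match(ids, cohort$id)] + 15)
    expect_equal(b[["overtime"]] * b[["earliness"]], 0)
    expect_equal(b[["earliness"]] - b[["overtime"]], 390 - s)
  }

  empty <- new_schedule(data.frame(patient_id = character(),
                                   endoscopist_id = character(),
                                   day = integer(), start_minute = numeric(),
                                   planned_minutes = numeric()))
  rep0 <- build_report(empty, cohort, unit$calendar)
  expect_equal(rep0$n_scheduled_total, 0L)
  expect_equal(rep0$total_earliness_minutes, nrow(unit$calendar) * 390)

  cal0 <- unit$calendar
  cal0$block_minutes <- 0
  expect_error(build_report(sched, cohort, cal0), "degenerate")
})

test_that("schedule validation rejects structural violations", {
  unit <- make_unit(1, 1, block = 60)
  cohort <- make_patients(2, appointment_minutes = 40)
  dup <- data.frame(patient_id = c("P001", "P001"), endoscopist_id = "E01",
                    day = 1L, start_minute = c(0, 40), planned_minutes = 40)
  expect_error(new_schedule(dup), "more than once")
  over <- new_schedule(data.frame(patient_id = c("P001", "P002"),
                                  endoscopist_id = "E01", day = 1L,
                                  start_minute = c(0, 40),
                                  planned_minutes = 40))
  expect_error(validate_schedule(over, cohort, unit$roster, unit$calendar),
               "capacity")
  nom <- make_patients(1, designated_endoscopist = "E99")
  bad <- new_schedule(data.frame(patient_id = "P001", endoscopist_id = "E01",
                                 day = 1L, start_minute = 0,
                                 planned_minutes = 30))
  expect_error(validate_schedule(bad, nom, unit$roster, unit$calendar),
               "eligible")
})
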