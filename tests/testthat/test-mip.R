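test_that("instance construction honours nominative sets and the weight condition", {
  unit <- make_unit(3, 2)
  nom <- make_patients(1, designated_endoscopist = "E02",
                       appointment_minutes = 40)
  inst <- build_instance(nom, unit$roster, unit$calendar)
  expect_true(all(inst$opts[[1]]$e == 2L))
  expect_identical(inst$n_vars, 2L)   # one endoscopist x two days

  free <- make_patients(1, appointment_minutes = 40)
  inst <- build_instance(free, unit$roster, unit$calendar)
  expect_identical(inst$n_vars, 6L)

  # horizon max lateness 17 days: omega2 = 1/1000 satisfies
  # omega1 > omega2 * 17^2, a violating omega2 is scaled down
  late <- make_patients(1, due_date = -7L, appointment_minutes = 40)
  cal <- make_unit(1, 10)$calendar
  inst <- build_instance(late, make_unit(1, 10)$roster, cal)
  expect_equal(inst$omega2, 1e-3)
  expect_warning(
    inst2 <- build_instance(late, make_unit(1, 10)$roster, cal, omega2 = 0.5),
    "weight condition")
  expect_lt(inst2$omega2 * 17^2, inst2$omega1)

  empty <- make_patients(0)
  inst0 <- build_instance(empty, unit$roster, unit$calendar)
  expect_identical(inst0$n_vars, 0L)
  sol0 <- solve_mip(inst0)
  expect_equal(sol0$objective, 0)

  orphan <- make_patients(1, designated_endoscopist = "E99",
                          appointment_minutes = 40)
  expect_warning(inst <- build_instance(orphan, unit$roster, unit$calendar),
                 "no eligible")
  expect_identical(nrow(inst$patients), 0L)
})

test_that("branch and bound matches exhaustive enumeration on random small instances", {
  for (s in 1:60) {
    inst <- random_small_instance(s)
    a <- solve_mip(inst, gap_tol = 0)
    b <- brute_force_oracle(inst)
    expect_equal(a$objective, b$objective, tolerance = 1e-9,
                 info = paste("seed", s))
    expect_identical(a$status, "optimal")
  }
})

test_that("the oracle refuses instances beyond its enumeration cap", {
  unit <- make_unit(2, 3)
  co <- make_patients(4, appointment_minutes = 40)
  inst <- build_instance(co, unit$roster, unit$calendar)  # 24 variables
  expect_error(brute_force_oracle(inst), "at most 20")
})

test_that("solver resolves capacity contention and overdue penalties correctly", {
  # two 200-minute requests, one 390-minute day: exactly one fits
  unit <- make_unit(1, 1)
  two <- make_patients(2, due_date = -2L, appointment_minutes = 200)
  inst <- build_instance(two, unit$roster, unit$calendar)
  sol <- solve_mip(inst, gap_tol = 0)
  expect_identical(nrow(sol$assignments), 1L)
  expect_equal(sol$objective, 1 - 1e-3 * 3^2)

  # a patient is scheduled even at a lateness cost (weight condition)
  unitd <- make_unit(1, 1)
  unitd$calendar$day <- 12L
  one <- make_patients(1, due_date = 10L, appointment_minutes = 40)
  inst <- build_instance(one, unitd$roster, unitd$calendar)
  sol <- solve_mip(inst, gap_tol = 0)
  expect_identical(nrow(sol$assignments), 1L)
  expect_equal(sol$objective, 1 - 1e-3 * 4)

  # zero capacity everywhere: the empty schedule is optimal
  unit0 <- make_unit(2, 2, block = 0)
  co <- make_patients(3, appointment_minutes = 30)
  inst <- build_instance(co, unit0$roster, unit0$calendar)
  sol <- solve_mip(inst, gap_tol = 0)
  expect_identical(nrow(sol$assignments), 0L)
  expect_equal(sol$objective, 0)

  # one slot, two contenders with lateness 0 and 3: the on-time one wins
  unit1 <- make_unit(1, 1)
  duo <- make_patients(2, due_date = c(1L, -2L), appointment_minutes = 390)
  inst <- build_instance(duo, unit1$roster, unit1$calendar)
  sol <- solve_mip(inst, gap_tol = 0)
  expect_identical(sol$assignments$patient_id, "P001")
})

test_that("the squared penalty spreads overdue days fairly", {
  # days 2 and 4, one slot each; due dates 2 and 0. The two full schedules
  # split the fixed total of 4 overdue days as 0+4 (penalty 16*omega2) or
  # 2+2 (penalty 8*omega2); the square makes the even split optimal.
  roster <- make_unit(1, 1)$roster
  calendar <- data.frame(endoscopist_id = "E01", day = c(2L, 4L),
                         block_minutes = 40)
  co <- make_patients(2, due_date = c(2L, 0L), appointment_minutes = 40)
  inst <- build_instance(co, roster, calendar)
  for (sol in list(solve_mip(inst, gap_tol = 0), brute_force_oracle(inst))) {
    asg <- sol$assignments[order(sol$assignments$patient_id), ]
    expect_identical(asg$day, c(4L, 2L))
    expect_equal(sol$objective, 2 - 1e-3 * 8)
  }
})

test_that("scheduled count never drops when one capacity block grows", {
  for (s in 1:15) {
    inst <- random_small_instance(s + 300)
    base <- brute_force_oracle(inst)
    grown <- inst
    cell <- which(grown$cap == max(grown$cap))[1]
    grown$cap[cell] <- grown$cap[cell] + 50
    expect_gte(nrow(brute_force_oracle(grown)$assignments),
               nrow(base$assignments))
  }
})

test_that("a feasible greedy schedule warm-starts the solver to at least its count", {
  unit <- make_unit(2, 4)
  co <- generate_cohort(cohort_spec(120, seed = 91), roster = unit$roster)
  co$predicted_minutes <- co$actual_minutes
  pg <- schedule_greedy(sort_waiting_list(co, "predictive"), unit$roster,
                        unit$calendar)
  co$appointment_minutes <- appointment_duration(co$predicted_minutes,
                                                 "predictive")
  inst <- build_instance(co, unit$roster, unit$calendar)
  sol <- solve_mip(inst, node_limit = 5000, warm_start = pg)
  expect_gte(nrow(sol$assignments), nrow(pg))
  expect_gte(sol$bound + 1e-9, sol$objective)
})

test_that("within-day sequencing packs back-to-back and keeps all invariants", {
  unit <- make_unit(1, 1)
  co <- make_patients(3, appointment_minutes = 100,
                      due_date = c(3L, 3L, 3L))
  inst <- build_instance(co, unit$roster, unit$calendar)
  sol <- solve_mip(inst, gap_tol = 0)
  sched <- sequence_within_day(sol, inst, co)
  expect_identical(sort(sched$start_minute), c(0, 100, 200))
  validate_schedule(sched, co, unit$roster, unit$calendar)

  unit2 <- make_unit(2, 3)
  co2 <- generate_cohort(cohort_spec(80, seed = 14), roster = unit2$roster)
  co2$predicted_minutes <- co2$actual_minutes
  co2$appointment_minutes <- appointment_duration(co2$predicted_minutes,
                                                  "predictive")
  inst2 <- build_instance(co2, unit2$roster, unit2$calendar)
  sol2 <- solve_mip(inst2, node_limit = 20000)
  sched2 <- sequence_within_day(sol2, inst2, co2)
  validate_schedule(sched2, co2, unit2$roster, unit2$calendar)

  expect_identical(nrow(sequence_within_day(
    solve_mip(build_instance(make_patients(0), unit$roster, unit$calendar)),
    inst, co)), 0L)
})
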