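test_that("cohort generation is reproducible bit-for-bit under a fixed seed", {
  a <- generate_cohort(cohort_spec(500, seed = 99))
  b <- generate_cohort(cohort_spec(500, seed = 99))
  d <- generate_cohort(cohort_spec(500, seed = 100))
  expect_identical(a, b)
  expect_false(identical(a, d))
  expect_identical(nrow(generate_cohort(cohort_spec(0, seed = 1))), 0L)
})

test_that("empirical marginals match the configured ones", {
  n <- 100000
  co <- generate_cohort(cohort_spec(n, seed = 123))
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(co$sex == "male") - 0.512), 3 * se(0.512))
  expect_lt(abs(mean(co$procedure_type == "colonoscopy") - 0.642),
            3 * se(0.642))
  expect_lt(abs(mean(co$prior_pelvic_surgery) - 0.137), 3 * se(0.137))
  # female-only feature and the failed-reason consistency rule
  expect_true(!any(co$prior_pelvic_surgery[co$sex == "male"]))
  expect_identical(co$failed_reason == "none", !co$past_failed_colonoscopy)
})

test_that("duration draws stay in bounds and match the calibrated moments", {
  n <- 100000
  co <- generate_cohort(cohort_spec(n, seed = 321))
  x <- co$actual_minutes
  expect_true(all(x >= 2 & x <= 85))
  m <- duration_mixture_moments()
  expect_equal(m[["mean"]], 16.2, tolerance = 1e-6)
  expect_equal(m[["sd"]], 9.85, tolerance = 1e-6)
  se_mean <- sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - 16.2), 3 * se_mean)
  mu4 <- mean((x - mean(x))^4)
  se_sd <- sqrt(max(0, mu4 - var(x)^2) / n) / (2 * sd(x))
  expect_lt(abs(sd(x) - 9.85), 3 * se_sd)
})

test_that("calibration recovers parameters hitting arbitrary targets", {
  p <- calibrate_duration_params(target_mean = 20, target_sd = 8)
  m <- duration_mixture_moments(p)
  expect_equal(m[["mean"]], 20, tolerance = 1e-5)
  expect_equal(m[["sd"]], 8, tolerance = 1e-5)
})

test_that("zero dispersion collapses draws to their covariate-cell location", {
  p0 <- duration_params(sigma = 0)
  co <- make_patients(3, procedure_type = c("colonoscopy", "gastroscopy",
                                            "other"),
                      respiratory = c(FALSE, TRUE, FALSE),
                      diabetes = c(FALSE, FALSE, TRUE))
  d <- sample_durations(co, p0)
  expect_equal(d, pmin(85, pmax(2, exp(p0$mu0 + c(0, -0.55 + 0.2,
                                                  0.35 + 0.12)))))
})

test_that("due dates are uniform on the window and admission respects offsets", {
  n <- 100000
  co <- generate_cohort(cohort_spec(n, seed = 7))
  expect_true(all(co$due_date >= -7 & co$due_date <= 14))
  gof <- suppressWarnings(chisq.test(table(factor(co$due_date,
                                                  levels = -7:14))))
  expect_gt(gof$p.value, 0.001)
  # admission = due - offset(priority)
  one <- make_patients(1, priority = "P2")
  one$due_date <- NULL
  set.seed(1)
  dated <- assign_dates(one, due_window = c(3L, 3L))
  expect_identical(dated$due_date, 3L)
  expect_identical(dated$admission_date, -11L)
  expect_true(all(dated$admission_date <= dated$due_date))
  expect_error(assign_dates(one, priority_due_offsets =
                              c(P2 = -1, P3 = 60, P4 = 180, P5 = 365,
                                SURV = 365)),
               "nonnegative")
})

test_that("invalid probability vectors are rejected at spec construction", {
  m <- default_marginals()
  m$procedure_type <- c(colonoscopy = 0.9, gastroscopy = 0.3, other = 0.1)
  expect_error(cohort_spec(10, marginals = m), "probability")
  m2 <- default_marginals()
  m2$sex_male <- 1.4
  expect_error(cohort_spec(10, marginals = m2), "probability")
})

test_that("roster generation yields the advertised capacity", {
  r1 <- generate_roster(roster_spec(6, 10, 390, seed = 1))
  expect_identical(nrow(r1$calendar), 60L)
  expect_equal(sum(r1$calendar$block_minutes), 23400)
  r2 <- generate_roster(roster_spec(2, 8, 390, seed = 1))
  expect_equal(sum(r2$calendar$block_minutes), 6240)
  r3 <- generate_roster(roster_spec(1, 1, 390, seed = 1))
  expect_identical(nrow(r3$calendar), 1L)
  expect_true(all(r1$roster$accepts_non_nominative))
})
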