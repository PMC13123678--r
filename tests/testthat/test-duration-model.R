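test_that("cleaning drops missing and outlier duration labels", {
  co <- generate_cohort(cohort_spec(1332, seed = 17))
  masked <- co
  masked$actual_minutes[sample.int(1332, 79)] <- NA
  expect_identical(nrow(clean_cohort(masked)), 1253L)

  zero <- make_patients(3, actual_minutes = c(0, 16, 120))
  expect_identical(clean_cohort(zero)$id, "P002")

  expect_identical(nrow(clean_cohort(co)), nrow(co))
  all_bad <- make_patients(2, actual_minutes = NA_real_)
  expect_error(clean_cohort(all_bad), "no usable rows")
})

test_that("regression metrics follow their definitions and Jensen's bound", {
  m <- regression_metrics(c(10, 20), c(12, 26))
  expect_equal(m[["mae"]], 4)
  expect_equal(m[["mse"]], 20)
  set.seed(2)
  for (i in 1:20) {
    m <- regression_metrics(rnorm(50), rnorm(50))
    expect_lte(m[["mae"]], sqrt(m[["mse"]]) + 1e-12)
  }
})

test_that("every registered regressor fits, predicts positively, and obeys MAE <= rmse", {
  co <- clean_cohort(generate_cohort(cohort_spec(400, seed = 31)))
  tr <- co[1:300, ]
  te <- co[301:400, ]
  for (rg in c("linear", "random_forest", "gradient_boosted_trees",
               "gaussian_process", "multilayer_perceptron")) {
    fp <- fit_predict(rg, tr, te, seed = 5, nrounds = 40, num_trees = 100)
    expect_true(all(fp$predictions >= 2), info = rg)
    expect_lte(fp$mae, sqrt(fp$mse) + 1e-12)
    # beats or ties predicting far off the data scale
    expect_lt(fp$mae, 3 * sd(te$actual_minutes))
  }
  expect_error(fit_predict("ridge", tr, te), "unknown regressor")
})

test_that("constant labels give zero error", {
  co <- make_patients(60, actual_minutes = 25,
                      procedure_type = rep(c("colonoscopy", "gastroscopy"), 30))
  fp_lin <- fit_predict("linear", co, co, seed = 1)
  expect_equal(fp_lin$mae, 0, tolerance = 1e-8)
  expect_equal(fp_lin$mse, 0, tolerance = 1e-8)
  fp_gbt <- fit_predict("gradient_boosted_trees", co, co, seed = 1,
                        nrounds = 60)
  expect_equal(fp_gbt$mae, 0, tolerance = 1e-3)
})

test_that("gradient boosting beats the predict-the-mean baseline on a held-out split", {
  co <- clean_cohort(generate_cohort(cohort_spec(1253, seed = 41)))
  set.seed(8)
  test_idx <- sample.int(1253, 251)   # 80/20 split
  tr <- co[-test_idx, ]
  te <- co[test_idx, ]
  fp <- fit_predict("gradient_boosted_trees", tr, te, seed = 8, nrounds = 80)
  baseline_mae <- mean(abs(mean(tr$actual_minutes) - te$actual_minutes))
  expect_lt(fp$mae, baseline_mae)
  expect_lt(fp$mae, sd(te$actual_minutes))
})

test_that("appointment lengths follow the buffer and flat-slot conventions", {
  expect_equal(appointment_duration(16.2, "predictive"), 31.2)
  expect_equal(appointment_duration(2, "predictive"), 17)
  expect_equal(appointment_duration(c(5, 50, 80), "fixed"), c(30, 30, 30))
  expect_error(appointment_duration(0, "predictive"), "positive")
  expect_error(appointment_duration(NA_real_, "predictive"), "positive")
})

test_that("backward elimination recovers the features that carry signal", {
  hits <- 0L
  for (s in 1:3) {
    co <- clean_cohort(generate_cohort(
      cohort_spec(2500, duration_params = signal_only_params(),
                  seed = 500 + s)))
    be <- backward_eliminate(co, max_features = 4, seed = s, nrounds = 40)
    hits <- hits +
      all(c("procedure_type", "respiratory") %in% be$selected_features)
    expect_lte(length(be$selected_features), 4L)
    # one feature removed per round, down to a single feature
    expect_identical(nrow(be$trace), length(FEATURE_ORDER) - 1L)
  }
  expect_gte(hits, 2L)
})

test_that("single-feature input needs no elimination", {
  co <- clean_cohort(generate_cohort(cohort_spec(300, seed = 77)))
  be <- backward_eliminate(co, features = "procedure_type", seed = 1,
                           nrounds = 30)
  expect_identical(nrow(be$trace), 0L)
  expect_identical(be$selected_features, "procedure_type")
})

test_that("pure-noise labels show no systematic validation improvement", {
  co <- clean_cohort(generate_cohort(cohort_spec(800, seed = 88)))
  set.seed(88)
  co$actual_minutes <- sample(co$actual_minutes)   # break all associations
  be <- backward_eliminate(co, max_features = 4, seed = 2, nrounds = 30)
  mae_full <- be$sets$cv_mae[be$sets$n_features == length(FEATURE_ORDER)]
  expect_lt((mae_full - min(be$sets$cv_mae)) / mae_full, 0.05)
})
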