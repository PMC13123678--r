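#' Clean a raw waiting list for model building
#'
#' Removes rows whose procedure-duration label is missing, nonpositive, or
#' outside the plausible bounds (outliers); the remaining rows are complete
#' because every categorical feature carries an explicit "missing" level
#' where needed (BMI).
#'
#' @param raw waiting-list data frame with an `actual_minutes` column.
#' @param bounds admissible duration interval in minutes.
#' @return The cleaned data frame.
#' @export
clean_cohort <- function(raw, bounds = DURATION_BOUNDS) {
  keep <- !is.na(raw$actual_minutes) & raw$actual_minutes > 0 &
    raw$actual_minutes >= bounds[1] & raw$actual_minutes <= bounds[2]
  out <- raw[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no usable rows after cleaning (all duration labels invalid)",
         call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Fixed factor levels per feature so train and test encode identically.
feature_levels <- function() {
  list(sex = c("female", "male"), age_band = AGE_BANDS, bmi_band = BMI_BANDS,
       priority = PRIORITY_LEVELS, failed_reason = FAILED_REASONS,
       procedure_type = PROCEDURE_TYPES, indication = INDICATIONS,
       endoscopist_type = ENDOSCOPIST_TYPES)
}

#' Encode patient features as a numeric design matrix
#'
#' Categorical features become treatment-contrast dummies over fixed level
#' sets, flags become 0/1, and the comorbidity score stays numeric. Each
#' matrix column is tagged with the patient-level feature it came from so
#' importances can be aggregated per feature.
#'
#' @param cohort waiting-list data frame.
#' @param features character vector of feature names (see `FEATURE_ORDER`).
#' @return List with `x` (matrix including intercept), `groups` (feature of
#'   each column), and `y` (duration labels, possibly NA).
#' @export
encode_features <- function(cohort, features = FEATURE_ORDER) {
  stopifnot(all(features %in% FEATURE_ORDER), length(features) >= 1L)
  lev <- feature_levels()
  df <- lapply(features, function(f) {
    v <- cohort[[f]]
    if (f %in% names(lev)) factor(v, levels = lev[[f]]) else as.numeric(v)
  })
  names(df) <- features
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  x <- stats::model.matrix(~ ., data = df)
  groups <- c("(Intercept)", features)[attr(x, "assign") + 1L]
  list(x = x, groups = groups, y = cohort$actual_minutes)
}

# ---- regressor registry -------------------------------------------------

REGRESSOR_SPECS <- c("linear", "random_forest", "gradient_boosted_trees",
                     "gaussian_process", "multilayer_perceptron")

fit_regressor <- function(spec, x, y, seed = 1L, options = list()) {
  if (!spec %in% REGRESSOR_SPECS) {
    stop(sprintf("unknown regressor '%s'; use one of: %s", spec,
                 paste(REGRESSOR_SPECS, collapse = ", ")), call. = FALSE)
  }
  set.seed(seed)
  fit <- switch(spec,
    linear = {
      f <- stats::lm.fit(x, y)
      list(coef = f$coefficients)
    },
    random_forest = {
      ranger::ranger(x = as.data.frame(x[, -1, drop = FALSE]), y = y,
                     num.trees = options$num_trees %||% 300L,
                     importance = "impurity", seed = seed, num.threads = 1L)
    },
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(x[, -1, drop = FALSE], label = y,
                                     nthread = 1L)
      xgboost::xgb.train(params = list(objective = "reg:squarederror",
                                       max_depth = options$max_depth %||% 4L,
                                       eta = options$eta %||% 0.1,
                                       nthread = 1L, seed = seed),
                         data = dtrain, nrounds = options$nrounds %||% 120L,
                         verbose = 0)
    },
    gaussian_process = {
      gp <- NULL
      # kernlab prints its automatic kernel-width estimate; keep quiet
      invisible(capture.output(
        gp <- kernlab::gausspr(x = x[, -1, drop = FALSE], y = y,
                               kernel = "rbfdot", variance.model = FALSE)))
      gp
    },
    multilayer_perceptron = {
      xs <- scale(x[, -1, drop = FALSE])
      xs[!is.finite(xs)] <- 0
      net <- nnet::nnet(x = xs, y = y, size = options$mlp_size %||% 6L,
                        linout = TRUE, decay = options$mlp_decay %||% 0.05,
                        maxit = options$mlp_maxit %||% 200L, trace = FALSE,
                        MaxNWts = 5000L)
      list(net = net, center = attr(xs, "scaled:center"),
           scale = attr(xs, "scaled:scale"))
    })
  structure(list(spec = spec, fit = fit, columns = colnames(x)),
            class = "endo_regressor")
}

predict_regressor <- function(model, x) {
  x <- x[, model$columns, drop = FALSE]
  p <- switch(model$spec,
    linear = {
      co <- model$fit$coef
      co[is.na(co)] <- 0
      as.numeric(x %*% co)
    },
    random_forest = {
      stats::predict(model$fit,
                     data = as.data.frame(x[, -1, drop = FALSE]))$predictions
    },
    gradient_boosted_trees = {
      stats::predict(model$fit, x[, -1, drop = FALSE])
    },
    gaussian_process = {
      as.numeric(kernlab::predict(model$fit, x[, -1, drop = FALSE]))
    },
    multilayer_perceptron = {
      xs <- sweep(x[, -1, drop = FALSE], 2, model$fit$center, "-")
      sc <- model$fit$scale
      sc[sc == 0 | !is.finite(sc)] <- 1
      xs <- sweep(xs, 2, sc, "/")
      as.numeric(stats::predict(model$fit$net, xs))
    })
  # a procedure can never take less than the physiological floor
  pmax(DURATION_BOUNDS[1], as.numeric(p))
}

# Per-feature importance. Tree ensembles expose an internal measure (gain /
# impurity reduction), aggregated over a feature's dummy columns; other
# models fall back to grouped permutation importance (mean MAE increase when
# the feature's columns are jointly permuted).
importance_by_feature <- function(model, encoded, seed = 1L, n_perm = 3L) {
  features <- setdiff(unique(encoded$groups), "(Intercept)")
  cols_of <- function(f) which(encoded$groups == f)
  if (model$spec == "gradient_boosted_trees") {
    imp <- xgboost::xgb.importance(model = model$fit)
    by_col <- setNames(imp$Gain, imp$Feature)
  } else if (model$spec == "random_forest") {
    by_col <- model$fit$variable.importance
  } else {
    by_col <- NULL
  }
  if (!is.null(by_col)) {
    out <- vapply(features, function(f) {
      sum(by_col[intersect(names(by_col), colnames(encoded$x)[cols_of(f)])],
          na.rm = TRUE)
    }, numeric(1))
    return(out)
  }
  base_mae <- mean(abs(predict_regressor(model, encoded$x) - encoded$y))
  set.seed(seed)
  out <- vapply(features, function(f) {
    cols <- cols_of(f)
    delta <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      xp <- encoded$x
      perm <- sample.int(nrow(xp))
      xp[, cols] <- xp[perm, cols, drop = FALSE]
      delta[r] <- mean(abs(predict_regressor(model, xp) - encoded$y)) - base_mae
    }
    mean(delta)
  }, numeric(1))
  out
}

#' Mean absolute and squared error of predictions
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return Named vector `c(mae, mse)`.
#' @export
regression_metrics <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  c(mae = mean(abs(predicted - observed)),
    mse = mean((predicted - observed)^2))
}

#' Fit a duration regressor and evaluate it on held-out patients
#'
#' The model is fit on the training rows only; predictions on the test rows
#' are clamped at the 2-minute physiological floor and scored by MAE and
#' MSE.
#'
#' @param regressor_spec one of `"linear"`, `"random_forest"`,
#'   `"gradient_boosted_trees"`, `"gaussian_process"`,
#'   `"multilayer_perceptron"`.
#' @param train,test cleaned waiting-list data frames with labels.
#' @param features features to use (default: all).
#' @param seed integer seed controlling any model randomness.
#' @param ... tuning options forwarded to the regressor (e.g. `nrounds`).
#' @return List with `model` (a `duration_model`), `predictions`, `mae`,
#'   `mse`.
#' @export
fit_predict <- function(regressor_spec, train, test,
                        features = FEATURE_ORDER, seed = 1L, ...) {
  enc_tr <- encode_features(train, features)
  reg <- fit_regressor(regressor_spec, enc_tr$x, enc_tr$y, seed = seed,
                       options = list(...))
  model <- structure(list(regressor = reg, features = features, seed = seed),
                     class = "duration_model")
  pred <- predict_durations(model, test)
  met <- regression_metrics(pred, test$actual_minutes)
  list(model = model, predictions = pred,
       mae = met[["mae"]], mse = met[["mse"]])
}

#' Train a duration model on a full training cohort
#'
#' Convenience wrapper around the regressor registry when no held-out
#' evaluation is wanted (e.g. inside simulation experiments, where the
#' model is trained on a disjoint synthetic cohort).
#'
#' @inheritParams fit_predict
#' @return A `duration_model`.
#' @export
train_duration_model <- function(train,
                                 regressor_spec = "gradient_boosted_trees",
                                 features = FEATURE_ORDER, seed = 1L, ...) {
  enc <- encode_features(train, features)
  reg <- fit_regressor(regressor_spec, enc$x, enc$y, seed = seed,
                       options = list(...))
  structure(list(regressor = reg, features = features, seed = seed),
            class = "duration_model")
}

#' Predict procedure durations for new patients
#'
#' @param model a `duration_model` from [fit_predict()].
#' @param cohort waiting-list data frame.
#' @return Numeric vector of predicted minutes (>= 2).
#' @export
predict_durations <- function(model, cohort) {
  enc <- encode_features(cohort, model$features)
  predict_regressor(model$regressor, enc$x)
}

# Cross-validated MAE of one feature set on the training data.
cv_mae <- function(train, features, regressor_spec, n_folds, seed, options) {
  n <- nrow(train)
  set.seed(substream_seed(seed, "cv-folds"))
  fold <- sample(rep_len(seq_len(n_folds), n))
  errs <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    tr <- train[fold != k, , drop = FALSE]
    va <- train[fold == k, , drop = FALSE]
    enc_tr <- encode_features(tr, features)
    reg <- fit_regressor(regressor_spec, enc_tr$x, enc_tr$y, seed = seed,
                         options = options)
    enc_va <- encode_features(va, features)
    pred <- predict_regressor(reg, enc_va$x)
    errs[k] <- mean(abs(pred - va$actual_minutes))
  }
  mean(errs)
}

#' Wrapper backward feature elimination scored by validation MAE
#'
#' Starting from the full feature set, the model is refit each round and
#' the least-important feature (by the regressor's importance measure, with
#' grouped permutation importance as the fallback) is dropped; every
#' visited set is scored by k-fold cross-validated MAE on the training
#' data. The selected set is the one with the lowest validation MAE among
#' sets no larger than `max_features`. Importance ties are broken by
#' dropping the feature that appears later in the canonical feature order,
#' so elimination is deterministic under a fixed seed. Test labels are
#' never touched.
#'
#' @param train cleaned training waiting list.
#' @param regressor_spec regressor used inside the wrapper.
#' @param max_features size cap on the selected set.
#' @param n_folds folds of the validation scheme.
#' @param features starting feature set.
#' @param seed integer seed.
#' @param ... tuning options for the regressor.
#' @return List with `selected_features`, `trace` (one row per removal:
#'   `removed_feature`, `n_features_left`, `cv_mae` of the remaining set)
#'   and `sets` (every visited set with its size and validation MAE).
#' @export
backward_eliminate <- function(train, regressor_spec = "gradient_boosted_trees",
                               max_features = 4L, n_folds = 5L,
                               features = FEATURE_ORDER, seed = 1L, ...) {
  stopifnot(length(features) >= 1L, max_features >= 1L)
  options <- list(...)
  feats <- features
  sets <- list()
  trace <- data.frame(removed_feature = character(),
                      n_features_left = integer(), cv_mae = numeric(),
                      stringsAsFactors = FALSE)
  repeat {
    score <- cv_mae(train, feats, regressor_spec, n_folds, seed, options)
    sets[[length(sets) + 1L]] <- list(features = feats, cv_mae = score)
    if (length(feats) == 1L) break
    enc <- encode_features(train, feats)
    reg <- fit_regressor(regressor_spec, enc$x, enc$y, seed = seed,
                         options = options)
    imp <- importance_by_feature(reg, enc, seed = seed)
    imp <- imp[feats]
    names(imp) <- feats
    imp[is.na(imp)] <- 0
    worst <- min(imp)
    tied <- feats[imp <= worst + 1e-12]
    # drop the tied feature that comes last in the canonical order
    drop <- tied[which.max(match(tied, FEATURE_ORDER))]
    feats <- setdiff(feats, drop)
    score_after <- cv_mae(train, feats, regressor_spec, n_folds, seed, options)
    trace <- rbind(trace, data.frame(removed_feature = drop,
                                     n_features_left = length(feats),
                                     cv_mae = score_after,
                                     stringsAsFactors = FALSE))
  }
  # sets revisited below the cap after each removal were scored once each
  sizes <- vapply(sets, function(s) length(s$features), integer(1))
  maes <- vapply(sets, function(s) s$cv_mae, numeric(1))
  ok <- which(sizes <= max_features)
  best <- ok[which.min(maes[ok])]
  list(selected_features = sets[[best]]$features,
       trace = trace,
       sets = data.frame(n_features = sizes, cv_mae = maes))
}

#' Planned appointment length from a predicted procedure duration
#'
#' In predictive mode a fixed buffer (consent, preparation, room turnover)
#' is added to the predicted procedure time; in fixed mode every patient
#' gets the conventional flat slot regardless of the prediction.
#'
#' @param predicted_minutes numeric vector of predicted procedure minutes.
#' @param mode `"predictive"` or `"fixed"`.
#' @param buffer_minutes buffer added in predictive mode.
#' @param fixed_minutes flat slot length in fixed mode.
#' @return Numeric vector of planned appointment minutes.
#' @export
appointment_duration <- function(predicted_minutes,
                                 mode = c("predictive", "fixed"),
                                 buffer_minutes = DEFAULT_BUFFER_MINUTES,
                                 fixed_minutes = DEFAULT_FIXED_SLOT_MINUTES) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    return(rep(fixed_minutes, length(predicted_minutes)))
  }
  if (any(is.na(predicted_minutes)) || any(predicted_minutes <= 0)) {
    stop("predictive mode requires strictly positive predicted durations",
         call. = FALSE)
  }
  predicted_minutes + buffer_minutes
}
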