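#' Default feature marginals of the synthetic waiting list
#'
#' Category probabilities for every patient feature. Sex, age, BMI,
#' comorbidity score, prior pelvic surgery (a female-only feature whose
#' rate is set so that 13.7% of all patients carry it) and the procedure
#' mix follow the published unit's cohort; flags and categories whose
#' distribution was not published (respiratory, cardiovascular, diabetes,
#' failed colonoscopies, indication) use plausible defaults and are fully
#' configurable.
#'
#' @return Named list of probability vectors / rates.
#' @export
default_marginals <- function() {
  list(
    sex_male = 0.512,
    age_band = c("<45" = 0.178, "45-59" = 0.27, "60-80" = 0.471,
                 ">80" = 0.08) / 0.999,
    bmi_band = c("<25" = 0.233, "25-30" = 0.215, ">30" = 0.125,
                 "missing" = 0.427),
    priority = c(P2 = 0.02, P3 = 0.43, P4 = 0.15, P5 = 0.14, SURV = 0.26),
    comorbidity_score = c("0" = 0.546, "1" = 0.227, "2" = 0.144,
                          "3" = 0.06, "4" = 0.023),
    respiratory = 0.12,
    cardiovascular = 0.25,
    diabetes = 0.15,
    prior_pelvic_surgery_overall = 0.137,
    past_failed_colonoscopy = 0.08,
    failed_reason = c("poor preparation" = 0.4, "technical difficulties" = 0.3,
                      "disease-related" = 0.2, "other" = 0.1),
    procedure_type = c(colonoscopy = 0.642, gastroscopy = 0.307,
                       other = 0.051),
    indication = c(high = 0.10, intermediate = 0.35, low = 0.29,
                   surveillance = 0.26),
    endoscopist_type = c(gastrointestinal = 0.799, colorectal = 0.156,
                         hepatologic = 0.025, thoracic = 0.02)
  )
}

#' Parameters of the procedure-duration generator
#'
#' Durations are drawn from a log-normal distribution truncated to
#' `bounds` minutes, with additive log-scale effects for procedure type,
#' respiratory disease and diabetes. The default location `mu0` and
#' dispersion `sigma` were calibrated with [calibrate_duration_params()] so
#' that, under [default_marginals()], the mixture has mean 16.2 minutes and
#' standard deviation 9.85 minutes.
#'
#' @param mu0 baseline log-minute location (colonoscopy, no comorbidity).
#' @param sigma within-cell log-scale dispersion.
#' @param beta_procedure named log-scale offsets per procedure type.
#' @param beta_respiratory,beta_diabetes log-scale offsets for the flags.
#' @param bounds two-element truncation interval in minutes.
#' @return A `duration_params` list.
#' @export
duration_params <- function(mu0 = 2.7300499832,
                            sigma = 0.5046216016,
                            beta_procedure = c(colonoscopy = 0,
                                               gastroscopy = -0.55,
                                               other = 0.35),
                            beta_respiratory = 0.20,
                            beta_diabetes = 0.12,
                            bounds = DURATION_BOUNDS) {
  stopifnot(sigma >= 0, length(bounds) == 2L, bounds[1] > 0,
            bounds[1] < bounds[2],
            all(PROCEDURE_TYPES %in% names(beta_procedure)))
  structure(list(mu0 = mu0, sigma = sigma,
                 beta_procedure = beta_procedure,
                 beta_respiratory = beta_respiratory,
                 beta_diabetes = beta_diabetes,
                 bounds = bounds),
            class = "duration_params")
}

# kth moment of a log-normal truncated (on the minute scale) to [lo, hi]
truncated_lnorm_moment <- function(k, mu, sigma, lo, hi) {
  a <- (log(lo) - mu) / sigma
  b <- (log(hi) - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  exp(k * mu + k^2 * sigma^2 / 2) *
    (pnorm(b - k * sigma) - pnorm(a - k * sigma)) / z
}

# cell table (procedure x respiratory x diabetes) with mixture weights and
# log-scale offsets implied by the marginals and effect sizes
duration_cells <- function(params, marginals) {
  cells <- expand.grid(procedure_type = PROCEDURE_TYPES,
                       respiratory = c(FALSE, TRUE),
                       diabetes = c(FALSE, TRUE),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- marginals$procedure_type[cells$procedure_type] *
    ifelse(cells$respiratory, marginals$respiratory, 1 - marginals$respiratory) *
    ifelse(cells$diabetes, marginals$diabetes, 1 - marginals$diabetes)
  eff <- params$beta_procedure[cells$procedure_type] +
    params$beta_respiratory * cells$respiratory +
    params$beta_diabetes * cells$diabetes
  cbind(cells, weight = as.numeric(p), effect = as.numeric(eff))
}

#' Population mean and sd of the duration mixture
#'
#' Closed-form moments of the truncated log-normal mixture implied by a
#' parameter set and feature marginals; used for calibration and testing.
#'
#' @param params a [duration_params()] object.
#' @param marginals feature marginals, see [default_marginals()].
#' @return Named numeric vector `c(mean, sd)` in minutes.
#' @export
duration_mixture_moments <- function(params = duration_params(),
                                     marginals = default_marginals()) {
  cl <- duration_cells(params, marginals)
  lo <- params$bounds[1]; hi <- params$bounds[2]
  m1 <- sum(cl$weight * truncated_lnorm_moment(1, params$mu0 + cl$effect,
                                               params$sigma, lo, hi))
  m2 <- sum(cl$weight * truncated_lnorm_moment(2, params$mu0 + cl$effect,
                                               params$sigma, lo, hi))
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

#' Calibrate the duration generator to target moments
#'
#' Solves numerically for the baseline location and dispersion so that the
#' truncated log-normal mixture implied by the covariate effects and the
#' feature marginals attains a target population mean and standard
#' deviation.
#'
#' @param target_mean,target_sd moments to match, in minutes.
#' @param params starting parameter set carrying the effect sizes and bounds.
#' @param marginals feature marginals.
#' @return A calibrated `duration_params` object.
#' @export
calibrate_duration_params <- function(target_mean = 16.2, target_sd = 9.85,
                                      params = duration_params(),
                                      marginals = default_marginals()) {
  obj <- function(par) {
    p <- params
    p$mu0 <- par[1]
    p$sigma <- exp(par[2])
    m <- duration_mixture_moments(p, marginals)
    (m[["mean"]] - target_mean)^2 + (m[["sd"]] - target_sd)^2
  }
  fit <- stats::optim(c(log(target_mean), log(0.5)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  params$mu0 <- fit$par[1]
  params$sigma <- exp(fit$par[2])
  params
}

#' Draw procedure durations for a set of patients
#'
#' Samples from the truncated log-normal duration model given each
#' patient's procedure type, respiratory flag and diabetes flag, by inverse
#' CDF (so draws are exact, vectorized and reproducible). With zero
#' dispersion every draw equals its covariate cell's location, clamped to
#' the bounds.
#'
#' @param covariates data frame with columns `procedure_type`,
#'   `respiratory`, `diabetes`.
#' @param params a [duration_params()] object.
#' @return Numeric vector of minutes, all within `params$bounds`.
#' @export
sample_durations <- function(covariates, params = duration_params()) {
  n <- nrow(covariates)
  if (n == 0L) return(numeric())
  mu <- params$mu0 +
    params$beta_procedure[as.character(covariates$procedure_type)] +
    params$beta_respiratory * covariates$respiratory +
    params$beta_diabetes * covariates$diabetes
  mu <- as.numeric(mu)
  lo <- params$bounds[1]; hi <- params$bounds[2]
  if (params$sigma < 1e-12) {
    return(pmin(hi, pmax(lo, exp(mu))))
  }
  a <- pnorm((log(lo) - mu) / params$sigma)
  b <- pnorm((log(hi) - mu) / params$sigma)
  u <- a + runif(n) * (b - a)
  exp(mu + params$sigma * qnorm(u))
}

#' Specification of a synthetic waiting list
#'
#' @param n_patients number of patients to generate.
#' @param marginals feature marginals, see [default_marginals()].
#' @param duration_params duration generator parameters.
#' @param due_window integer interval (days relative to horizon start, day 1)
#'   in which due dates fall uniformly.
#' @param priority_due_offsets named nonnegative days between admission and
#'   due date per priority class (admission = due - offset).
#' @param nominative_fraction probability that a patient arrives with a
#'   designated endoscopist.
#' @param seed optional integer seed; when given, generation is reproducible
#'   bit-for-bit.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients,
                        marginals = default_marginals(),
                        duration_params = endosched::duration_params(),
                        due_window = c(-7L, 14L),
                        priority_due_offsets = c(P2 = 14, P3 = 60, P4 = 180,
                                                 P5 = 365, SURV = 365),
                        nominative_fraction = 0.5,
                        seed = NULL) {
  stopifnot(n_patients >= 0, due_window[1] <= due_window[2],
            nominative_fraction >= 0, nominative_fraction <= 1)
  if (any(priority_due_offsets < 0)) {
    stop("priority_due_offsets must be nonnegative", call. = FALSE)
  }
  stopifnot(all(PRIORITY_LEVELS %in% names(priority_due_offsets)))
  for (nm in c("age_band", "bmi_band", "priority", "comorbidity_score",
               "failed_reason", "procedure_type", "indication",
               "endoscopist_type")) {
    assert_prob_vector(marginals[[nm]], nm)
  }
  for (nm in c("sex_male", "respiratory", "cardiovascular", "diabetes",
               "prior_pelvic_surgery_overall", "past_failed_colonoscopy")) {
    p <- marginals[[nm]]
    if (!is.finite(p) || p < 0 || p > 1) {
      stop(sprintf("'%s' must be a probability in [0, 1]", nm), call. = FALSE)
    }
  }
  structure(list(n_patients = as.integer(n_patients), marginals = marginals,
                 duration_params = duration_params, due_window = due_window,
                 priority_due_offsets = priority_due_offsets,
                 nominative_fraction = nominative_fraction, seed = seed),
            class = "cohort_spec")
}

sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic waiting list
#'
#' Features are drawn independently from the marginals, except that the
#' failed-colonoscopy reason is conditioned on a past failed colonoscopy
#' (and is `"none"` otherwise) and prior pelvic surgery occurs in female
#' patients only, at a rate chosen so the whole-cohort fraction matches the
#' configured overall rate. Procedure durations come from the truncated
#' log-normal model; admission and due dates from [assign_dates()].
#'
#' @param spec a [cohort_spec()].
#' @param roster optional endoscopist roster; when supplied, a
#'   `nominative_fraction` share of patients is given a designated
#'   endoscopist drawn uniformly among compatible providers.
#' @return Data frame with one row per patient.
#' @export
generate_cohort <- function(spec, roster = NULL) {
  gen <- function() {
    n <- spec$n_patients
    m <- spec$marginals
    sex <- ifelse(runif(n) < m$sex_male, "male", "female")
    female <- sex == "female"
    # female-only feature at rate p_f so the overall rate is as configured
    p_f <- min(1, m$prior_pelvic_surgery_overall / max(1e-12, 1 - m$sex_male))
    pelvic <- female & runif(n) < p_f
    failed <- runif(n) < m$past_failed_colonoscopy
    reason <- rep("none", n)
    if (any(failed)) reason[failed] <- sample_cat(sum(failed), m$failed_reason)
    cohort <- data.frame(
      id = if (n > 0) sprintf("P%05d", seq_len(n)) else character(),
      sex = sex,
      age_band = if (n > 0) sample_cat(n, m$age_band) else character(),
      bmi_band = if (n > 0) sample_cat(n, m$bmi_band) else character(),
      priority = if (n > 0) sample_cat(n, m$priority) else character(),
      comorbidity_score = if (n > 0) {
        as.integer(sample_cat(n, m$comorbidity_score))
      } else integer(),
      respiratory = runif(n) < m$respiratory,
      cardiovascular = runif(n) < m$cardiovascular,
      diabetes = runif(n) < m$diabetes,
      prior_pelvic_surgery = pelvic,
      past_failed_colonoscopy = failed,
      failed_reason = reason,
      procedure_type = if (n > 0) sample_cat(n, m$procedure_type) else character(),
      indication = if (n > 0) sample_cat(n, m$indication) else character(),
      endoscopist_type = if (n > 0) sample_cat(n, m$endoscopist_type) else character(),
      designated_endoscopist = rep(NA_character_, n),
      stringsAsFactors = FALSE
    )
    cohort$actual_minutes <- sample_durations(cohort, spec$duration_params)
    cohort$predicted_minutes <- rep(NA_real_, n)
    cohort$appointment_minutes <- rep(NA_real_, n)
    cohort <- assign_dates(cohort, spec$due_window, spec$priority_due_offsets)
    if (!is.null(roster) && n > 0) {
      nominative <- runif(n) < spec$nominative_fraction
      for (i in which(nominative)) {
        compat <- vapply(
          strsplit(roster$compatible_procedures, ";", fixed = TRUE),
          function(s) cohort$procedure_type[i] %in% s, logical(1))
        ids <- roster$id[compat]
        if (length(ids)) {
          cohort$designated_endoscopist[i] <- ids[sample.int(length(ids), 1L)]
        }
      }
    }
    cohort
  }
  if (!is.null(spec$seed)) with_seed(spec$seed, gen()) else gen()
}

#' Fill admission and due dates
#'
#' Due dates are uniform on the integer `due_window` (days relative to the
#' first day of the planning horizon, day 1; negative values mean the
#' patient is already overdue when planning starts). The admission date is
#' the due date minus the priority class's offset, so tighter priorities
#' have joined the list more recently.
#'
#' @param cohort waiting-list data frame with a `priority` column.
#' @param due_window length-2 integer interval.
#' @param priority_due_offsets named nonnegative day offsets per class.
#' @return The cohort with `admission_date` and `due_date` columns filled.
#' @export
assign_dates <- function(cohort, due_window = c(-7L, 14L),
                         priority_due_offsets = c(P2 = 14, P3 = 60, P4 = 180,
                                                  P5 = 365, SURV = 365)) {
  if (any(priority_due_offsets < 0)) {
    stop("priority_due_offsets must be nonnegative", call. = FALSE)
  }
  n <- nrow(cohort)
  days <- seq.int(due_window[1], due_window[2])
  due <- if (n > 0) days[sample.int(length(days), n, replace = TRUE)] else integer()
  off <- priority_due_offsets[cohort$priority]
  cohort$due_date <- as.integer(due)
  cohort$admission_date <- as.integer(due - off)
  cohort
}

#' Specification of an endoscopist roster and capacity calendar
#'
#' @param n_endoscopists number of providers (one daily room stream each).
#' @param n_days planning-horizon length in working days.
#' @param daily_block_minutes working-block minutes per provider per day.
#' @param specialty_mix probabilities over specialties.
#' @param accepts_non_nominative_fraction fraction of providers (rounded,
#'   taken from the head of the roster) who accept non-nominative patients.
#' @param compatible_procedures procedure set every provider can perform.
#' @param seed optional integer seed.
#' @return A `roster_spec` list.
#' @export
roster_spec <- function(n_endoscopists, n_days,
                        daily_block_minutes = DEFAULT_BUDGET_MINUTES,
                        specialty_mix = c(gastrointestinal = 0.799,
                                          colorectal = 0.156,
                                          hepatologic = 0.025,
                                          thoracic = 0.02),
                        accepts_non_nominative_fraction = 1,
                        compatible_procedures = PROCEDURE_TYPES,
                        seed = NULL) {
  stopifnot(n_endoscopists >= 1, n_days >= 1, daily_block_minutes > 0)
  assert_prob_vector(specialty_mix, "specialty_mix")
  structure(list(n_endoscopists = as.integer(n_endoscopists),
                 n_days = as.integer(n_days),
                 daily_block_minutes = daily_block_minutes,
                 specialty_mix = specialty_mix,
                 accepts_non_nominative_fraction = accepts_non_nominative_fraction,
                 compatible_procedures = compatible_procedures,
                 seed = seed),
            class = "roster_spec")
}

#' Generate an endoscopist roster and its capacity calendar
#'
#' @param spec a [roster_spec()].
#' @return List with elements `roster` (data frame: `id`, `specialty`,
#'   `accepts_non_nominative`, `compatible_procedures`) and `calendar`
#'   (data frame: `endoscopist_id`, `day`, `block_minutes` for every
#'   provider-day in the horizon).
#' @export
generate_roster <- function(spec) {
  gen <- function() {
    n <- spec$n_endoscopists
    k <- round(spec$accepts_non_nominative_fraction * n)
    roster <- data.frame(
      id = sprintf("E%02d", seq_len(n)),
      specialty = sample_cat(n, spec$specialty_mix),
      accepts_non_nominative = seq_len(n) <= k,
      compatible_procedures = paste(spec$compatible_procedures, collapse = ";"),
      stringsAsFactors = FALSE
    )
    calendar <- expand.grid(endoscopist_id = roster$id,
                            day = seq_len(spec$n_days),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    calendar$block_minutes <- spec$daily_block_minutes
    calendar <- calendar[order(calendar$endoscopist_id, calendar$day), ]
    rownames(calendar) <- NULL
    list(roster = roster, calendar = calendar)
  }
  if (!is.null(spec$seed)) with_seed(spec$seed, gen()) else gen()
}
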