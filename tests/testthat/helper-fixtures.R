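# In-code fixtures shared across test files.

# A minimal waiting-list data frame; any column can be overridden with a
# vector recycled to n.
make_patients <- function(n, ...) {
  base <- list(
    id = sprintf("P%03d", seq_len(n)),
    sex = "female",
    age_band = "45-59",
    bmi_band = "<25",
    priority = "P3",
    comorbidity_score = 0L,
    respiratory = FALSE,
    cardiovascular = FALSE,
    diabetes = FALSE,
    prior_pelvic_surgery = FALSE,
    past_failed_colonoscopy = FALSE,
    failed_reason = "none",
    procedure_type = "colonoscopy",
    indication = "intermediate",
    endoscopist_type = "gastrointestinal",
    designated_endoscopist = NA_character_,
    admission_date = -10L,
    due_date = 5L,
    actual_minutes = 16,
    predicted_minutes = 16,
    appointment_minutes = NA_real_
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(data.frame, c(lapply(base, rep_len, n),
                        list(stringsAsFactors = FALSE)))
}

# A rectangular roster + calendar: n_e providers x n_d days x block minutes.
make_unit <- function(n_e, n_d, block = 390, accepts = TRUE) {
  roster <- data.frame(
    id = sprintf("E%02d", seq_len(n_e)),
    specialty = "gastrointestinal",
    accepts_non_nominative = rep_len(accepts, n_e),
    compatible_procedures = "colonoscopy;gastroscopy;other",
    stringsAsFactors = FALSE)
  calendar <- expand.grid(endoscopist_id = roster$id, day = seq_len(n_d),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  calendar$block_minutes <- block
  list(roster = roster, calendar = calendar)
}

# A random small assignment instance with at most `max_vars` binary
# variables, for oracle-equivalence checks.
random_small_instance <- function(seed, max_vars = 20L) {
  set.seed(seed)
  n_e <- sample(1:2, 1)
  n_d <- sample(1:3, 1)
  n_p <- sample(1:5, 1)
  while (n_p * n_e * n_d > max_vars) n_p <- n_p - 1L
  unit <- make_unit(n_e, n_d, block = 0)
  unit$calendar$block_minutes <- sample(c(0, 40, 60, 90),
                                        nrow(unit$calendar), replace = TRUE)
  cohort <- make_patients(n_p,
                          due_date = sample(-2:3, n_p, replace = TRUE),
                          appointment_minutes = round(runif(n_p, 15, 80)))
  suppressWarnings(build_instance(cohort, unit$roster, unit$calendar))
}

# Duration generator in which only procedure type and respiratory disease
# carry signal.
signal_only_params <- function() {
  duration_params(beta_procedure = c(colonoscopy = 0, gastroscopy = -0.55,
                                     other = 0.35),
                  beta_respiratory = 0.4,
                  beta_diabetes = 0)
}
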