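# Shared fixtures and independent oracles used across the test files.

# --- fixture configs -----------------------------------------------------

# clean pipeline config: no measurement noise, every lesion measurable,
# so the table path reproduces the generator's true volumes exactly
clean_config <- function(n = 30, seed = 1, ...) {
  cohort_config(n_patients = n, seed = seed, modality_noise_sd = 0,
                single_modality_prob = 0, unmeasurable_prob = 0, ...)
}

# planted binary SOG-event hazard (SOG > 0 steps the hazard by HR 8.42)
recovery_config <- function(seed, n = 500, hr = 8.42) {
  clean_config(n = n, seed = seed,
               log_hr_per_100mm3_sog = 0, log_hr_per_log10_ttv = 0,
               log_hr_sog_event = log(hr), sog_event_cutoff = 0,
               baseline_progression_hazard_per_month = 0.003)
}

# sharp-step mechanism at SOG > 114 mm^3/month: three deterministic growth
# components (stable, slow intermediate crossing 114 at the 4th MRI, fast
# grower) on an exact 13-month grid, so the candidate cutoffs form point
# masses around the planted threshold
step_config <- function(seed, n = 500) {
  cohort_config(n_patients = n, seed = seed,
                median_visit_interval_months = 13,
                visit_interval_dispersion = 0,
                mean_visits_per_patient = 4.2,
                baseline_lesion_rate = 1.2, zero_lesion_fraction = 0.25,
                baseline_log_volume_mean = log(11800),
                baseline_log_volume_sd = 0,
                growth_rate_mixture = data.frame(
                  weight = c(0.40, 0.30, 0.30),
                  mean = c(0, log(1.105) / 13, 0.2),
                  sd = c(0, 0, 0)),
                new_lesion_rate_per_year = 0, unmeasurable_prob = 0,
                modality_noise_sd = 0, single_modality_prob = 0,
                log_hr_per_100mm3_sog = 0, log_hr_per_log10_ttv = 0,
                log_hr_sog_event = log(52.7), sog_event_cutoff = 114,
                baseline_progression_hazard_per_month = 0.0015)
}

run_pipeline <- function(cohort) {
  series <- biomarker_series(suppressWarnings(
    visit_volumes(cohort$lesion_table)))
  list(series = series, outcomes = outcome_records(cohort$clinical_table))
}

# small hand-built lesion table: one patient, volumes chosen for easy
# mental arithmetic
toy_lesion_table <- function() {
  data.frame(
    patient_id = "P1",
    visit_months = rep(c(0, 10, 20, 30), each = 2),
    lesion_id = rep(c("L1", "L2"), 4),
    vol_t1_mm3 = c(400, 900, 500, 1100, NA, 1300, 800, 1500),
    vol_t2_mm3 = c(600, 900, 500, 1100, NA, 1300, 800, 1500),
    measurable = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

# --- independent oracles -------------------------------------------------

# direct product-limit computation (loop over the risk-set definition,
# kept deliberately separate from the package implementation)
oracle_km <- function(time, status, at) {
  s <- 1
  for (t in sort(unique(time[status == 1]))) {
    if (t > at) break
    s <- s * (1 - sum(time == t & status == 1) / sum(time >= t))
  }
  s
}

# brute-force partial likelihood for right-censored data without ties,
# one covariate; maximized by stats::optimize
oracle_cox_coef <- function(time, status, x) {
  negll <- function(b) {
    ll <- 0
    for (i in which(status == 1)) {
      rs <- which(time >= time[i])
      ll <- ll + b * x[i] - log(sum(exp(b * x[rs])))
    }
    -ll
  }
  stats::optimize(negll, c(-10, 10), tol = 1e-9)$minimum
}

# Holm step-down straight from the definition
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (j in seq_len(m)) {
    running <- max(running, min(1, (m - j + 1) * p[ord[j]]))
    adj[ord[j]] <- running
  }
  adj
}
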