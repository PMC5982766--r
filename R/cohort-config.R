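#' Configuration for the synthetic SMM cohort generator
#'
#' Bundles every tunable of the cohort simulator with validation.  The
#' defaults emulate the structure of a retrospective longitudinal SMM
#' imaging cohort: 63 patients, a median inter-MRI interval of 13 months,
#' on average about 3.5 MRIs per patient (so roughly 220 MRIs in total), a
#' minority of patients with a single MRI, around 20% cohort-level
#' progression within 2 years, and a small number of deaths as competing
#' events.
#'
#' @param n_patients number of patients to simulate.
#' @param median_visit_interval_months median gap between consecutive MRIs;
#'   gaps are drawn log-normal so that the median equals this value.
#' @param visit_interval_dispersion log-scale standard deviation of the
#'   inter-visit gaps; 0 makes every gap exactly the median.
#' @param mean_visits_per_patient mean number of *scheduled* MRIs per
#'   patient; counts are `1 + Poisson(mean - 1)`, so every patient has at
#'   least one MRI and single-MRI patients occur naturally.  Visits
#'   scheduled after the outcome are truncated, so the observed mean is
#'   lower (the default yields about 200 observed MRIs for 63 patients).
#' @param baseline_lesion_rate Poisson mean of the baseline focal-lesion
#'   count for patients that are not structural zeros.
#' @param zero_lesion_fraction probability that a patient carries no focal
#'   lesions at all (structural zero of the zero-inflated Poisson).
#' @param baseline_log_volume_mean,baseline_log_volume_sd log-normal
#'   parameters of baseline lesion volumes, log mm^3.
#' @param growth_rate_mixture data frame with columns `weight`, `mean`,
#'   `sd`: a finite normal mixture for the patient-level monthly
#'   exponential (log) growth rate of lesion volumes.  Weights must sum to
#'   1.  The defaults are a convention (no per-lesion growth-rate
#'   distribution is published for SMM focal lesions): a stable/shrinking
#'   component and a growing component.
#' @param new_lesion_rate_per_year Poisson-process rate of newly appearing
#'   lesions per patient-year; new lesions enter at the 5 mm detection
#'   boundary (65.45 mm^3) with a small log-normal jitter.
#' @param unmeasurable_prob per lesion-visit probability that the lesion is
#'   flagged unmeasurable (exercises carry-forward); flags are independent,
#'   so a lesion may become measurable again later.
#' @param modality_noise_sd log-scale sd of independent T1/T2 measurement
#'   noise around the true lesion volume.
#' @param single_modality_prob probability that a measurable lesion-visit
#'   was measured in only one of T1/T2.
#' @param baseline_progression_hazard_per_month cause-specific baseline
#'   hazard of progression.
#' @param log_hr_per_100mm3_sog log hazard ratio of progression per
#'   100 mm^3/month of current SOG.
#' @param log_hr_per_log10_ttv log hazard ratio per tenfold TTV increase
#'   (covariate is log10(TTV + 1)).
#' @param log_hr_sog_event log hazard ratio applied once the patient's SOG
#'   has exceeded `sog_event_cutoff` at some MRI (a planted step mechanism
#'   for recovery experiments; 0 disables it).
#' @param sog_event_cutoff SOG threshold (mm^3/month, strict `>`) for the
#'   step mechanism.
#' @param death_hazard_per_month constant hazard of death without prior
#'   progression (the competing event).
#' @param admin_censor_months administrative censoring time.
#' @param mprotein_mean,mprotein_sd normal parameters of baseline serum
#'   M-protein in g/l.
#' @param lab_growth_correlation correlation between the patient's latent
#'   growth rate and the lab values (default 0 = independent labs).
#' @param seed integer seed; identical `(config, seed)` pairs reproduce
#'   identical cohorts.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_patients = 10, seed = 42)
#' cohort <- generate_cohort(cfg)
#' head(cohort$lesion_table)
#' @export
cohort_config <- function(n_patients = 63L,
                          median_visit_interval_months = 13,
                          visit_interval_dispersion = 0.45,
                          mean_visits_per_patient = 5,
                          baseline_lesion_rate = 2.2,
                          zero_lesion_fraction = 0.35,
                          baseline_log_volume_mean = log(500),
                          baseline_log_volume_sd = 1.0,
                          growth_rate_mixture = data.frame(
                            weight = c(0.55, 0.45),
                            mean   = c(0.000, 0.060),
                            sd     = c(0.006, 0.025)),
                          new_lesion_rate_per_year = 0.35,
                          unmeasurable_prob = 0.04,
                          modality_noise_sd = 0.02,
                          single_modality_prob = 0.05,
                          baseline_progression_hazard_per_month = 0.0020,
                          log_hr_per_100mm3_sog = log(1.37),
                          log_hr_per_log10_ttv = log(1.65),
                          log_hr_sog_event = 0,
                          sog_event_cutoff = 0,
                          death_hazard_per_month = 0.0005,
                          admin_censor_months = 56,
                          mprotein_mean = 15,
                          mprotein_sd = 8,
                          lab_growth_correlation = 0,
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    median_visit_interval_months = median_visit_interval_months,
    visit_interval_dispersion = visit_interval_dispersion,
    mean_visits_per_patient = mean_visits_per_patient,
    baseline_lesion_rate = baseline_lesion_rate,
    zero_lesion_fraction = zero_lesion_fraction,
    baseline_log_volume_mean = baseline_log_volume_mean,
    baseline_log_volume_sd = baseline_log_volume_sd,
    growth_rate_mixture = as.data.frame(growth_rate_mixture),
    new_lesion_rate_per_year = new_lesion_rate_per_year,
    unmeasurable_prob = unmeasurable_prob,
    modality_noise_sd = modality_noise_sd,
    single_modality_prob = single_modality_prob,
    baseline_progression_hazard_per_month = baseline_progression_hazard_per_month,
    log_hr_per_100mm3_sog = log_hr_per_100mm3_sog,
    log_hr_per_log10_ttv = log_hr_per_log10_ttv,
    log_hr_sog_event = log_hr_sog_event,
    sog_event_cutoff = sog_event_cutoff,
    death_hazard_per_month = death_hazard_per_month,
    admin_censor_months = admin_censor_months,
    mprotein_mean = mprotein_mean,
    mprotein_sd = mprotein_sd,
    lab_growth_correlation = lab_growth_correlation,
    seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 1L)
    stop_sogrisk("n_patients must be a positive integer",
                 class = "sogrisk_config_error")
  assert_pos(cfg$median_visit_interval_months, "median_visit_interval_months")
  assert_pos(cfg$visit_interval_dispersion, "visit_interval_dispersion",
             strict = FALSE)
  if (cfg$mean_visits_per_patient < 1)
    stop_sogrisk("mean_visits_per_patient must be >= 1",
                 class = "sogrisk_config_error")
  assert_pos(cfg$baseline_lesion_rate, "baseline_lesion_rate", strict = FALSE)
  assert_prob(cfg$zero_lesion_fraction, "zero_lesion_fraction")
  assert_prob(cfg$unmeasurable_prob, "unmeasurable_prob")
  assert_prob(cfg$single_modality_prob, "single_modality_prob")
  assert_pos(cfg$modality_noise_sd, "modality_noise_sd", strict = FALSE)
  mix <- cfg$growth_rate_mixture
  if (!all(c("weight", "mean", "sd") %in% names(mix)) || nrow(mix) < 1L)
    stop_sogrisk("growth_rate_mixture needs columns weight, mean, sd",
                 class = "sogrisk_config_error")
  if (any(mix$weight < 0) || abs(sum(mix$weight) - 1) > 1e-9)
    stop_sogrisk("growth_rate_mixture weights must be nonnegative and sum to 1",
                 class = "sogrisk_config_error")
  if (any(mix$sd < 0))
    stop_sogrisk("growth_rate_mixture sds must be nonnegative",
                 class = "sogrisk_config_error")
  assert_pos(cfg$new_lesion_rate_per_year, "new_lesion_rate_per_year",
             strict = FALSE)
  assert_pos(cfg$baseline_progression_hazard_per_month,
             "baseline_progression_hazard_per_month", strict = FALSE)
  assert_pos(cfg$death_hazard_per_month, "death_hazard_per_month",
             strict = FALSE)
  assert_pos(cfg$admin_censor_months, "admin_censor_months")
  if (abs(cfg$lab_growth_correlation) > 1)
    stop_sogrisk("lab_growth_correlation must be in [-1, 1]",
                 class = "sogrisk_config_error")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d patients, median MRI interval %.1f mo, ~%.2f visits/patient\n",
              x$n_patients, x$median_visit_interval_months,
              x$mean_visits_per_patient))
  cat(sprintf("  baseline progression hazard %.4g/mo, death hazard %.4g/mo, censor %.0f mo\n",
              x$baseline_progression_hazard_per_month,
              x$death_hazard_per_month, x$admin_censor_months))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# mean and sd of the growth-rate mixture (used to correlate labs)
mixture_moments <- function(mix) {
  m <- sum(mix$weight * mix$mean)
  v <- sum(mix$weight * (mix$sd^2 + mix$mean^2)) - m^2
  list(mean = m, sd = sqrt(max(v, 0)))
}
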