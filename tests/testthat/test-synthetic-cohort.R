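# Cohort generator: schedules, lesion dynamics, outcome sampling,
# determinism, agreement with closed forms.

test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(median_visit_interval_months = 0),
               class = "sogrisk_config_error")
  expect_error(cohort_config(zero_lesion_fraction = 1.2),
               class = "sogrisk_config_error")
  expect_error(cohort_config(growth_rate_mixture = data.frame(
    weight = c(0.5, 0.6), mean = c(0, 0), sd = c(0, 0))),
    class = "sogrisk_config_error")
  expect_error(cohort_config(baseline_progression_hazard_per_month = -1),
               class = "sogrisk_config_error")
})

test_that("visit schedules: degenerate dispersion, patient count, gap median", {
  cfg <- cohort_config(n_patients = 63, visit_interval_dispersion = 0,
                       mean_visits_per_patient = 4)
  sched <- with_seed(1, simulate_visit_schedule(cfg))
  expect_length(sched, 63)
  gaps <- unlist(lapply(sched, diff))
  expect_true(all(abs(gaps - 13) < 1e-12))
  expect_true(all(vapply(sched, function(v) v[1] == 0, logical(1))))

  # log-normal parameterization: empirical median of ~10,000 gaps within
  # 5% of the configured 13 months
  cfg2 <- cohort_config(n_patients = 2500, mean_visits_per_patient = 5)
  gaps2 <- unlist(lapply(with_seed(2, simulate_visit_schedule(cfg2)), diff))
  expect_gt(length(gaps2), 8000)
  expect_lt(abs(stats::median(gaps2) - 13) / 13, 0.05)
})

test_that("lesion dynamics honor degenerate configs", {
  cfg <- cohort_config(zero_lesion_fraction = 1,
                       new_lesion_rate_per_year = 0)
  co <- generate_cohort(cfg)
  expect_true(all(is.na(co$lesion_table$lesion_id)))

  # zero growth, no arrivals, no noise: TTV constant, SOG identically 0
  cfg2 <- clean_config(n = 15, seed = 3,
                       growth_rate_mixture = data.frame(weight = 1, mean = 0,
                                                        sd = 0),
                       new_lesion_rate_per_year = 0)
  pl <- run_pipeline(generate_cohort(cfg2))
  sog <- pl$series$sog_mm3_month
  expect_true(all(abs(sog[!is.na(sog)]) < 1e-9))
  for (pid in unique(pl$series$patient_id)) {
    ttv <- pl$series$ttv_mm3[pl$series$patient_id == pid]
    expect_true(all(abs(ttv - ttv[1]) < 1e-6))
  }
})

test_that("all-zero hazards censor everyone at the administrative limit", {
  cfg <- clean_config(n = 25, seed = 4,
                      baseline_progression_hazard_per_month = 0,
                      death_hazard_per_month = 0)
  co <- generate_cohort(cfg)
  expect_true(all(co$clinical_table$outcome_cause == "censored"))
  expect_true(all(co$clinical_table$outcome_months == cfg$admin_censor_months))
})

test_that("competing-exponential cumulative incidence matches the closed form", {
  # with both regression terms 0 and no lesions, progression and death are
  # two competing exponentials: CIF_prog(t) = lp/(lp+ld) (1 - exp(-(lp+ld)t))
  lp <- 0.02; ld <- 0.01; horizon <- 24
  cfg <- cohort_config(n_patients = 1, zero_lesion_fraction = 1,
                       log_hr_per_100mm3_sog = 0, log_hr_per_log10_ttv = 0,
                       baseline_progression_hazard_per_month = lp,
                       death_hazard_per_month = ld,
                       admin_censor_months = 120)
  n <- 10000
  res <- with_seed(99, {
    dyn <- list(growth_rate = 0,
                lesions = data.frame(lesion_id = character(0),
                                     birth_months = numeric(0),
                                     v0_mm3 = numeric(0)),
                measurable = matrix(TRUE, 0, 1))
    t(vapply(seq_len(n), function(i) {
      o <- simulate_outcomes(0, dyn, cfg)
      c(o$time_months, o$cause)
    }, numeric(2)))
  })
  emp <- mean(res[, 1] <= horizon & res[, 2] == 1)
  theo <- lp / (lp + ld) * (1 - exp(-(lp + ld) * horizon))
  expect_lt(abs(emp - theo), 3 * sqrt(theo * (1 - theo) / n) + 0.005)
})

test_that("fraction of patients ever exceeding SOG 114 matches the analytic value", {
  # degenerate sub-distributions make the crossing probability exact:
  # fixed lesion volume v0, fixed growth g, exact 13-month grid, no
  # arrivals; a patient crosses iff lesion count k >= k* and >= 2 visits
  v0 <- 3000; g <- 0.05
  cfg <- cohort_config(n_patients = 4000, seed = 1,
                       visit_interval_dispersion = 0,
                       mean_visits_per_patient = 4,
                       baseline_lesion_rate = 1.5, zero_lesion_fraction = 0.3,
                       baseline_log_volume_mean = log(v0),
                       baseline_log_volume_sd = 0,
                       growth_rate_mixture = data.frame(weight = 1, mean = g,
                                                        sd = 0),
                       new_lesion_rate_per_year = 0, unmeasurable_prob = 0,
                       modality_noise_sd = 0, single_modality_prob = 0,
                       baseline_progression_hazard_per_month = 0,
                       death_hazard_per_month = 0)
  sog1 <- v0 * (exp(g * 13) - 1) / 13          # per-lesion first-interval SOG
  kstar <- ceiling(114 / sog1)
  p_k <- (1 - cfg$zero_lesion_fraction) *
    stats::ppois(kstar - 1, cfg$baseline_lesion_rate, lower.tail = FALSE)
  p_2v <- 1 - stats::dpois(0, cfg$mean_visits_per_patient - 1)
  theo <- p_k * p_2v
  pl <- run_pipeline(generate_cohort(cfg))
  crossed <- tapply(pl$series$sog_mm3_month, pl$series$patient_id,
                    function(s) any(s[!is.na(s)] >= 114))
  emp <- mean(crossed)
  expect_lt(abs(emp - theo), 3 * sqrt(theo * (1 - theo) / cfg$n_patients))
})

test_that("identical config and seed reproduce byte-identical cohorts", {
  cfg <- cohort_config(n_patients = 12, seed = 77)
  d1 <- tempfile(); d2 <- tempfile()
  co1 <- generate_cohort(cfg, out_dir = d1)
  co2 <- generate_cohort(cfg, out_dir = d2)
  expect_identical(co1$lesion_table, co2$lesion_table)
  expect_identical(co1$clinical_table, co2$clinical_table)
  for (f in c("lesions.csv", "clinical.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("voxelized spheres match their nominal volume within one voxel", {
  o <- sogrisk:::sphere_voxel_offsets(4188.79, c(1, 1, 1))
  expect_lte(abs(nrow(o) - 4188.79), 1)
  o2 <- sogrisk:::sphere_voxel_offsets(1000, c(2, 2, 2))
  expect_lte(abs(nrow(o2) * 8 - 1000), 8)
})

test_that("default cohort reproduces the intended 2-year progression band", {
  # cohort-level 2-year progression around 20%, averaged over seeds
  p2 <- vapply(1:12, function(s) {
    out <- outcome_records(generate_cohort(cohort_config(seed = s))$clinical_table)
    cif_at(aalen_johansen(out$time_months, out$cause), 24)
  }, numeric(1))
  expect_gte(mean(p2), 0.15)
  expect_lte(mean(p2), 0.25)
})
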