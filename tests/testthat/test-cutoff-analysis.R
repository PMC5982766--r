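# Cutoff sweep, selection and reporting.

test_that("event anchoring: event clock, last-MRI rule, exclusion guard", {
  ser <- data.frame(patient_id = c("A", "A", "B", "B"),
                    visit_months = c(0, 10, 0, 40), ttv_mm3 = 1,
                    n_fl = 1L, stringsAsFactors = FALSE)
  ev <- data.frame(patient_id = c("A", "B"),
                   event_time_months = c(10, NA),
                   event_visit_index = c(2L, NA))
  out <- data.frame(patient_id = c("A", "B"), time_months = c(22, 46),
                    cause = c(1L, 0L))
  an <- event_anchored_outcomes(ev, out, ser)
  expect_equal(an$anchored_time_months[an$patient_id == "A"], 12)
  expect_equal(an$anchored_time_months[an$patient_id == "B"], 6)
  expect_true(an$positive[an$patient_id == "A"])
  expect_false(an$positive[an$patient_id == "B"])

  out2 <- out; out2$time_months[1] <- 8    # outcome before the anchor
  expect_warning(an2 <- event_anchored_outcomes(ev, out2, ser),
                 "at or before the anchor")
  expect_false("A" %in% an2$patient_id)
})

test_that("two-year progression rate: raw fraction, low-information, AJ oracle", {
  # 10 patients, 8 progress within 24 months, 2 at 30, no censoring
  t <- c(seq(2, 23, length.out = 8), 30, 30)
  expect_equal(two_year_progression_rate(t, rep(1L, 10))$estimate, 0.8)

  expect_warning(r <- two_year_progression_rate(c(5, 10), c(0L, 0L)),
                 "low information")
  expect_true(r$flagged)

  # with one death: equals the hand-computed Aalen-Johansen value
  tt <- c(6, 12, 18, 30); cc <- c(1L, 2L, 1L, 0L)
  # CIF_prog(24) = 1/4 + (3/4)(2/3)(1/2) = 0.5
  expect_equal(two_year_progression_rate(tt, cc)$estimate, 0.5)
})

test_that("sweep: candidate set, monotonicity, selection scan", {
  pl <- run_pipeline(generate_cohort(clean_config(n = 40, seed = 13)))
  sw <- sweep_cutoffs(pl$series, pl$outcomes, "sog_mm3_month")
  vals <- pl$series$sog_mm3_month
  expect_equal(nrow(sw), length(unique(vals[!is.na(vals)])))
  # n_positive non-increasing in the cutoff
  expect_true(all(diff(sw$n_positive) <= 0))
  expect_true(all(sw$p_holm >= sw$p_raw, na.rm = TRUE))

  # selection equals a brute-force scan of the result list
  sel <- select_cutoff(sw, target = 0.5)
  ok <- which(!is.na(sw$two_year_pr) & sw$two_year_pr >= 0.5 &
                !is.na(sw$p_holm) & sw$p_holm < 0.05)
  if (length(ok) == 0) {
    expect_null(sel)
  } else {
    expect_equal(sel$cutoff, min(sw$cutoff[ok]))
  }

  # raising the target never lowers the selected cutoff
  s1 <- select_cutoff(sw, target = 0.5)
  s2 <- select_cutoff(sw, target = 0.9)
  if (!is.null(s1) && !is.null(s2)) expect_gte(s2$cutoff, s1$cutoff)
})

test_that("degenerate constant track yields an empty sweep with a warning", {
  ser <- data.frame(patient_id = rep(c("A", "B"), each = 2),
                    visit_months = c(0, 12, 0, 12), ttv_mm3 = 500,
                    n_fl = 1L, stringsAsFactors = FALSE)
  ser$lesion_ids <- replicate(4, "L1", simplify = FALSE)
  ser <- biomarker_series(ser)
  out <- data.frame(patient_id = c("A", "B"), time_months = c(30, 40),
                    cause = c(1L, 0L))
  expect_warning(sw <- sweep_cutoffs(ser, out, "sog_mm3_month"),
                 "degenerate")
  expect_equal(nrow(sw), 0)
})

test_that("single-cutoff evaluation agrees with the vectorized sweep", {
  pl <- run_pipeline(generate_cohort(clean_config(n = 40, seed = 14)))
  sw <- sweep_cutoffs(pl$series, pl$outcomes, "sog_mm3_month")
  mid <- sw$cutoff[round(nrow(sw) / 2)]
  one <- sogrisk:::sweep_cutoffs_at(pl$series, pl$outcomes, "sog_mm3_month",
                                    mid, ">=", 24, "second-mri", "cox",
                                    "efron")
  ref <- sw[sw$cutoff == mid, ]
  expect_equal(one$n_positive, ref$n_positive)
  expect_equal(one$two_year_pr, ref$two_year_pr, tolerance = 1e-10)
  expect_equal(one$p_raw, ref$p_raw, tolerance = 1e-6)
  expect_equal(one$sensitivity, ref$sensitivity, tolerance = 1e-10)
  expect_equal(one$fpr, ref$fpr, tolerance = 1e-10)
})

test_that("comparison report: row structure, assessed counts, serialization", {
  pl <- run_pipeline(generate_cohort(clean_config(n = 45, seed = 15)))
  rep <- biomarker_comparison_report(pl$series, pl$outcomes)
  expect_s3_class(rep, "biomarker_report")
  expect_equal(rep$biomarkers$biomarker,
               c("imwg_gt1fl", "nfl", "dev_nfl", "ttv", "sog"))
  n_all <- length(unique(pl$series$patient_id))
  nv <- table(pl$series$patient_id)
  n_dyn <- sum(nv >= 2)
  expect_equal(rep$biomarkers$n_assessed[rep$biomarkers$biomarker == "ttv"],
               n_all)
  expect_equal(rep$biomarkers$n_assessed[rep$biomarkers$biomarker == "sog"],
               n_dyn)
  expect_equal(rep$c_index$biomarker, c("nfl", "dev_nfl", "ttv", "sog"))
  expect_true(all(rep$c_index$c_index >= 0 & rep$c_index$c_index <= 1,
                  na.rm = TRUE))

  # JSON round-trip preserves the report content
  d <- tempfile()
  write_report(rep, d, provenance = list(seed = 15))
  back <- read_report(d)
  expect_equal(back$biomarkers$cutoff, rep$biomarkers$cutoff,
               tolerance = 1e-12)
  expect_equal(back$biomarkers$two_year_pr, rep$biomarkers$two_year_pr,
               tolerance = 1e-12)
  expect_equal(back$c_index$c_index, rep$c_index$c_index, tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})

test_that("stratified incidence: symmetry, planted difference, degenerate strata", {
  # two identical groups -> HR 1 within tolerance
  t <- rep(c(3, 6, 9, 12, 20, 30), 2)
  c0 <- rep(c(1L, 1L, 0L, 1L, 0L, 1L), 2)
  g <- rep(c("a", "b"), each = 6)
  si <- stratified_incidence(t, c0, g)
  expect_equal(si$pairwise$hr, 1, tolerance = 1e-6)

  # planted hazard difference recovered within the fitted CI
  set.seed(19)
  n <- 2000
  grp <- rep(c("no_new_fl", "new_fl"), each = n / 2)
  rate <- ifelse(grp == "new_fl", 0.02 * 1.28, 0.02)
  tt <- rexp(n, rate); cens <- runif(n, 10, 80)
  obs <- pmin(tt, cens); cc <- ifelse(tt <= cens, 1L, 0L)
  si2 <- stratified_incidence(obs, cc, grp)
  row <- si2$pairwise
  hr <- ifelse(row$group2 == "no_new_fl", 1 / row$hr, row$hr)
  lo <- ifelse(row$group2 == "no_new_fl", 1 / row$ci_upper, row$ci_lower)
  hi <- ifelse(row$group2 == "no_new_fl", 1 / row$ci_lower, row$ci_upper)
  expect_true(lo <= 1.28 && 1.28 <= hi)
  expect_equal(hr, 1.28, tolerance = 0.15)

  # strata without events give flat zero curves and flagged comparisons
  si3 <- stratified_incidence(rep(10, 8), rep(0L, 8),
                              rep(c("a", "b", "c", "d"), 2))
  expect_length(si3$cif, 4)
  for (cf in si3$cif) expect_equal(nrow(cf), 0)
})
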