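# Hand-implemented estimators against closed forms, brute-force oracles
# and the reference implementations in survival/cmprsk.

test_that("Kaplan-Meier matches the product-limit definition", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km_at(km, 2.5), 0.5)
  expect_equal(km_at(kaplan_meier(c(5, 8, 9), c(0, 0, 0)), 100), 1)
  expect_error(kaplan_meier(numeric(0), numeric(0)),
               class = "sogrisk_data_error")

  set.seed(31)
  time <- round(rexp(40, 0.1), 1); status <- rbinom(40, 1, 0.6)
  km2 <- kaplan_meier(time, status)
  for (at in c(2, 7, 15, 40))
    expect_equal(km_at(km2, at), oracle_km(time, status, at))
})

test_that("Aalen-Johansen: hand example, single-cause reduction, degenerate cases", {
  # {1: progression, 2: death, 3: progression, 4: censored}
  aj <- aalen_johansen(c(1, 2, 3, 4), c(1L, 2L, 1L, 0L))
  expect_equal(cif_at(aj, 3), 0.5)
  expect_equal(cif_at(aj, 2, cause = 2), 0.25)
  expect_equal(cif_at(aj, 1), 0.25)

  # no competing deaths: CIF_1 = 1 - KM exactly
  set.seed(5)
  time <- rexp(60, 0.05); cause <- rbinom(60, 1, 0.7)
  aj2 <- aalen_johansen(time, as.integer(cause))
  km <- kaplan_meier(time, cause)
  for (at in c(5, 12, 30, 80))
    expect_equal(cif_at(aj2, at), 1 - km_at(km, at), tolerance = 1e-12)

  # all censored: CIF identically 0
  aj3 <- aalen_johansen(c(3, 6, 9), c(0L, 0L, 0L))
  expect_equal(cif_at(aj3, 100), 0)
  expect_error(aalen_johansen(1, 5L), class = "sogrisk_data_error")
})

test_that("Aalen-Johansen CIFs sum to at most 1 and match cmprsk", {
  skip_if_not_installed("cmprsk")
  set.seed(17)
  time <- rexp(80, 0.04)
  cause <- sample(0:2, 80, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  aj <- aalen_johansen(time, as.integer(cause))
  expect_true(all(aj$cif1 + aj$cif2 <= 1 + 1e-12))
  expect_true(all(diff(aj$cif1) >= -1e-12))
  ref <- cmprsk::cuminc(time, cause, cencode = 0)
  at <- c(10, 25, 50)
  expect_equal(cif_at(aj, at),
               as.numeric(cmprsk::timepoints(ref["1 1"], at)$est),
               tolerance = 1e-10)
  expect_equal(cif_at(aj, at, cause = 2),
               as.numeric(cmprsk::timepoints(ref["1 2"], at)$est),
               tolerance = 1e-10)
})

test_that("Cox: symmetry and location invariance", {
  # two groups with mirror-image event patterns -> coefficient 0
  rows <- data.frame(patient_id = 1:8, start = 0,
                     stop = c(1, 2, 3, 4, 1, 2, 3, 4),
                     cause = 1L, x = c(0, 1, 0, 1, 1, 0, 1, 0))
  fit <- cox_cause_specific(rows, "x")
  expect_equal(unname(fit$coef), 0, tolerance = 1e-8)

  set.seed(23)
  rows2 <- data.frame(patient_id = 1:30, start = 0,
                      stop = sort(runif(30, 1, 50)),
                      cause = sample(c(0L, 1L), 30, replace = TRUE),
                      x = rnorm(30))
  rows3 <- rows2; rows3$x <- rows3$x + 100
  f2 <- cox_cause_specific(rows2, "x")
  f3 <- cox_cause_specific(rows3, "x")
  expect_equal(unname(f2$coef), unname(f3$coef), tolerance = 1e-6)
})

test_that("Cox maximizer matches a brute-force partial-likelihood oracle", {
  set.seed(41)
  checked <- 0
  while (checked < 6) {
    n <- sample(4:8, 1)
    time <- sort(runif(n, 1, 20)) + seq_len(n) * 1e-4   # no ties
    status <- rbinom(n, 1, 0.7)
    x <- rbinom(n, 1, 0.5)
    if (sum(status) < 2 || length(unique(x)) < 2) next
    b_oracle <- oracle_cox_coef(time, status, x)
    if (abs(b_oracle) > 8) next                         # monotone likelihood
    rows <- data.frame(patient_id = 1:n, start = 0, stop = time,
                       cause = as.integer(status), x = x)
    fit <- cox_cause_specific(rows, "x")
    expect_equal(unname(fit$coef), b_oracle, tolerance = 1e-4)
    checked <- checked + 1
  }
})

test_that("Cox agrees with survival::coxph under ties, both tie methods", {
  skip_if_not_installed("survival")
  set.seed(42)
  n <- 50
  rows <- data.frame(patient_id = 1:n, start = 0,
                     stop = sample(1:12, n, replace = TRUE),
                     cause = sample(c(0L, 1L, 1L, 2L), n, replace = TRUE),
                     x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  for (tie in c("efron", "breslow")) {
    fit <- cox_cause_specific(rows, c("x1", "x2"), ties = tie)
    ref <- survival::coxph(survival::Surv(stop, cause == 1) ~ x1 + x2,
                           data = rows, ties = tie)
    expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-7)
  }
})

test_that("Cox flags complete separation instead of failing silently", {
  rows <- data.frame(patient_id = 1:6, start = 0, stop = 1:6,
                     cause = c(1L, 1L, 1L, 0L, 0L, 0L),
                     x = c(1, 1, 1, 0, 0, 0))
  fit <- cox_cause_specific(rows, "x")
  expect_true(fit$flagged)
})

test_that("concordance: perfect order, reversal, null behavior", {
  n <- 12
  rows <- data.frame(patient_id = 1:n, start = 0, stop = 1:n, cause = 1L,
                     m = n:1)     # higher marker -> earlier event
  expect_equal(harrell_c_td(rows, "m")$c_index, 1)
  rows$m <- 1:n
  expect_equal(harrell_c_td(rows, "m")$c_index, 0)

  set.seed(8)
  n <- 200
  rows2 <- data.frame(patient_id = 1:n, start = 0,
                      stop = rexp(n, 0.05) + 0.01,
                      cause = sample(c(0L, 1L), n, replace = TRUE),
                      m = rnorm(n))
  cc <- harrell_c_td(rows2, "m")$c_index
  expect_gt(cc, 0.45); expect_lt(cc, 0.55)

  # no comparable pairs -> flagged
  single <- data.frame(patient_id = 1, start = 0, stop = 5, cause = 1L, m = 1)
  expect_true(harrell_c_td(single, "m")$flagged)
})

test_that("td sensitivity/FPR reduce to raw proportions without censoring", {
  # 10 patients: 4 progress by 24 months (3 marker+), 6 do not (1 marker+)
  marker <- c(rep(TRUE, 3), FALSE, TRUE, rep(FALSE, 5))
  time <- c(10, 12, 20, 18, 60, 60, 60, 60, 60, 60)
  cause <- c(1L, 1L, 1L, 1L, rep(0L, 6))
  r <- td_sensitivity_fpr(marker, time, cause, horizon = 24)
  expect_equal(r$sensitivity, 0.75)
  expect_equal(r$fpr, 1 / 6)

  r2 <- td_sensitivity_fpr(rep(TRUE, 10), time, cause, horizon = 24)
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$fpr, 1)
})

test_that("td sensitivity/FPR compose the Bayes formula from separate CIFs", {
  set.seed(12)
  n <- 90
  marker <- rbinom(n, 1, 0.4) == 1
  time <- rexp(n, ifelse(marker, 0.06, 0.02))
  cause <- ifelse(runif(n) < 0.7, 1L, sample(c(0L, 2L), n, replace = TRUE))
  cens <- runif(n, 5, 60)
  obs <- pmin(time, cens)
  cc <- ifelse(time <= cens, cause, 0L)
  r <- td_sensitivity_fpr(marker, obs, cc, horizon = 24)
  p <- mean(marker)
  F1 <- cif_at(aalen_johansen(obs[marker], cc[marker]), 24)
  Fa <- cif_at(aalen_johansen(obs, cc), 24)
  expect_equal(r$sensitivity, p * F1 / Fa)
  expect_equal(r$fpr, p * (1 - F1) / (1 - Fa))
})

test_that("Holm: step-down formula, dominance, permutation invariance, p.adjust", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(3)
  for (rep in 1:5) {
    p <- runif(sample(3:12, 1))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_equal(adj, oracle_holm(p))
    expect_equal(adj, stats::p.adjust(p, method = "holm"))
    perm <- sample(seq_along(p))
    expect_equal(holm_adjust(p[perm]), adj[perm])
  }
  expect_error(holm_adjust(c(0.2, 1.4)), class = "sogrisk_data_error")
})

test_that("Spearman: monotone extremes, ties, agreement with cor.test", {
  x <- 1:10
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)

  x2 <- c(1, 2, 2, 3, 4, 4, 4, 7)
  y2 <- c(5, 3, 8, 1, 9, 9, 2, 6)
  r <- spearman_cor(x2, y2)
  expect_equal(r$rho, stats::cor(rank(x2), rank(y2)))
  ref <- suppressWarnings(stats::cor.test(x2, y2, method = "spearman"))
  expect_equal(r$rho, unname(ref$estimate))

  # pairwise-complete handling reports the retained n
  x3 <- c(1, 2, NA, 4, 5); y3 <- c(2, NA, 3, 8, 10)
  expect_equal(spearman_cor(x3, y3)$n, 3)
  expect_true(spearman_cor(c(1, 1, 1), c(2, 3, 4))$flagged)
})
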