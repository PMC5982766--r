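# Product-limit and Aalen-Johansen estimators, implemented directly from
# the risk-set definitions.

#' Kaplan-Meier product-limit estimator
#'
#' @param time nonnegative event/censoring times.
#' @param status 1 = event, 0 = censored.  At tied times events are
#'   handled before censorings (censored subjects at t remain in the risk
#'   set for events at t).
#' @return data frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `surv` (survival just after `time`).
#' @export
kaplan_meier <- function(time, status) {
  if (length(time) == 0L)
    stop_sogrisk("empty input", class = "sogrisk_data_error")
  if (any(time < 0)) stop_sogrisk("negative times", class = "sogrisk_data_error")
  et <- sort(unique(time[status == 1]))
  surv <- 1
  nas <- rep(NA_real_, length(et))
  out <- data.frame(time = et, n_risk = nas, n_event = nas, surv = nas)
  for (i in seq_along(et)) {
    t <- et[i]
    r <- sum(time >= t)
    d <- sum(time == t & status == 1)
    surv <- surv * (1 - d / r)
    out$n_risk[i] <- r; out$n_event[i] <- d; out$surv[i] <- surv
  }
  out
}

# step-function evaluation: value of `y` (aligned to jump times `t`) at
# `at`, with `y0` before the first jump
step_at <- function(t, y, at, y0) {
  vapply(at, function(a) {
    i <- findInterval(a, t)
    if (i == 0L) y0 else y[i]
  }, numeric(1))
}

#' Evaluate a Kaplan-Meier fit at arbitrary times
#' @param km result of [kaplan_meier()].
#' @param at numeric times.
#' @return survival probabilities.
#' @export
km_at <- function(km, at) step_at(km$time, km$surv, at, 1)

#' Aalen-Johansen cumulative incidence under competing risks
#'
#' For causes coded 1 (progression) and 2 (death), with 0 = censored:
#' `CIF_k(t) = sum over event times t_i <= t of S(t_i-) d_k(t_i)/n(t_i)`,
#' with `S` the all-cause Kaplan-Meier.  With no competing events,
#' `CIF_1 = 1 - KM` exactly.
#'
#' @param time nonnegative times.
#' @param cause integer codes 0 (censored), 1, 2.
#' @return object of class `aj_cif`: data frame with `time`, `n_risk`,
#'   `d1`, `d2`, `surv` (all-cause KM just after `time`), `cif1`, `cif2`.
#' @export
aalen_johansen <- function(time, cause) {
  if (length(time) == 0L)
    stop_sogrisk("empty input", class = "sogrisk_data_error")
  if (!all(cause %in% c(0L, 1L, 2L)))
    stop_sogrisk("cause codes must be 0 (censored), 1 or 2",
                 class = "sogrisk_data_error")
  et <- sort(unique(time[cause != 0L]))
  surv_prev <- 1
  nas <- rep(NA_real_, length(et))
  out <- data.frame(time = et, n_risk = nas, d1 = nas, d2 = nas,
                    surv = nas, cif1 = nas, cif2 = nas)
  cif1 <- 0; cif2 <- 0
  for (i in seq_along(et)) {
    t <- et[i]
    r <- sum(time >= t)
    d1 <- sum(time == t & cause == 1L)
    d2 <- sum(time == t & cause == 2L)
    cif1 <- cif1 + surv_prev * d1 / r
    cif2 <- cif2 + surv_prev * d2 / r
    surv <- surv_prev * (1 - (d1 + d2) / r)
    out[i, -1] <- c(r, d1, d2, surv, cif1, cif2)
    surv_prev <- surv
  }
  class(out) <- c("aj_cif", "data.frame")
  out
}

#' Evaluate an Aalen-Johansen CIF at arbitrary times
#' @param aj result of [aalen_johansen()].
#' @param at numeric times.
#' @param cause 1 or 2.
#' @return cumulative incidence values.
#' @export
cif_at <- function(aj, at, cause = 1L) {
  col <- if (cause == 1L) aj$cif1 else if (cause == 2L) aj$cif2 else
    stop_sogrisk("cause must be 1 or 2", class = "sogrisk_data_error")
  step_at(aj$time, col, at, 0)
}

#' Plot Aalen-Johansen cumulative incidence curves
#' @param x an `aj_cif` object.
#' @param cause which cause to draw.
#' @param ... passed to [graphics::plot.default].
#' @export
plot.aj_cif <- function(x, cause = 1L, ...) {
  y <- if (cause == 1L) x$cif1 else x$cif2
  graphics::plot(stats::stepfun(x$time, c(0, y)), do.points = FALSE,
                 xlab = "months", ylab = "cumulative incidence",
                 ylim = c(0, 1), ...)
  invisible(x)
}
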