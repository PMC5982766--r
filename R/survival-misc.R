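# Concordance, time-dependent sensitivity/FPR, Holm correction, Spearman.

#' Harrell's c-index for a time-dependent marker
#'
#' Over all event times of the cause of interest, the failing subject's
#' current marker value is compared with the current marker value of every
#' at-risk subject (higher marker expected to fail earlier).  Marker ties
#' count 0.5; subjects failing at the same time are excluded from each
#' other's comparisons.
#'
#' @param rows counting-process data frame: `patient_id`, `start`, `stop`,
#'   `cause`, and the marker column.
#' @param marker marker column name.
#' @param cause cause of interest.
#' @return list with `c_index`, `comparable`, `concordant`, `tied`;
#'   `c_index` is `NA` (flagged) when no pairs are comparable.
#' @export
harrell_c_td <- function(rows, marker, cause = 1L) {
  start <- rows$start; stop_ <- rows$stop
  status <- rows$cause == cause
  m <- rows[[marker]]
  if (any(is.na(m)))
    stop_sogrisk("marker must be defined for every row", class = "sogrisk_data_error")
  conc <- 0; tied <- 0; comp <- 0
  ev <- which(status)
  for (i in ev) {
    t <- stop_[i]
    at_risk <- which(start < t & stop_ >= t &
                     rows$patient_id != rows$patient_id[i])
    # exclude subjects failing at exactly t (time ties)
    at_risk <- at_risk[!(stop_[at_risk] == t & status[at_risk])]
    if (!length(at_risk)) next
    comp <- comp + length(at_risk)
    conc <- conc + sum(m[i] > m[at_risk])
    tied <- tied + sum(m[i] == m[at_risk])
  }
  if (comp == 0)
    return(list(c_index = NA_real_, comparable = 0, concordant = 0,
                tied = 0, flagged = TRUE))
  list(c_index = (conc + 0.5 * tied) / comp, comparable = comp,
       concordant = conc, tied = tied, flagged = FALSE)
}

#' Time-dependent sensitivity and false positive rate under censoring
#'
#' Cumulative/dynamic estimator composed by Bayes' rule from
#' Aalen-Johansen cumulative incidences:
#' `Sens(t) = p F1(t) / F(t)` and `FPR(t) = p (1 - F1(t)) / (1 - F(t))`,
#' where `p` is the marker-positive fraction, `F1` the progression CIF
#' among marker-positive patients and `F` the overall progression CIF.
#' With no censoring or competing deaths before the horizon this reduces
#' exactly to the raw proportions.
#'
#' @param marker_positive logical vector, one entry per patient.
#' @param time,cause outcome records (cause 0/1/2) aligned with
#'   `marker_positive`.
#' @param horizon evaluation time in months (default 24 = the 2-year
#'   IMWG horizon).
#' @return list with `sensitivity`, `fpr`, `p_positive`, `cif_positive`,
#'   `cif_overall`, `flagged` (TRUE when F(t) is 0 or 1 and the ratio is
#'   undefined).
#' @export
td_sensitivity_fpr <- function(marker_positive, time, cause, horizon = 24) {
  if (horizon <= 0)
    stop_sogrisk("horizon must be > 0", class = "sogrisk_config_error")
  stopifnot(length(marker_positive) == length(time),
            length(time) == length(cause))
  p <- mean(marker_positive)
  F_all <- cif_at(aalen_johansen(time, cause), horizon)
  F1 <- if (any(marker_positive))
    cif_at(aalen_johansen(time[marker_positive], cause[marker_positive]),
           horizon)
  else 0
  if (F_all <= 0 || F_all >= 1)
    return(list(sensitivity = NA_real_, fpr = NA_real_, p_positive = p,
                cif_positive = F1, cif_overall = F_all, flagged = TRUE))
  sens <- p * F1 / F_all
  fpr <- p * (1 - F1) / (1 - F_all)
  list(sensitivity = min(max(sens, 0), 1), fpr = min(max(fpr, 0), 1),
       p_positive = p, cif_positive = F1, cif_overall = F_all,
       flagged = FALSE)
}

#' Holm step-down multiple-testing correction
#'
#' Sort ascending; adjusted `p_(i) = max_{j <= i} min(1, (m - j + 1)
#' p_(j))`; returned in input order.  Adjusted values dominate the raw
#' ones and never exceed 1.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return adjusted p-values, same order as input.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_sogrisk("p-values must lie in [0, 1]", class = "sogrisk_data_error")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  ord <- ok[order(p[ok])]
  adj <- pmin(1, (m - seq_len(m) + 1) * p[ord])
  adj <- cummax(adj)
  out[ord] <- adj
  out
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of average (midrank) ranks on pairwise-complete
#' observations; the p-value uses the t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y paired numeric vectors; pairs with any `NA` are dropped and
#'   the retained `n` is reported.
#' @return list with `rho`, `p_value`, `n`; `rho` is `NA` (flagged) when
#'   fewer than 3 complete pairs remain or ranks have zero variance.
#' @export
spearman_cor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, flagged = TRUE))
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, flagged = TRUE))
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, flagged = FALSE)
}
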