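# Bridges between the clinical/biomarker tables and the counting-process
# representation consumed by the survival estimators.

#' Outcome records from a clinical table
#'
#' @param clinical_table data frame with `patient_id`, `outcome_months`,
#'   `outcome_cause` (`"censored"`, `"progression"`, `"death"`).
#' @return data frame `patient_id`, `time_months`, `cause` (0/1/2).
#' @export
outcome_records <- function(clinical_table) {
  data.frame(patient_id = clinical_table$patient_id,
             time_months = clinical_table$outcome_months,
             cause = cause_from_label(clinical_table$outcome_cause),
             stringsAsFactors = FALSE)
}

#' Counting-process rows with time-dependent biomarker covariates
#'
#' Expands each patient into intervals `[t_i, t_{i+1})` on the MRI visit
#' grid (last interval closing at the outcome time), carrying the
#' biomarker values known at the interval's opening visit.  Dynamic
#' tracks (SOG, new FL/year) are 0 before their first defined visit — no
#' growth information has been observed yet.  Event-indicator covariates
#' (0 before, 1 from the first threshold crossing) can be added from
#' [detect_event()] results.
#'
#' @param series output of [biomarker_series()].
#' @param outcomes output of [outcome_records()].
#' @param covariates track columns of `series` to carry.
#' @param events named list of [detect_event()] results; each adds an
#'   indicator column of that name.
#' @return data frame `patient_id`, `start`, `stop`, `cause`, one column
#'   per covariate/indicator.  Patients whose outcome precedes their
#'   first visit interval are dropped.
#' @export
counting_rows <- function(series, outcomes, covariates = character(0),
                          events = list()) {
  out <- list()
  for (pid in unique(series$patient_id)) {
    rows <- which(series$patient_id == pid)
    rows <- rows[order(series$visit_months[rows])]
    o <- outcomes[outcomes$patient_id == pid, , drop = FALSE]
    if (nrow(o) != 1L) next
    t_out <- o$time_months
    vt <- series$visit_months[rows]
    k <- length(vt)
    start <- vt
    stop_ <- c(pmin(vt[-1L], t_out), t_out)
    keep <- start < stop_
    if (!any(keep)) next
    cause <- ifelse(stop_ < t_out, 0L, o$cause)
    res_p <- data.frame(patient_id = rep(pid, sum(keep)),
                        start = start[keep], stop = stop_[keep],
                        cause = cause[keep], stringsAsFactors = FALSE)
    for (cn in covariates) {
      v <- as.numeric(series[[cn]][rows])
      v[is.na(v)] <- 0
      res_p[[cn]] <- v[keep]
    }
    for (en in names(events)) {
      et <- events[[en]]$event_time_months[events[[en]]$patient_id == pid]
      on <- length(et) == 1L && !is.na(et)
      res_p[[en]] <- as.numeric(on & start[keep] >= (if (on) et else Inf))
    }
    out[[length(out) + 1L]] <- res_p
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
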