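# Cutoff sweep and selection against the IMWG >=80% two-year-progression
# criterion, biomarker-event anchored outcome clocks, and the biomarker
# comparison report.

#' Anchor outcome times at the biomarker event
#'
#' For event-positive patients the clock starts at the MRI with the
#' biomarker event; event-free patients are anchored at their last MRI.
#' Causes are preserved.  Patients whose outcome precedes the anchor
#' (impossible by construction in simulated data) are excluded with a
#' warning.
#'
#' @param events result of [detect_event()].
#' @param outcomes result of [outcome_records()].
#' @param series the [biomarker_series()] (supplies each patient's last
#'   MRI time).
#' @return data frame `patient_id`, `anchored_time_months`, `cause`,
#'   `positive`.
#' @export
event_anchored_outcomes <- function(events, outcomes, series) {
  last_mri <- tapply(series$visit_months, series$patient_id, max)
  df <- merge(events, outcomes, by = "patient_id")
  anchor <- ifelse(is.na(df$event_time_months),
                   as.numeric(last_mri[df$patient_id]),
                   df$event_time_months)
  out <- data.frame(patient_id = df$patient_id,
                    anchored_time_months = df$time_months - anchor,
                    cause = df$cause,
                    positive = !is.na(df$event_time_months),
                    stringsAsFactors = FALSE)
  bad <- out$anchored_time_months <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d patient(s) with outcome at or before the anchor: %s",
                    sum(bad), paste(out$patient_id[bad], collapse = ", ")),
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Two-year progression rate from biomarker-event onset
#'
#' Aalen-Johansen cumulative incidence of progression evaluated at the
#' horizon, on event-anchored outcome records of the event-positive
#' group.
#'
#' @param time anchored times (months).
#' @param cause cause codes 0/1/2.
#' @param horizon months (default 24).
#' @return list with `estimate`, `n`, `n_progressions`, `flagged`.
#' @export
two_year_progression_rate <- function(time, cause, horizon = 24) {
  if (length(time) == 0L)
    return(list(estimate = NA_real_, n = 0L, n_progressions = 0L,
                flagged = TRUE))
  if (!any(cause != 0L)) {
    warning("no events in the group: 2-year progression rate is 0 with low information",
            call. = FALSE)
    return(list(estimate = 0, n = length(time), n_progressions = 0L,
                flagged = TRUE))
  }
  aj <- aalen_johansen(time, cause)
  list(estimate = cif_at(aj, horizon), n = length(time),
       n_progressions = sum(cause == 1L), flagged = FALSE)
}

# --- internal sweep machinery -------------------------------------------

cmp_ge <- function(comparator) {
  if (!comparator %in% c(">", ">="))
    stop_sogrisk("comparator must be '>' or '>='", class = "sogrisk_config_error")
  comparator == ">="
}

# count of values in sorted vector v satisfying (v >= c) or (v > c),
# vectorized over candidates c
count_crossing <- function(v_sorted, cands, ge) {
  n <- length(v_sorted)
  if (n == 0L) return(rep(0L, length(cands)))
  if (ge) n - findInterval(cands, v_sorted, left.open = TRUE)
  else n - findInterval(cands, v_sorted)
}

# per-patient pieces of the sweep: visit times, running max of the track,
# outcome; patients are "assessed" if the track is defined at >= 1 visit
sweep_patient_data <- function(series, outcomes, track) {
  dat <- list()
  for (pid in unique(series$patient_id)) {
    rows <- which(series$patient_id == pid)
    rows <- rows[order(series$visit_months[rows])]
    v <- series[[track]][rows]
    if (all(is.na(v))) next
    o <- outcomes[outcomes$patient_id == pid, , drop = FALSE]
    if (nrow(o) != 1L) next
    vt <- series$visit_months[rows]
    runmax <- cummax(ifelse(is.na(v), -Inf, v))
    dat[[length(dat) + 1L]] <- list(
      patient_id = pid, visit_times = vt, values = v, runmax = runmax,
      time = o$time_months, cause = o$cause,
      landmark = vt[min(2L, length(vt))])
  }
  dat
}

# first crossing time of candidate c for one patient (NA if never)
crossing_times <- function(pd, cands, ge) {
  k <- length(pd$runmax)
  cnt <- count_crossing(pd$runmax, cands, ge)   # runmax nondecreasing
  idx <- k - cnt + 1L
  t <- rep(NA_real_, length(cands))
  has <- cnt > 0L
  t[has] <- pd$visit_times[idx[has]]
  t
}

#' Sweep all candidate cutoffs of a biomarker track
#'
#' Candidate cutoffs are all distinct observed values of the track ("all
#' possible cutoffs" on a finite sample).  For each candidate the sweep
#' detects first-crossing events, anchors outcomes on the event clock,
#' estimates the 2-year progression rate of the event-positive group
#' (Aalen-Johansen at `horizon`), computes a raw p-value from a
#' cause-specific Cox model on the time-dependent binary event indicator
#' (or its score/log-rank variant), and the time-dependent
#' sensitivity/FPR at the horizon.  Holm correction is applied across the
#' full candidate set.
#'
#' @param series output of [biomarker_series()].
#' @param outcomes output of [outcome_records()].
#' @param track track column of `series`.
#' @param comparator `">="` (default for the volumetry cutoffs) or `">"`.
#' @param horizon months (default 24).
#' @param marker_clock `"second-mri"` (marker status = event at or before
#'   the 2nd MRI landmark; sensitivity/FPR clock starts there) or
#'   `"any-time"` (status = event at any time; clock from first MRI).
#' @param test `"cox"` (Wald p from the fitted indicator model) or
#'   `"logrank"` (score test at beta = 0).
#' @param ties Cox tie handling.
#' @return data frame of class `cutoff_sweep`: one row per candidate with
#'   `cutoff`, `comparator`, `n_assessed`, `n_positive`, `two_year_pr`,
#'   `p_raw`, `p_holm`, `sensitivity`, `fpr`, `hr`.
#' @export
sweep_cutoffs <- function(series, outcomes, track, comparator = ">=",
                          horizon = 24, marker_clock = c("second-mri", "any-time"),
                          test = c("cox", "logrank"),
                          ties = c("efron", "breslow")) {
  marker_clock <- match.arg(marker_clock)
  test <- match.arg(test)
  ties <- match.arg(ties)
  ge <- cmp_ge(comparator)

  dat <- sweep_patient_data(series, outcomes, track)
  vals <- sort(unique(unlist(lapply(dat, function(p)
    p$values[!is.na(p$values)]))))
  if (length(vals) < 2L) {
    warning("degenerate track (fewer than 2 distinct observed values): empty sweep",
            call. = FALSE)
    empty <- data.frame(cutoff = numeric(0), comparator = character(0),
                        n_assessed = integer(0), n_positive = integer(0),
                        two_year_pr = numeric(0), p_raw = numeric(0),
                        p_holm = numeric(0), sensitivity = numeric(0),
                        fpr = numeric(0), hr = numeric(0))
    class(empty) <- c("cutoff_sweep", "data.frame")
    return(empty)
  }
  n_assessed <- length(dat)

  # shared counting-process skeleton: intervals on the visit grid with the
  # running-max marker value at the interval start
  iv_start <- c(); iv_stop <- c(); iv_cause <- c(); iv_runmax <- c()
  for (pd in dat) {
    k <- length(pd$visit_times)
    for (i in seq_len(k)) {
      s <- pd$visit_times[i]
      e <- if (i < k) min(pd$visit_times[i + 1L], pd$time) else pd$time
      if (!(s < e)) next
      iv_start <- c(iv_start, s); iv_stop <- c(iv_stop, e)
      iv_cause <- c(iv_cause, if (e < pd$time) 0L else pd$cause)
      iv_runmax <- c(iv_runmax, pd$runmax[i])
    }
  }
  status <- iv_cause == 1L
  et <- sort(unique(iv_stop[status]))
  n_risk <- d <- integer(length(et))
  risk_vals <- death_vals <- vector("list", length(et))
  for (m in seq_along(et)) {
    t <- et[m]
    R <- iv_start < t & iv_stop >= t
    D <- iv_stop == t & status
    n_risk[m] <- sum(R); d[m] <- sum(D)
    risk_vals[[m]] <- sort(iv_runmax[R])
    death_vals[[m]] <- sort(iv_runmax[D])
  }
  C <- length(vals)
  N1 <- matrix(0L, length(et), C); D1 <- matrix(0L, length(et), C)
  for (m in seq_along(et)) {
    N1[m, ] <- count_crossing(risk_vals[[m]], vals, ge)
    D1[m, ] <- count_crossing(death_vals[[m]], vals, ge)
  }

  cross <- vapply(dat, function(pd) crossing_times(pd, vals, ge),
                  numeric(C))
  if (C == 1L) cross <- matrix(cross, nrow = 1L)
  cross <- t(cross)                      # patients x candidates
  pt_time <- vapply(dat, `[[`, numeric(1), "time")
  pt_cause <- vapply(dat, `[[`, numeric(1), "cause")
  pt_last <- vapply(dat, function(pd) max(pd$visit_times), numeric(1))
  pt_landmark <- vapply(dat, `[[`, numeric(1), "landmark")

  res <- data.frame(cutoff = vals, comparator = comparator,
                    n_assessed = n_assessed, n_positive = NA_integer_,
                    two_year_pr = NA_real_, p_raw = NA_real_,
                    p_holm = NA_real_, sensitivity = NA_real_,
                    fpr = NA_real_, hr = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(C)) {
    ct <- cross[, j]
    pos <- !is.na(ct)
    res$n_positive[j] <- sum(pos)
    if (length(et)) {
      fit <- cox_binary_counts(n_risk, N1[, j], d, D1[, j], ties = ties)
      res$p_raw[j] <- if (test == "cox") fit$p_value else fit$p_score
      res$hr[j] <- exp(fit$coef)
    }
    if (any(pos)) {
      at <- pt_time[pos] - ct[pos]
      keep <- at > 0
      if (any(keep)) {
        pr <- suppressWarnings(
          two_year_progression_rate(at[keep], pt_cause[pos][keep], horizon))
        res$two_year_pr[j] <- pr$estimate
      }
    }
    if (marker_clock == "second-mri") {
      status_pos <- pos & !is.na(ct) & ct <= pt_landmark
      keep <- pt_time > pt_landmark
      tf <- td_sensitivity_fpr(status_pos[keep],
                               pt_time[keep] - pt_landmark[keep],
                               pt_cause[keep], horizon)
    } else {
      tf <- td_sensitivity_fpr(pos, pt_time, pt_cause, horizon)
    }
    res$sensitivity[j] <- tf$sensitivity
    res$fpr[j] <- tf$fpr
  }
  res$p_holm <- holm_adjust(res$p_raw)
  attr(res, "track") <- track
  attr(res, "horizon") <- horizon
  attr(res, "marker_clock") <- marker_clock
  attr(res, "test") <- test
  class(res) <- c("cutoff_sweep", "data.frame")
  res
}

#' Select the qualifying cutoff
#'
#' Among candidates with a two-year progression rate of at least `target`
#' and a Holm-adjusted p below `alpha`, returns the smallest cutoff (the
#' smallest qualifying cutoff maximizes sensitivity).  `NULL` when no
#' candidate qualifies.
#'
#' @param sweep result of [sweep_cutoffs()].
#' @param target IMWG two-year progression criterion (default 0.80).
#' @param alpha familywise significance level for the Holm-adjusted p.
#' @return a single-row data frame, or `NULL`.
#' @export
select_cutoff <- function(sweep, target = 0.80, alpha = 0.05) {
  ok <- !is.na(sweep$two_year_pr) & sweep$two_year_pr >= target &
    !is.na(sweep$p_holm) & sweep$p_holm < alpha
  if (!any(ok)) return(NULL)
  sweep[which(ok)[which.min(sweep$cutoff[ok])], , drop = FALSE]
}

# evaluate one fixed, prespecified cutoff (used for the IMWG >1 FL row);
# p_raw from the same time-dependent Cox, no Holm (single test)
sweep_cutoffs_at <- function(series, outcomes, track, cutoff, comparator,
                             horizon, marker_clock, test, ties) {
  ge <- cmp_ge(comparator)
  dat <- sweep_patient_data(series, outcomes, track)
  ev <- detect_event(series[series$patient_id %in%
                              vapply(dat, `[[`, character(1), "patient_id"), ,
                            drop = FALSE],
                     track, cutoff, comparator)
  rows <- counting_rows(series[series$patient_id %in% ev$patient_id, ,
                               drop = FALSE],
                        outcomes, events = list(evind = ev))
  p_raw <- NA_real_; hr <- NA_real_
  fit <- tryCatch(cox_cause_specific(rows, "evind", ties = ties),
                  error = function(e) NULL)
  if (!is.null(fit)) {
    p_raw <- unname(fit$p_value); hr <- unname(fit$hr)
  }
  anch <- suppressWarnings(event_anchored_outcomes(
    ev, outcomes[outcomes$patient_id %in% ev$patient_id, , drop = FALSE],
    series))
  posn <- anch[anch$positive, , drop = FALSE]
  pr <- suppressWarnings(two_year_progression_rate(
    posn$anchored_time_months, posn$cause, horizon))
  pt_time <- vapply(dat, `[[`, numeric(1), "time")
  pt_cause <- vapply(dat, `[[`, numeric(1), "cause")
  pt_landmark <- vapply(dat, `[[`, numeric(1), "landmark")
  pid <- vapply(dat, `[[`, character(1), "patient_id")
  evt <- ev$event_time_months[match(pid, ev$patient_id)]
  if (marker_clock == "second-mri") {
    status_pos <- !is.na(evt) & evt <= pt_landmark
    keep <- pt_time > pt_landmark
    tf <- td_sensitivity_fpr(status_pos[keep], pt_time[keep] - pt_landmark[keep],
                             pt_cause[keep], horizon)
  } else {
    tf <- td_sensitivity_fpr(!is.na(evt), pt_time, pt_cause, horizon)
  }
  data.frame(cutoff = cutoff, comparator = comparator,
             n_assessed = length(dat), n_positive = sum(!is.na(evt)),
             two_year_pr = pr$estimate, p_raw = p_raw, p_holm = NA_real_,
             sensitivity = tf$sensitivity, fpr = tf$fpr, hr = hr,
             stringsAsFactors = FALSE)
}

#' Biomarker comparison report
#'
#' One row per MRI biomarker: the fixed IMWG ">1 focal lesion" criterion
#' plus the selected (smallest qualifying) cutoff for nFL, dev-nFL, TTV
#' and SOG, each with raw and Holm-adjusted p, two-year progression rate
#' of the high-risk group, time-dependent sensitivity and FPR at the
#' horizon, and group sizes; dynamic biomarkers are assessed on patients
#' with at least two MRIs.  A companion table reports the cutoff-free
#' Harrell c-index of each biomarker track computed on all longitudinal
#' values.
#'
#' @inheritParams sweep_cutoffs
#' @param target IMWG two-year progression criterion.
#' @param alpha familywise level for cutoff selection.
#' @return list of class `biomarker_report` with elements `biomarkers`
#'   (data frame), `c_index` (data frame) and `params`.
#' @export
biomarker_comparison_report <- function(series, outcomes, horizon = 24,
                                        target = 0.80, alpha = 0.05,
                                        marker_clock = c("second-mri", "any-time"),
                                        test = c("cox", "logrank"),
                                        ties = c("efron", "breslow")) {
  marker_clock <- match.arg(marker_clock)
  test <- match.arg(test)
  ties <- match.arg(ties)
  defs <- biomarker_defs()
  rows <- list()
  for (i in seq_len(nrow(defs))) {
    def <- defs[i, ]
    if (!is.na(def$fixed_cutoff)) {
      r <- sweep_cutoffs_at(series, outcomes, def$track, def$fixed_cutoff,
                            def$comparator, horizon, marker_clock, test, ties)
    } else {
      sw <- sweep_cutoffs(series, outcomes, def$track, def$comparator,
                          horizon, marker_clock, test, ties)
      sel <- select_cutoff(sw, target = target, alpha = alpha)
      r <- if (is.null(sel)) {
        data.frame(cutoff = NA_real_, comparator = def$comparator,
                   n_assessed = if (nrow(sw)) sw$n_assessed[1L] else 0L,
                   n_positive = NA_integer_, two_year_pr = NA_real_,
                   p_raw = NA_real_, p_holm = NA_real_,
                   sensitivity = NA_real_, fpr = NA_real_, hr = NA_real_,
                   stringsAsFactors = FALSE)
      } else sel
    }
    rows[[i]] <- cbind(data.frame(biomarker = def$biomarker,
                                  label = def$label, unit = def$unit,
                                  stringsAsFactors = FALSE), r)
  }
  biomarkers <- do.call(rbind, rows)
  rownames(biomarkers) <- NULL

  cidx <- lapply(c(nfl = "n_fl", dev_nfl = "new_fl_per_year",
                   ttv = "ttv_mm3", sog = "sog_mm3_month"), function(track) {
    dynamic <- track %in% c("new_fl_per_year", "sog_mm3_month")
    ser <- series
    if (dynamic) {
      nv <- table(series$patient_id)
      ser <- series[series$patient_id %in% names(nv)[nv >= 2L], ,
                    drop = FALSE]
    }
    cr <- counting_rows(ser, outcomes, covariates = track)
    harrell_c_td(cr, track)$c_index
  })
  c_index <- data.frame(biomarker = names(cidx),
                        c_index = unlist(cidx, use.names = FALSE),
                        stringsAsFactors = FALSE)
  out <- list(biomarkers = biomarkers, c_index = c_index,
              params = list(horizon = horizon, target = target,
                            alpha = alpha, marker_clock = marker_clock,
                            test = test, ties = ties))
  class(out) <- "biomarker_report"
  out
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat("Biomarker comparison (horizon", x$params$horizon, "months, target",
      sprintf("%.0f%%", 100 * x$params$target), "2-year progression)\n\n")
  df <- x$biomarkers
  df$two_year_pr <- sprintf("%.1f%%", 100 * df$two_year_pr)
  df$sensitivity <- sprintf("%.1f%%", 100 * df$sensitivity)
  df$fpr <- sprintf("%.1f%%", 100 * df$fpr)
  print(df[, c("label", "cutoff", "comparator", "unit", "two_year_pr",
               "sensitivity", "fpr", "n_assessed", "n_positive")],
        row.names = FALSE)
  cat("\nHarrell c-index (cutoff-free):\n")
  print(x$c_index, row.names = FALSE)
  invisible(x)
}

#' Serialize a biomarker report
#'
#' Writes `biomarkers.csv`, `c_index.csv` and a JSON mirror
#' `report.json` with a provenance block.
#'
#' @param report a `biomarker_report`.
#' @param dir output directory.
#' @param provenance optional list (e.g. config and seed) echoed in the
#'   JSON.
#' @return invisibly, the files written.
#' @export
write_report <- function(report, dir, provenance = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, "biomarkers.csv")
  f2 <- file.path(dir, "c_index.csv")
  f3 <- file.path(dir, "report.json")
  write.csv(format_numeric_df(report$biomarkers), f1, row.names = FALSE,
            quote = FALSE)
  write.csv(format_numeric_df(report$c_index), f2, row.names = FALSE,
            quote = FALSE)
  jsonlite::write_json(list(biomarkers = report$biomarkers,
                            c_index = report$c_index,
                            params = report$params,
                            provenance = provenance),
                       f3, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(c(f1, f2, f3))
}

#' Read back a serialized biomarker report
#' @param dir directory written by [write_report()].
#' @return list with `biomarkers` and `c_index` data frames.
#' @export
read_report <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "report.json"),
                           simplifyVector = TRUE)
  list(biomarkers = as.data.frame(j$biomarkers),
       c_index = as.data.frame(j$c_index), params = j$params)
}

#' Stratified cumulative incidence with pairwise hazard ratios
#'
#' Aalen-Johansen progression CIF per stratum plus pairwise cause-specific
#' Cox hazard ratios between strata (binary indicator covariate on the
#' given clock).
#'
#' @param time,cause outcome records (any clock).
#' @param group factor/character stratum label per patient.
#' @return list with `cif` (named list of `aj_cif`), `pairwise` (data
#'   frame: group1, group2, hr, ci_lower, ci_upper, p_value, flagged).
#' @export
stratified_incidence <- function(time, cause, group) {
  stopifnot(length(time) == length(cause), length(time) == length(group))
  group <- as.character(group)
  levs <- sort(unique(group))
  cifs <- lapply(levs, function(g) {
    idx <- group == g
    if (!any(cause[idx] != 0L)) {
      aj <- data.frame(time = numeric(0), n_risk = numeric(0),
                       d1 = numeric(0), d2 = numeric(0), surv = numeric(0),
                       cif1 = numeric(0), cif2 = numeric(0))
      class(aj) <- c("aj_cif", "data.frame")
      aj
    } else aalen_johansen(time[idx], cause[idx])
  })
  names(cifs) <- levs
  pw <- list()
  if (length(levs) >= 2L) {
    for (a in seq_len(length(levs) - 1L)) for (b in (a + 1L):length(levs)) {
      idx <- group %in% c(levs[a], levs[b])
      rows <- data.frame(patient_id = seq_len(sum(idx)),
                         start = 0, stop = time[idx], cause = cause[idx],
                         g = as.numeric(group[idx] == levs[b]))
      fit <- tryCatch(cox_cause_specific(rows, "g"), error = function(e) NULL)
      pw[[length(pw) + 1L]] <- data.frame(
        group1 = levs[a], group2 = levs[b],
        hr = if (is.null(fit)) NA_real_ else unname(fit$hr),
        ci_lower = if (is.null(fit)) NA_real_ else unname(fit$ci_lower),
        ci_upper = if (is.null(fit)) NA_real_ else unname(fit$ci_upper),
        p_value = if (is.null(fit)) NA_real_ else unname(fit$p_value),
        flagged = if (is.null(fit)) TRUE else fit$flagged,
        stringsAsFactors = FALSE)
    }
  }
  list(cif = cifs, pairwise = do.call(rbind, pw))
}
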