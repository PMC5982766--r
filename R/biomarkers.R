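# Biomarker tracks per patient-visit and first-crossing biomarker events.

#' Speed of growth between two consecutive MRIs
#'
#' `(ttv_curr - ttv_prev) / delta_months`, mm^3/month; may be negative
#' when the tumor burden shrinks.
#'
#' @param ttv_prev,ttv_curr total tumor volumes (mm^3).
#' @param delta_months positive elapsed time.
#' @return SOG in mm^3/month.
#' @examples
#' compute_sog(1000, 2140, 10)  # 114 mm^3/month
#' @export
compute_sog <- function(ttv_prev, ttv_curr, delta_months) {
  if (any(delta_months <= 0, na.rm = TRUE))
    stop_sogrisk("delta_months must be > 0", class = "sogrisk_data_error")
  (ttv_curr - ttv_prev) / delta_months
}

#' Newly appearing focal lesions per year
#'
#' Counts lesion-id appearances between two consecutive MRIs, annualized
#' by the interval; disappearances are ignored (appearance semantics, not
#' a net difference).
#'
#' @param prev_ids,curr_ids character vectors of lesion ids present.
#' @param delta_months positive elapsed time.
#' @return new focal lesions per year.
#' @export
compute_new_fl_per_year <- function(prev_ids, curr_ids, delta_months) {
  if (any(delta_months <= 0, na.rm = TRUE))
    stop_sogrisk("delta_months must be > 0", class = "sogrisk_data_error")
  length(setdiff(curr_ids, prev_ids)) * 12 / delta_months
}

#' Build the biomarker series for every patient
#'
#' From per-visit volumes, derives the five biomarker tracks per
#' patient-visit: TTV, log10(TTV), nFL, the IMWG indicator "more than one
#' FL", and the dynamic tracks SOG (mm^3/month) and new FL/year, which are
#' undefined (`NA`) at each patient's first MRI — patients with a single
#' MRI carry no dynamic biomarker values.
#'
#' TTV = 0 is mapped, for the log10 track only, to half the minimum
#' positive TTV observed in the cohort (a pseudo-volume floor).
#'
#' @param visit_df output of [visit_volumes()]; requires strictly
#'   increasing visit times within a patient.
#' @return data frame with one row per patient-visit and columns
#'   `patient_id`, `visit_months`, `ttv_mm3`, `log10_ttv`, `n_fl`,
#'   `more_than_one_fl`, `sog_mm3_month`, `new_fl_per_year`, plus the
#'   `lesion_ids` list column.
#' @export
biomarker_series <- function(visit_df) {
  df <- visit_df[order(visit_df$patient_id, visit_df$visit_months), ,
                 drop = FALSE]
  dup <- stats::ave(df$visit_months, df$patient_id,
                    FUN = function(t) duplicated(t))
  if (any(dup > 0))
    stop_sogrisk("duplicate visit times within a patient",
                 class = "sogrisk_data_error")
  pos <- df$ttv_mm3[df$ttv_mm3 > 0]
  floor_ttv <- if (length(pos)) min(pos) / 2 else NA_real_
  df$log10_ttv <- ifelse(df$ttv_mm3 > 0, log10(df$ttv_mm3), log10(floor_ttv))
  df$more_than_one_fl <- df$n_fl > 1
  df$sog_mm3_month <- NA_real_
  df$new_fl_per_year <- NA_real_
  for (pid in unique(df$patient_id)) {
    rows <- which(df$patient_id == pid)
    if (length(rows) < 2L) next
    t <- df$visit_months[rows]
    dt <- diff(t)
    df$sog_mm3_month[rows[-1L]] <-
      compute_sog(df$ttv_mm3[rows[-length(rows)]], df$ttv_mm3[rows[-1L]], dt)
    for (j in 2:length(rows)) {
      df$new_fl_per_year[rows[j]] <- compute_new_fl_per_year(
        df$lesion_ids[[rows[j - 1L]]], df$lesion_ids[[rows[j]]], dt[j - 1L])
    }
  }
  rownames(df) <- NULL
  df
}

# biomarker registry: track column, default comparator/cutoff, whether the
# track needs >= 2 MRIs
biomarker_defs <- function() {
  data.frame(
    biomarker  = c("imwg_gt1fl", "nfl", "dev_nfl", "ttv", "sog"),
    label      = c(">1 focal lesion", "Number of focal lesions",
                   "Development of number of focal lesions",
                   "Total tumor volume", "Speed of growth"),
    track      = c("n_fl", "n_fl", "new_fl_per_year", "ttv_mm3",
                   "sog_mm3_month"),
    comparator = c(">", ">=", ">=", ">=", ">="),
    unit       = c("FL", "FL", "new FL/year", "mm3", "mm3/month"),
    dynamic    = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    fixed_cutoff = c(1, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

#' Detect the first threshold crossing of a biomarker track
#'
#' A biomarker event is the first MRI at which the track value satisfies
#' `value comparator cutoff` (`>` or `>=`).  `NA` track values (e.g. the
#' dynamic tracks at the first MRI) never trigger an event.
#'
#' @param series output of [biomarker_series()].
#' @param track column name of the track (`"sog_mm3_month"`, `"ttv_mm3"`,
#'   `"n_fl"`, `"new_fl_per_year"`).
#' @param cutoff numeric threshold.
#' @param comparator `">"` or `">="`.
#' @return data frame: `patient_id`, `event_time_months`,
#'   `event_visit_index` (`NA` when the track never crosses).
#' @export
detect_event <- function(series, track, cutoff, comparator = ">=") {
  if (!comparator %in% c(">", ">="))
    stop_sogrisk("comparator must be '>' or '>='",
                 class = "sogrisk_config_error")
  if (!track %in% names(series))
    stop_sogrisk("unknown biomarker track: ", track,
                 class = "sogrisk_config_error")
  v <- series[[track]]
  hit <- if (comparator == ">") v > cutoff else v >= cutoff
  hit[is.na(hit)] <- FALSE
  pids <- unique(series$patient_id)
  out <- data.frame(patient_id = pids,
                    event_time_months = NA_real_,
                    event_visit_index = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(pids)) {
    rows <- which(series$patient_id == pids[i])
    rows <- rows[order(series$visit_months[rows])]
    w <- which(hit[rows])
    if (length(w)) {
      out$event_time_months[i] <- series$visit_months[rows[w[1L]]]
      out$event_visit_index[i] <- w[1L]
    }
  }
  out
}
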