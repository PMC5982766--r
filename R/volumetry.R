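# Volumetry: raw per-lesion measurements -> corrected volumes -> per-visit
# total tumor volume (TTV) and focal-lesion counts.

#' Per-label volumes from a labeled 3-D segmentation mask
#'
#' @param mask 3-D integer array (or RNifti image); label 0 is background.
#' @param spacing voxel spacing in mm, length 3; anisotropy is allowed.
#' @return named numeric vector, volume in mm^3 per nonzero label.
#' @examples
#' m <- array(0L, c(4, 4, 4)); m[1:2, 1, 1] <- 1L
#' lesion_volume_from_mask(m, c(1, 1, 1))
#' @export
lesion_volume_from_mask <- function(mask, spacing) {
  v <- as.vector(mask)
  if (any(abs(v - round(v)) > 1e-8, na.rm = TRUE))
    stop_sogrisk("mask must be integer-labeled", class = "sogrisk_format_error")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_sogrisk("spacing must be three positive numbers",
                 class = "sogrisk_format_error")
  v <- as.integer(round(v))
  v <- v[v != 0L]
  if (length(v) == 0L) return(setNames(numeric(0), character(0)))
  counts <- table(v)
  setNames(as.numeric(counts) * prod(spacing), names(counts))
}

#' Equivalent sphere diameter of a lesion volume
#'
#' `d = (6 V / pi)^(1/3)`.  Lesions with `d <= 5` mm do not count as focal
#' lesions and are excluded from nFL and TTV (strictly-greater ">5 mm"
#' rule).
#'
#' @param volume_mm3 nonnegative volume(s) in mm^3.
#' @return diameter(s) in mm.
#' @examples
#' equivalent_sphere_diameter(65.4498)   # ~5 mm
#' @export
equivalent_sphere_diameter <- function(volume_mm3) {
  if (any(volume_mm3 < 0, na.rm = TRUE))
    stop_sogrisk("volume must be nonnegative", class = "sogrisk_data_error")
  (6 * volume_mm3 / pi)^(1 / 3)
}

#' Average T1/T2 lesion volumes
#'
#' Both modalities present: arithmetic mean.  One present: that value
#' (single-modality fallback).  Both missing: error naming the offending
#' measurement(s).
#'
#' @param vol_t1,vol_t2 numeric vectors (NA = not measured).
#' @param label optional character vector used in error messages.
#' @return corrected raw volume(s).
#' @export
average_modalities <- function(vol_t1, vol_t2, label = NULL) {
  both_na <- is.na(vol_t1) & is.na(vol_t2)
  if (any(both_na)) {
    who <- if (is.null(label)) paste("index", which(both_na)) else label[both_na]
    stop_sogrisk("measurable lesion without any modality volume: ",
                 paste(who, collapse = "; "), class = "sogrisk_data_error")
  }
  out <- rowMeans(cbind(vol_t1, vol_t2), na.rm = TRUE)
  unname(out)
}

#' Carry-forward correction for unmeasurable lesions
#'
#' For each lesion-visit flagged unmeasurable, the corrected volume is the
#' lesion's corrected volume at its most recent measurable visit; the rule
#' propagates across consecutive unmeasurable visits and ends as soon as
#' the lesion is measured again.  Volumes are never carried backward: a
#' lesion that is unmeasurable at its first-ever appearance has nothing to
#' carry and is dropped from that visit with a warning.
#'
#' @param lesion_df lesion measurement data frame with columns
#'   `patient_id`, `visit_months`, `lesion_id`, `vol_t1_mm3`,
#'   `vol_t2_mm3`, `measurable` (placeholder rows with `lesion_id` NA are
#'   passed through).
#' @return the data frame with a `corrected_vol_mm3` column, minus dropped
#'   rows.
#' @export
apply_carryforward <- function(lesion_df) {
  df <- lesion_df
  if (!"corrected_vol_mm3" %in% names(df)) df$corrected_vol_mm3 <- NA_real_
  is_les <- !is.na(df$lesion_id)
  meas <- is_les & df$measurable %in% TRUE
  if (any(meas)) {
    df$corrected_vol_mm3[meas] <- average_modalities(
      df$vol_t1_mm3[meas], df$vol_t2_mm3[meas],
      label = sprintf("%s/%s/visit %.6g", df$patient_id[meas],
                      df$lesion_id[meas], df$visit_months[meas]))
  }
  drop <- logical(nrow(df))
  key <- paste(df$patient_id, df$lesion_id, sep = "\r")
  for (k in unique(key[is_les])) {
    rows <- which(key == k & is_les)
    rows <- rows[order(df$visit_months[rows])]
    last <- NA_real_
    for (r in rows) {
      if (isTRUE(df$measurable[r])) {
        last <- df$corrected_vol_mm3[r]
      } else if (!is.na(last)) {
        df$corrected_vol_mm3[r] <- last
      } else {
        drop[r] <- TRUE
        warning(sprintf(
          "lesion %s of %s unmeasurable at its first appearance (visit %.6g): dropped from that visit",
          df$lesion_id[r], df$patient_id[r], df$visit_months[r]),
          call. = FALSE)
      }
    }
  }
  df[!drop, , drop = FALSE]
}

#' Per-visit total tumor volume and focal-lesion count
#'
#' Applies the >5 mm focal-lesion rule via the equivalent sphere diameter
#' of the corrected volume; TTV is the sum of all qualifying corrected
#' lesion volumes, nFL their count.  Visits known only through placeholder
#' rows (no detectable lesion) yield TTV 0, nFL 0.
#'
#' @param corrected_df output of [apply_carryforward()].
#' @return data frame: `patient_id`, `visit_months`, `ttv_mm3`, `n_fl`,
#'   `lesion_ids` (list column of focal-lesion ids at that visit).
#' @export
compute_visit_volumes <- function(corrected_df) {
  df <- corrected_df
  is_fl <- !is.na(df$lesion_id) & !is.na(df$corrected_vol_mm3) &
    equivalent_sphere_diameter(pmax(df$corrected_vol_mm3, 0)) > 5
  keys <- unique(df[, c("patient_id", "visit_months")])
  keys <- keys[order(keys$patient_id, keys$visit_months), , drop = FALSE]
  ttv <- numeric(nrow(keys)); nfl <- integer(nrow(keys))
  ids <- vector("list", nrow(keys))
  kk <- paste(df$patient_id, df$visit_months, sep = "\r")
  kref <- paste(keys$patient_id, keys$visit_months, sep = "\r")
  for (i in seq_len(nrow(keys))) {
    sel <- kk == kref[i] & is_fl
    ttv[i] <- sum(df$corrected_vol_mm3[sel])
    nfl[i] <- sum(sel)
    ids[[i]] <- sort(df$lesion_id[sel])
  }
  out <- data.frame(patient_id = keys$patient_id,
                    visit_months = keys$visit_months,
                    ttv_mm3 = ttv, n_fl = nfl,
                    stringsAsFactors = FALSE)
  out$lesion_ids <- ids
  rownames(out) <- NULL
  out
}

#' Lesion table to per-visit volumes in one step
#'
#' Convenience wrapper: carry-forward correction followed by
#' [compute_visit_volumes()].
#'
#' @param lesion_df lesion measurement table (see [read_lesion_table()]).
#' @return per-visit volume table.
#' @export
visit_volumes <- function(lesion_df) {
  compute_visit_volumes(apply_carryforward(lesion_df))
}
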