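# File formats: lesion and clinical CSV tables, NIfTI mask directories.
# CSV dialect: comma-separated, UTF-8, dot decimal, ISO-8601 dates.

LESION_COLS <- c("patient_id", "lesion_id", "vol_t1_mm3", "vol_t2_mm3",
                 "measurable")
CLINICAL_COLS <- c("patient_id", "outcome_months", "outcome_cause")

#' Read and validate a per-lesion measurement table
#'
#' Required columns: `patient_id`, `lesion_id`, `vol_t1_mm3`,
#' `vol_t2_mm3`, `measurable`, and either `visit_months` or `visit_date`
#' (ISO-8601; converted to months from each patient's first visit at
#' 365.25/12 days per month).  Unknown columns are preserved but ignored.
#' Placeholder rows (`lesion_id` empty/NA) mark MRI visits without any
#' detectable lesion.  Row-level problems (negative volumes, measurable
#' lesions without any modality volume) are collected and reported
#' together.
#'
#' @param path CSV file.
#' @return typed data frame with `visit_months` populated.
#' @export
read_lesion_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(LESION_COLS, names(df))
  has_time <- any(c("visit_months", "visit_date") %in% names(df))
  if (length(missing_cols) || !has_time)
    stop_sogrisk("lesion table is missing required column(s): ",
                 paste(c(missing_cols,
                         if (!has_time) "visit_months or visit_date"),
                       collapse = ", "),
                 class = "sogrisk_format_error")
  if (!"visit_months" %in% names(df)) {
    d <- as.Date(df$visit_date)
    if (anyNA(d))
      stop_sogrisk("unparseable visit_date entries (expected ISO-8601)",
                   class = "sogrisk_format_error")
    first <- tapply(d, df$patient_id, min)
    df$visit_months <- as.numeric(d - as.Date(first[df$patient_id],
                                              origin = "1970-01-01")) /
      DAYS_PER_MONTH
  }
  df$lesion_id <- as.character(df$lesion_id)
  df$lesion_id[!is.na(df$lesion_id) & df$lesion_id == ""] <- NA_character_
  df$vol_t1_mm3 <- as.numeric(df$vol_t1_mm3)
  df$vol_t2_mm3 <- as.numeric(df$vol_t2_mm3)
  df$measurable <- as.logical(df$measurable)

  errs <- character(0)
  neg <- which(df$vol_t1_mm3 < 0 | df$vol_t2_mm3 < 0)
  if (length(neg))
    errs <- c(errs, sprintf("row %d: negative volume", neg))
  nomod <- which(!is.na(df$lesion_id) & df$measurable %in% TRUE &
                   is.na(df$vol_t1_mm3) & is.na(df$vol_t2_mm3))
  if (length(nomod))
    errs <- c(errs, sprintf("row %d: measurable lesion without any modality volume",
                            nomod))
  if (length(errs))
    stop_sogrisk("invalid lesion table rows:\n  ",
                 paste(errs, collapse = "\n  "),
                 class = "sogrisk_format_error")
  df
}

#' Read and validate a clinical outcome table
#'
#' Required columns: `patient_id` (one row per patient),
#' `outcome_months`, `outcome_cause` in
#' `{censored, progression, death}`; any lab columns (e.g.
#' `m_protein_g_l`, `b2mg`, `hemoglobin`) are carried along.
#'
#' @param path CSV file.
#' @return typed data frame.
#' @export
read_clinical_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CLINICAL_COLS, names(df))
  if (length(missing_cols))
    stop_sogrisk("clinical table is missing required column(s): ",
                 paste(missing_cols, collapse = ", "),
                 class = "sogrisk_format_error")
  if (anyDuplicated(df$patient_id))
    stop_sogrisk("clinical table must have one row per patient",
                 class = "sogrisk_format_error")
  cause_from_label(df$outcome_cause)   # validates the vocabulary
  df$outcome_months <- as.numeric(df$outcome_months)
  if (any(is.na(df$outcome_months) | df$outcome_months < 0))
    stop_sogrisk("outcome_months must be nonnegative numbers",
                 class = "sogrisk_format_error")
  df
}

#' Read a directory of labeled NIfTI masks into a lesion table
#'
#' Files must be named `<patient>_m<months>.nii(.gz)` (as written by
#' [write_cohort_masks()]); lesion identity across visits is the shared
#' integer label.  Volumes are voxel count times voxel volume from the
#' header spacing; anisotropic spacing is honored.  An empty mask yields
#' a placeholder row (visit with zero lesions).
#'
#' @param dir directory of NIfTI files.
#' @return lesion measurement table with `vol_t1_mm3 = vol_t2_mm3 =`
#'   the mask volume and `measurable = TRUE`.
#' @export
read_masks <- function(dir) {
  files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (!length(files))
    stop_sogrisk("no NIfTI files in ", dir, class = "sogrisk_format_error")
  rx <- "^(.+)_m([0-9.]+)\\.nii(\\.gz)?$"
  base <- basename(files)
  if (any(!grepl(rx, base)))
    stop_sogrisk("mask files must be named <patient>_m<months>.nii[.gz]; offending: ",
                 paste(base[!grepl(rx, base)], collapse = ", "),
                 class = "sogrisk_format_error")
  rows <- list()
  for (i in seq_along(files)) {
    img <- RNifti::readNifti(files[i])
    arr <- as.array(img)
    if (is.double(arr) && any(abs(arr - round(arr)) > 1e-6))
      stop_sogrisk("float-valued mask: ", base[i],
                   class = "sogrisk_format_error")
    spacing <- RNifti::pixdim(img)[1:3]
    vols <- lesion_volume_from_mask(arr, spacing)
    pid <- sub(rx, "\\1", base[i])
    months <- as.numeric(sub(rx, "\\2", base[i]))
    if (length(vols) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, visit_months = months, lesion_id = NA_character_,
        vol_t1_mm3 = NA_real_, vol_t2_mm3 = NA_real_, measurable = NA,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, visit_months = months,
        lesion_id = sprintf("L%02d", as.integer(names(vols))),
        vol_t1_mm3 = as.numeric(vols), vol_t2_mm3 = as.numeric(vols),
        measurable = TRUE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$visit_months, out$lesion_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full evaluation pipeline on lesion + clinical tables
#'
#' Volumetry (carry-forward, >5 mm rule, TTV) -> biomarker series ->
#' cutoff sweep, selection and biomarker comparison report.
#'
#' @param lesion_df lesion table ([read_lesion_table()] or
#'   [generate_cohort()]).
#' @param clinical_df clinical table.
#' @param ... passed to [biomarker_comparison_report()].
#' @return a `biomarker_report`.
#' @export
evaluate_cohort <- function(lesion_df, clinical_df, ...) {
  vv <- visit_volumes(lesion_df)
  series <- biomarker_series(vv)
  outcomes <- outcome_records(clinical_df)
  biomarker_comparison_report(series, outcomes, ...)
}
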