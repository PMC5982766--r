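# Synthetic SMM cohort generator.
#
# The generator emulates the data-generating structure the downstream
# analysis assumes: irregular MRI schedules, exponentially growing focal
# lesions with new-lesion arrivals at the 5 mm detection boundary, and a
# progression hazard driven by the *observed* (visit-grid step-function)
# biomarker path, with death as an independent competing event.

# volume of a 5 mm equivalent-sphere-diameter lesion, mm^3
DETECTION_VOLUME_MM3 <- pi / 6 * 5^3

#' Simulate per-patient MRI visit schedules
#'
#' First visit at month 0; inter-visit gaps are log-normal with median
#' `median_visit_interval_months` and log-sd `visit_interval_dispersion`;
#' the number of visits is `1 + Poisson(mean_visits_per_patient - 1)` so the
#' cohort mean approaches the configured target while every patient keeps
#' at least one MRI.  Uses the current RNG state; seed via
#' [generate_cohort()] or `set.seed()` for reproducibility.
#'
#' @param config a [cohort_config()].
#' @return list of increasing numeric vectors of visit times (months),
#'   one per patient, each starting at 0.
#' @export
simulate_visit_schedule <- function(config) {
  validate_cohort_config(config)
  n_extra <- rpois(config$n_patients, config$mean_visits_per_patient - 1)
  lapply(n_extra, function(k) {
    if (k == 0L) return(0)
    gaps <- rlnorm(k, meanlog = log(config$median_visit_interval_months),
                   sdlog = config$visit_interval_dispersion)
    c(0, cumsum(gaps))
  })
}

#' Simulate lesion trajectories for one patient
#'
#' Baseline lesion count is zero-inflated Poisson; initial volumes are
#' log-normal; all lesions of one patient grow exponentially with a
#' patient-level monthly rate drawn from the configured normal mixture.
#' New lesions arrive as a Poisson process over the follow-up span and
#' enter at the 5 mm detection boundary (65.45 mm^3) with a small
#' log-normal jitter, so the "new lesion" and "growth" contributions to
#' SOG stay separable.  Each lesion-visit is independently flagged
#' unmeasurable with probability `unmeasurable_prob`.
#'
#' @param visit_times increasing numeric vector of visit times (months).
#' @param config a [cohort_config()].
#' @return list with `growth_rate` (monthly log growth), `lesions`
#'   (data frame: lesion_id, birth_months, v0_mm3) and `measurable`
#'   (lesions x visits logical matrix).
#' @export
simulate_lesion_dynamics <- function(visit_times, config) {
  if (length(visit_times) < 1L)
    stop_sogrisk("visit schedule must be nonempty", class = "sogrisk_data_error")
  mix <- config$growth_rate_mixture
  comp <- sample.int(nrow(mix), 1L, prob = mix$weight)
  g <- rnorm(1L, mix$mean[comp], mix$sd[comp])

  n0 <- if (runif(1L) < config$zero_lesion_fraction) 0L
        else rpois(1L, config$baseline_lesion_rate)
  v0 <- if (n0 > 0L)
    rlnorm(n0, config$baseline_log_volume_mean, config$baseline_log_volume_sd)
  else numeric(0)
  birth <- rep(0, n0)

  span <- max(visit_times)
  n_new <- if (span > 0 && config$new_lesion_rate_per_year > 0)
    rpois(1L, config$new_lesion_rate_per_year * span / 12)
  else 0L
  if (n_new > 0L) {
    tb <- sort(runif(n_new, 0, span))
    vb <- DETECTION_VOLUME_MM3 * rlnorm(n_new, 0, 0.10)
    birth <- c(birth, tb)
    v0 <- c(v0, vb)
  }
  n_les <- length(v0)
  lesions <- data.frame(
    lesion_id = if (n_les > 0L) sprintf("L%02d", seq_len(n_les)) else character(0),
    birth_months = birth,
    v0_mm3 = v0,
    stringsAsFactors = FALSE)

  measurable <- matrix(TRUE, nrow = n_les, ncol = length(visit_times))
  if (n_les > 0L && config$unmeasurable_prob > 0)
    measurable[] <- runif(n_les * length(visit_times)) >= config$unmeasurable_prob

  list(growth_rate = g, lesions = lesions, measurable = measurable)
}

# true lesion volumes (mm^3) at each visit; NA before a lesion's birth
lesion_volume_matrix <- function(visit_times, dyn) {
  n_les <- nrow(dyn$lesions)
  V <- matrix(NA_real_, nrow = n_les, ncol = length(visit_times))
  if (n_les == 0L) return(V)
  for (i in seq_len(n_les)) {
    alive <- visit_times >= dyn$lesions$birth_months[i]
    V[i, alive] <- dyn$lesions$v0_mm3[i] *
      exp(dyn$growth_rate * (visit_times[alive] - dyn$lesions$birth_months[i]))
  }
  V
}

# observed-path biomarkers on the visit grid from true volumes:
# only detected lesions (> 5 mm equivalent diameter) enter TTV
visit_path <- function(visit_times, dyn) {
  V <- lesion_volume_matrix(visit_times, dyn)
  detected <- !is.na(V) & V > DETECTION_VOLUME_MM3
  ttv <- colSums(V * detected, na.rm = TRUE)
  k <- length(visit_times)
  sog <- rep(0, k)                      # SOG unknown before 2nd MRI -> 0
  if (k >= 2L)
    sog[-1L] <- diff(ttv) / diff(visit_times)
  list(ttv = ttv, sog = sog, detected = detected, volumes = V)
}

#' Simulate the competing-risk outcome for one patient
#'
#' The cause-specific progression hazard is piecewise constant on the
#' visit grid,
#' `h(t) = lambda0 * exp(b_sog * SOG(t)/100 + b_ttv * log10(TTV(t)+1) +
#' b_event * 1[SOG has exceeded sog_event_cutoff])`,
#' where SOG(t) and TTV(t) are the step functions induced by the observed
#' visit grid (SOG is 0 before the second MRI).  Progression is sampled by
#' inversion on the piecewise-constant cumulative hazard; death is an
#' independent constant hazard; the outcome is the earliest of
#' progression, death and administrative censoring.
#'
#' @param visit_times increasing visit times (months).
#' @param dyn lesion dynamics from [simulate_lesion_dynamics()].
#' @param config a [cohort_config()].
#' @return list with `time_months` and `cause` (0 censored, 1 progression,
#'   2 death).
#' @export
simulate_outcomes <- function(visit_times, dyn, config) {
  path <- visit_path(visit_times, dyn)
  k <- length(visit_times)
  # SOG-event indicator at the start of each piece
  crossed <- cumsum(path$sog > config$sog_event_cutoff) > 0
  lam <- config$baseline_progression_hazard_per_month * exp(
    config$log_hr_per_100mm3_sog * path$sog / 100 +
    config$log_hr_per_log10_ttv * log10(path$ttv + 1) +
    config$log_hr_sog_event * as.numeric(crossed))

  breaks <- c(visit_times, config$admin_censor_months)
  keep <- breaks[-1L] > breaks[-length(breaks)]      # drop empty pieces
  lens <- (breaks[-1L] - breaks[-length(breaks)])[keep]
  rates <- lam[keep]
  starts <- breaks[-length(breaks)][keep]

  e <- rexp(1L)
  cum <- cumsum(rates * lens)
  t_prog <- Inf
  if (length(cum) > 0L && e <= cum[length(cum)]) {
    j <- which(e <= cum)[1L]
    prev <- if (j > 1L) cum[j - 1L] else 0
    t_prog <- starts[j] + (e - prev) / rates[j]
  }
  t_death <- if (config$death_hazard_per_month > 0)
    rexp(1L, config$death_hazard_per_month) else Inf

  t_out <- min(t_prog, t_death, config$admin_censor_months)
  cause <- if (t_out == t_prog) CAUSE_PROGRESSION
           else if (t_out == t_death) CAUSE_DEATH
           else CAUSE_CENSORED
  list(time_months = t_out, cause = cause)
}

lab_spec <- function(config) {
  list(
    m_protein_g_l   = list(mean = config$mprotein_mean, sd = config$mprotein_sd,
                           log = FALSE, lo = 0.1),
    b2mg            = list(mean = log(2.2), sd = 0.40, log = TRUE),
    hemoglobin      = list(mean = 13.5, sd = 1.5, log = FALSE, lo = 6),
    creatinine      = list(mean = 0.90, sd = 0.20, log = FALSE, lo = 0.3),
    calcium         = list(mean = 2.35, sd = 0.12, log = FALSE, lo = 1.5),
    ldh             = list(mean = 180, sd = 40, log = FALSE, lo = 50),
    albumin         = list(mean = 42, sd = 4, log = FALSE, lo = 20),
    crp             = list(mean = log(2), sd = 0.8, log = TRUE),
    platelets       = list(mean = 250, sd = 60, log = FALSE, lo = 30),
    leukocytes      = list(mean = 6.5, sd = 1.5, log = FALSE, lo = 1),
    plasma_cell_pct = list(mean = 18, sd = 9, log = FALSE, lo = 1))
}

simulate_labs <- function(growth_rate, config) {
  mm <- mixture_moments(config$growth_rate_mixture)
  zg <- if (mm$sd > 0) (growth_rate - mm$mean) / mm$sd else 0
  rho <- config$lab_growth_correlation
  vapply(lab_spec(config), function(s) {
    z <- rho * zg + sqrt(max(0, 1 - rho^2)) * rnorm(1L)
    x <- s$mean + s$sd * z
    if (isTRUE(s$log)) exp(x) else max(x, s$lo %||% -Inf)
  }, numeric(1))
}

#' Generate a synthetic SMM cohort
#'
#' Runs the full generator under the config's seed and returns (and
#' optionally writes) the two tables the analysis pipeline consumes: a
#' per-lesion measurement table and a per-patient clinical outcome table.
#' Visits scheduled after a patient's outcome are truncated.  Patient-visits
#' without any detectable lesion are emitted as placeholder rows
#' (`lesion_id = NA`, volumes `NA`) so the visit grid survives the
#' round-trip through CSV.
#'
#' Identical `(config, seed)` pairs give byte-identical CSV outputs.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory; if given, writes `lesions.csv`,
#'   `clinical.csv` and a `cohort.json` sidecar echoing config and seed.
#' @param masks if `TRUE`, also writes one labeled NIfTI mask per
#'   patient-visit under `file.path(out_dir, "masks")` (requires
#'   `out_dir`); lesions are voxelized spheres whose voxel-count volume
#'   matches the simulated true volume within one voxel.  Mask mode
#'   represents true volumes: set `modality_noise_sd = 0` and
#'   `unmeasurable_prob = 0` in the config if the table and mask paths
#'   must agree exactly.
#' @param mask_spacing voxel spacing in mm, length 3.
#' @return list with `lesion_table`, `clinical_table`, `config`, `patients`
#'   (internal per-patient simulation detail) and, in mask mode,
#'   `mask_dir`.
#' @export
generate_cohort <- function(config, out_dir = NULL, masks = FALSE,
                            mask_spacing = c(2, 2, 2)) {
  validate_cohort_config(config)
  if (masks && is.null(out_dir))
    stop_sogrisk("mask output requires out_dir", class = "sogrisk_io_error")

  sim <- with_seed(config$seed, {
    schedules <- simulate_visit_schedule(config)
    lapply(seq_len(config$n_patients), function(i) {
      vt <- schedules[[i]]
      dyn <- simulate_lesion_dynamics(vt, config)
      out <- simulate_outcomes(vt, dyn, config)
      labs <- simulate_labs(dyn$growth_rate, config)
      keep <- vt <= out$time_months
      keep[1L] <- TRUE
      vt_obs <- vt[keep]
      path <- visit_path(vt_obs, dyn)
      meas <- dyn$measurable[, keep, drop = FALSE]
      # per-modality measurement noise, drawn inside the patient block so
      # the stream is reproducible patient by patient
      n_cells <- length(meas)
      noise1 <- if (n_cells) rlnorm(n_cells, 0, config$modality_noise_sd) else numeric(0)
      noise2 <- if (n_cells) rlnorm(n_cells, 0, config$modality_noise_sd) else numeric(0)
      single <- if (n_cells) runif(n_cells) < config$single_modality_prob else logical(0)
      drop_t1 <- if (n_cells) runif(n_cells) < 0.5 else logical(0)
      list(patient_id = sprintf("P%03d", i), visit_times = vt_obs,
           dyn = dyn, outcome = out, labs = labs, path = path,
           meas = meas, noise1 = noise1, noise2 = noise2,
           single = single, drop_t1 = drop_t1)
    })
  })

  lesion_rows <- lapply(sim, patient_lesion_rows)
  lesion_table <- do.call(rbind, lesion_rows)
  rownames(lesion_table) <- NULL

  clinical_table <- do.call(rbind, lapply(sim, function(p) {
    data.frame(patient_id = p$patient_id,
               outcome_months = p$outcome$time_months,
               outcome_cause = cause_to_label(p$outcome$cause),
               t(p$labs),
               stringsAsFactors = FALSE)
  }))
  rownames(clinical_table) <- NULL

  res <- list(config = config, lesion_table = lesion_table,
              clinical_table = clinical_table, patients = sim)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir))
      stop_sogrisk("cannot create output directory ", out_dir,
                   class = "sogrisk_io_error")
    write.csv(format_numeric_df(lesion_table),
              file.path(out_dir, "lesions.csv"), row.names = FALSE, quote = FALSE)
    write.csv(format_numeric_df(clinical_table),
              file.path(out_dir, "clinical.csv"), row.names = FALSE, quote = FALSE)
    sidecar <- config
    class(sidecar) <- NULL
    jsonlite::write_json(list(config = sidecar, seed = config$seed),
                         file.path(out_dir, "cohort.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (masks) {
      mdir <- file.path(out_dir, "masks")
      write_cohort_masks(res, mdir, spacing = mask_spacing)
      res$mask_dir <- mdir
    }
  }
  res
}

# fixed-precision formatting so identical cohorts serialize byte-identically
format_numeric_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      x <- formatC(df[[j]], digits = 6, format = "f")
      x[is.na(df[[j]])] <- "NA"
      df[[j]] <- x
    }
  }
  df
}

patient_lesion_rows <- function(p) {
  vt <- p$visit_times
  det <- p$path$detected
  V <- p$path$volumes
  cells <- which(det)                 # column-major (lesion, visit) cells
  i <- (cells - 1L) %% nrow(det) + 1L
  j <- (cells - 1L) %/% nrow(det) + 1L
  m <- p$meas[cells]
  v1 <- ifelse(m, V[cells] * p$noise1[cells], NA_real_)
  v2 <- ifelse(m, V[cells] * p$noise2[cells], NA_real_)
  one <- m & p$single[cells]
  v1[one & p$drop_t1[cells]] <- NA_real_
  v2[one & !p$drop_t1[cells]] <- NA_real_
  les <- data.frame(
    patient_id = rep(p$patient_id, length(cells)), visit_months = vt[j],
    lesion_id = p$dyn$lesions$lesion_id[i], vol_t1_mm3 = v1,
    vol_t2_mm3 = v2, measurable = m, stringsAsFactors = FALSE)
  empty <- setdiff(seq_along(vt), unique(j))  # visits with no detectable lesion
  if (length(empty)) {
    les <- rbind(les, data.frame(
      patient_id = rep(p$patient_id, length(empty)),
      visit_months = vt[empty], lesion_id = NA_character_,
      vol_t1_mm3 = NA_real_, vol_t2_mm3 = NA_real_, measurable = NA,
      stringsAsFactors = FALSE))
  }
  les <- les[order(les$visit_months, les$lesion_id), , drop = FALSE]
  rownames(les) <- NULL
  les
}

#' Voxelize a volume as a compact quasi-spherical blob
#'
#' Selects exactly `round(volume / prod(spacing))` voxels, nearest to the
#' center first (physical distance), so the voxel-count volume matches the
#' nominal volume within one voxel by construction.
#'
#' @param volume_mm3 target volume.
#' @param spacing voxel spacing mm, length 3.
#' @return integer matrix of voxel offsets (n x 3) relative to the center.
#' @keywords internal
sphere_voxel_offsets <- function(volume_mm3, spacing) {
  voxvol <- prod(spacing)
  n <- max(1L, as.integer(round(volume_mm3 / voxvol)))
  r <- (3 * (n + 8) * voxvol / (4 * pi))^(1 / 3)   # generous bounding radius
  h <- pmax(1L, as.integer(ceiling(r / spacing)) + 1L)
  g <- expand.grid(x = -h[1]:h[1], y = -h[2]:h[2], z = -h[3]:h[3])
  d2 <- (g$x * spacing[1])^2 + (g$y * spacing[2])^2 + (g$z * spacing[3])^2
  ord <- order(d2, g$x, g$y, g$z)      # deterministic tie-break
  as.matrix(g[ord[seq_len(n)], , drop = FALSE])
}

#' Write labeled NIfTI masks for a simulated cohort
#'
#' One file per patient-visit, named `<patient>_m<months>.nii.gz`, with one
#' integer label per detectable lesion (label = lesion index, stable across
#' visits) and the voxel spacing in the header.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory.
#' @param spacing voxel spacing mm.
#' @return invisibly, the vector of files written.
#' @export
write_cohort_masks <- function(cohort, dir, spacing = c(2, 2, 2)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    stop_sogrisk("cannot create mask directory ", dir, class = "sogrisk_io_error")
  files <- character(0)
  for (p in cohort$patients) {
    for (j in seq_along(p$visit_times)) {
      idx <- which(p$path$detected[, j])
      offs <- lapply(idx, function(i)
        sphere_voxel_offsets(p$path$volumes[i, j], spacing))
      half <- vapply(offs, function(o)
        if (nrow(o)) max(abs(o)) else 0L, numeric(1))
      w <- as.integer(2 * half + 1)
      pad <- 2L
      dimx <- max(8L, sum(w) + pad * (length(idx) + 1L))
      dimy <- dimz <- max(8L, if (length(w)) max(w) + 2L * pad else 0L)
      arr <- array(0L, dim = c(dimx, dimy, dimz))
      cx <- pad
      for (k in seq_along(idx)) {
        ctr <- c(cx + half[k] + 1L, (dimy + 1L) %/% 2L, (dimz + 1L) %/% 2L)
        o <- offs[[k]]
        arr[cbind(o[, 1] + ctr[1], o[, 2] + ctr[2], o[, 3] + ctr[3])] <- idx[k]
        cx <- cx + w[k] + pad
      }
      f <- file.path(dir, sprintf("%s_m%.6f.nii.gz",
                                  p$patient_id, p$visit_times[j]))
      img <- RNifti::asNifti(structure(arr, pixdim = spacing),
                             datatype = "int16")
      RNifti::writeNifti(img, f)
      files <- c(files, f)
    }
  }
  invisible(files)
}
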