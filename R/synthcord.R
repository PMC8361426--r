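# Synthetic-data generators with analytic ground truth.
#
# Every downstream stage (morphometry, reliability, GLM, ROI extraction,
# association) is exercised against phantoms generated here, so the whole
# pipeline is testable without any patient data. All generators are
# bit-reproducible for a fixed seed.

#' Specification of a synthetic compressed-cord phantom
#'
#' Describes a cord as a stack of digital disks whose per-slice area
#' follows a constant baseline with localized compressions applied.
#' Compressions reduce *area* (not radius) by a stated fraction, so the
#' ground-truth volume deficit stays analytic. Disks are rasterized by
#' centre-of-voxel inclusion: voxel centre (x, y) belongs to the cord iff
#' x^2 + y^2 <= r^2.
#'
#' @param n_slices Number of axial slices.
#' @param voxel_dims Voxel dimensions in mm (in-plane x, in-plane y,
#'   slice thickness). Default 0.25 x 0.25 x 0.9 mm: the 0.9 mm slice
#'   thickness of a typical T2-weighted spine acquisition with the fine
#'   in-plane grid cord segmentations are resampled to, which keeps disk
#'   digitization error well below the compression effects of interest.
#' @param baseline_radius Uncompressed cord radius in mm (default 4, a
#'   realistic cervical cord radius).
#' @param compressions List of compressions, each a list with
#'   `center_slice` (index), `extent_slices` (box width, or FWHM for
#'   gaussian), `max_area_reduction` (fraction in \[0, 1)), and `shape`
#'   (`"box"` or `"gaussian"`). Compressions must not overlap.
#' @param surface_noise_sd SD in mm of per-slice radius noise (surface
#'   roughness). 0 gives a deterministic phantom.
#' @param seed Integer RNG seed.
#' @return A `cord_phantom_spec`.
#' @export
cord_phantom_spec <- function(n_slices = 60, voxel_dims = c(0.25, 0.25, 0.9),
                              baseline_radius = 4, compressions = list(),
                              surface_noise_sd = 0, seed = 1) {
  spec <- structure(list(n_slices = as.integer(n_slices),
                         voxel_dims = as.numeric(voxel_dims),
                         baseline_radius = baseline_radius,
                         compressions = compressions,
                         surface_noise_sd = surface_noise_sd,
                         seed = seed),
                    class = "cord_phantom_spec")
  validate_cord_phantom_spec(spec)
  spec
}

validate_cord_phantom_spec <- function(spec) {
  stopifnot(spec$n_slices >= 1, all(spec$voxel_dims > 0),
            spec$baseline_radius > 0, spec$surface_noise_sd >= 0)
  ivals <- lapply(spec$compressions, function(cp) {
    if (!cp$shape %in% c("box", "gaussian")) stopf("unknown compression shape '%s'", cp$shape)
    if (cp$extent_slices < 1) stopf("extent_slices must be >= 1")
    if (cp$max_area_reduction < 0 || cp$max_area_reduction >= 1) {
      stopf("max_area_reduction must be in [0, 1)")
    }
    compression_interval(cp)
  })
  if (length(ivals) > 1) {
    o <- order(vapply(ivals, `[`, numeric(1), 1))
    ivals <- ivals[o]
    for (i in seq_len(length(ivals) - 1)) {
      if (ivals[[i]][2] >= ivals[[i + 1]][1]) {
        stopf("compressions overlap: slices [%d, %d] and [%d, %d]",
              ivals[[i]][1], ivals[[i]][2], ivals[[i + 1]][1], ivals[[i + 1]][2])
      }
    }
  }
  invisible(spec)
}

# Analytic compressed interval of one compression (1-based inclusive).
# Box: the extent_slices reduced slices. Gaussian: the interval between the
# profile's inflection points (centre +/- sigma), where the slope rule's
# steepest descent/ascent sit on the continuous profile.
compression_interval <- function(cp) {
  if (cp$shape == "box") {
    lo <- cp$center_slice - (cp$extent_slices - 1) %/% 2
    c(lo, lo + cp$extent_slices - 1)
  } else {
    sigma <- cp$extent_slices / (2 * sqrt(2 * log(2)))
    c(round(cp$center_slice - sigma), round(cp$center_slice + sigma))
  }
}

# Fractional area reduction profile of one compression over slices z.
compression_fraction <- function(cp, z) {
  if (cp$shape == "box") {
    iv <- compression_interval(cp)
    ifelse(z >= iv[1] & z <= iv[2], cp$max_area_reduction, 0)
  } else {
    sigma <- cp$extent_slices / (2 * sqrt(2 * log(2)))
    cp$max_area_reduction * exp(-(z - cp$center_slice)^2 / (2 * sigma^2))
  }
}

#' Generate a compressed-cord phantom with analytic ground truth
#'
#' Builds the binary mask described by a [cord_phantom_spec()] and returns
#' it together with the analytic ground truth per compression: the
#' compressed interval implied by the slope rule on the noiseless profile
#' and the analytic volume deficit (sum over slices of fractional area
#' reduction times baseline area times slice thickness; for a box
#' compression this is `reduction * baseline_area * extent * thickness`).
#'
#' @param spec A [cord_phantom_spec()].
#' @return List with `mask` (a [cord_mask]) and `ground_truth`, a list of
#'   records with `z_lo`, `z_hi`, `deficit_mm3` and `baseline_area_mm2`
#'   (analytic, `pi * r^2`).
#' @export
make_cord_phantom <- function(spec) {
  stopifnot(inherits(spec, "cord_phantom_spec"))
  validate_cord_phantom_spec(spec)
  vd <- spec$voxel_dims
  r0 <- spec$baseline_radius
  z <- seq_len(spec$n_slices)
  frac <- rep(0, spec$n_slices)
  for (cp in spec$compressions) frac <- frac + compression_fraction(cp, z)
  frac <- pmin(frac, 0.999)
  radius <- r0 * sqrt(1 - frac)
  if (spec$surface_noise_sd > 0) {
    radius <- radius + with_seed(sub_seed(spec$seed, "cord"),
                                 stats::rnorm(spec$n_slices, 0, spec$surface_noise_sd))
    radius <- pmax(radius, vd[1])   # never lose the cord entirely
  }
  rmax <- max(radius) + 2 * vd[1]
  nx <- 2L * as.integer(ceiling(rmax / vd[1])) + 3L
  ny <- 2L * as.integer(ceiling(rmax / vd[2])) + 3L
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xs <- ((seq_len(nx) - cx) * vd[1])^2
  ys <- ((seq_len(ny) - cy) * vd[2])^2
  d2 <- outer(xs, ys, `+`)
  vox <- array(0, dim = c(nx, ny, spec$n_slices))
  for (k in z) vox[, , k] <- as.numeric(d2 <= radius[k]^2)

  a0 <- pi * r0^2
  gt <- lapply(spec$compressions, function(cp) {
    iv <- compression_interval(cp)
    list(z_lo = iv[1], z_hi = iv[2],
         deficit_mm3 = sum(compression_fraction(cp, z)) * a0 * vd[3],
         baseline_area_mm2 = a0)
  })
  list(mask = cord_mask(vox, vd), ground_truth = gt)
}

#' Specification of a block-design BOLD phantom
#'
#' The phantom alternates rest and active segments (the study paradigm:
#' 11 segments of 30 s at TR 1 s, starting at rest, i.e. six rest and
#' five active segments over 330 volumes). Voxels inside each active ROI
#' carry a known percent signal change modulated by the convolved task
#' regressor; Gaussian white noise is added everywhere and smooth motion
#' parameter traces are generated alongside.
#'
#' @param volume_shape Voxel grid (length 3).
#' @param voxel_dims Voxel dimensions in mm (default 2.3 mm isotropic,
#'   the BOLD acquisition resolution).
#' @param tr Repetition time, seconds.
#' @param n_segments,segment_duration Block paradigm geometry;
#'   `n_segments * segment_duration / tr` must be an integer.
#' @param start_state `"rest"` or `"active"`.
#' @param active_rois List of `list(mask = <3-D logical/0-1 array>,
#'   true_percent_signal = <%>)`.
#' @param baseline_intensity Baseline signal, arbitrary units.
#' @param noise_sd Gaussian noise SD, same units.
#' @param motion_amplitude Length-2: translation scale (mm) and rotation
#'   scale (rad) of the simulated motion traces.
#' @param seed Integer RNG seed.
#' @return A `bold_phantom_spec`.
#' @export
bold_phantom_spec <- function(volume_shape = c(16, 16, 12),
                              voxel_dims = c(2.3, 2.3, 2.3), tr = 1,
                              n_segments = 11, segment_duration = 30,
                              start_state = "rest", active_rois = list(),
                              baseline_intensity = 1000, noise_sd = 10,
                              motion_amplitude = c(0.2, 0.002), seed = 1) {
  nvol <- n_segments * segment_duration / tr
  if (abs(nvol - round(nvol)) > 1e-9) {
    stopf("paradigm does not divide into TR: %g segments x %g s / %g s is not an integer",
          n_segments, segment_duration, tr)
  }
  for (roi in active_rois) {
    if (roi$true_percent_signal < 0) stopf("true_percent_signal must be >= 0")
    if (!all(dim(roi$mask) == volume_shape)) stopf("active ROI mask must match volume_shape")
  }
  structure(list(volume_shape = as.integer(volume_shape),
                 voxel_dims = as.numeric(voxel_dims), tr = tr,
                 n_segments = as.integer(n_segments),
                 segment_duration = segment_duration,
                 start_state = match.arg(start_state, c("rest", "active")),
                 active_rois = active_rois,
                 baseline_intensity = baseline_intensity, noise_sd = noise_sd,
                 motion_amplitude = motion_amplitude, seed = seed),
            class = "bold_phantom_spec")
}

#' Generate a BOLD run with known per-ROI percent signal change
#'
#' Time series model: `baseline * (1 + psc/100 * x(t))` inside each active
#' ROI, `baseline` elsewhere, plus Gaussian white noise; `x(t)` is the
#' boxcar convolved with the double-gamma HRF, scaled to unit
#' peak-to-baseline range (the same task regressor the GLM uses, so
#' noiseless recovery is exact). Motion traces are smooth low-frequency
#' drifts plus white noise — realistic nuisance structure without scanner
#' physics.
#'
#' @param spec A [bold_phantom_spec()].
#' @return List with `run` (a `bold_run`: `data` 4-D array, `tr`,
#'   `voxel_dims`), `motion` (volumes x 6 matrix), `paradigm`, and
#'   `truth` (per-ROI true percent signal).
#' @export
make_bold_phantom <- function(spec) {
  stopifnot(inherits(spec, "bold_phantom_spec"))
  par <- paradigm(n_segments = spec$n_segments,
                  segment_duration = spec$segment_duration,
                  start_state = spec$start_state, tr = spec$tr)
  x <- build_task_regressor(par)
  nt <- length(x)
  nv <- prod(spec$volume_shape)
  dat <- matrix(spec$baseline_intensity, nrow = nt, ncol = nv)
  for (roi in spec$active_rois) {
    idx <- which(roi$mask > 0)
    mod <- spec$baseline_intensity * (1 + roi$true_percent_signal / 100 * x)
    dat[, idx] <- matrix(mod, nrow = nt, ncol = length(idx))
  }
  if (spec$noise_sd > 0) {
    dat <- dat + with_seed(sub_seed(spec$seed, "noise"),
                           matrix(stats::rnorm(nt * nv, 0, spec$noise_sd), nt, nv))
  }
  motion <- with_seed(sub_seed(spec$seed, "motion"),
                      simulate_motion(nt, spec$tr, spec$motion_amplitude))
  run <- structure(list(data = array(t(dat), dim = c(spec$volume_shape, nt)),
                        tr = spec$tr, voxel_dims = spec$voxel_dims),
                   class = "bold_run")
  truth <- vapply(spec$active_rois, `[[`, numeric(1), "true_percent_signal")
  list(run = run, motion = motion, paradigm = par, truth = truth)
}

# Smooth low-frequency drift (sum of slow cosines with random phase) plus
# white noise, per motion column.
simulate_motion <- function(n_volumes, tr, amplitude) {
  t <- seq_len(n_volumes) * tr
  make_col <- function(scale) {
    drift <- rep(0, n_volumes)
    for (f in c(0.002, 0.005, 0.01)) {
      drift <- drift + stats::rnorm(1, 0, scale) * cos(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
    drift + stats::rnorm(n_volumes, 0, scale / 10)
  }
  m <- cbind(make_col(amplitude[1]), make_col(amplitude[1]), make_col(amplitude[1]),
             make_col(amplitude[2]), make_col(amplitude[2]), make_col(amplitude[2]))
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' Simulate a repeated-measurements rater table
#'
#' Emulates a reliability study in which raters measure each subject's
#' compression volume several times:
#' `value(subject, rater, repeat) = truth + rater_bias + residual`, with
#' rater biases drawn once per rater from `N(0, rater_bias_sd^2)` and
#' residuals i.i.d. `N(0, residual_sd^2)`.
#'
#' @param true_values Per-subject true values (mm^3).
#' @param n_raters,n_repeats Design size (both >= 1).
#' @param rater_bias_sd,residual_sd Variance components, mm^3.
#' @param seed Integer RNG seed.
#' @return A `data.frame` with columns `subject_id`, `rater_id`,
#'   `repeat_index`, `value_mm3` (subjects x raters x repeats rows).
#' @export
make_rater_table <- function(true_values, n_raters = 2, n_repeats = 3,
                             rater_bias_sd = 0, residual_sd = 0, seed = 1) {
  stopifnot(n_raters >= 1, n_repeats >= 1, rater_bias_sd >= 0, residual_sd >= 0,
            length(true_values) >= 1)
  ns <- length(true_values)
  with_seed(sub_seed(seed, "raters"), {
    bias <- stats::rnorm(n_raters, 0, rater_bias_sd)
    tab <- expand.grid(repeat_index = seq_len(n_repeats),
                       rater_id = paste0("rater", seq_len(n_raters)),
                       subject_id = paste0("subj", formatC(seq_len(ns), width = 2, flag = "0")),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tab <- tab[, c("subject_id", "rater_id", "repeat_index")]
    si <- as.integer(factor(tab$subject_id, levels = unique(tab$subject_id)))
    ri <- as.integer(factor(tab$rater_id, levels = unique(tab$rater_id)))
    tab$value_mm3 <- true_values[si] + bias[ri] +
      stats::rnorm(nrow(tab), 0, residual_sd)
    tab
  })
}

#' Specification and generation of a synthetic patient cohort
#'
#' Draws a multivariate Gaussian with a target correlation structure over
#' the cohort variables (compression volume, percent BOLD signal, volume
#' of activation, mJOA, ...), transforms each variable to its stated
#' marginal mean and SD, and rounds/clips any variable named `mjoa*` to
#' the 0-18 integer disability scale.
#'
#' @param n_subjects Number of patients (> 0).
#' @param target_correlation Symmetric positive semi-definite correlation
#'   matrix with unit diagonal; dimnames give the variable names.
#' @param marginals Named list of `c(mean, sd)` per variable (same names
#'   and order as the correlation matrix).
#' @param seed Integer RNG seed.
#' @return A `data.frame` with one row per subject and one column per
#'   variable, plus a `case_id` column.
#' @export
make_cohort <- function(n_subjects, target_correlation, marginals, seed = 1) {
  if (n_subjects < 1) stopf("n_subjects must be >= 1")
  R <- as.matrix(target_correlation)
  p <- nrow(R)
  if (ncol(R) != p || any(abs(R - t(R)) > 1e-8) || any(abs(diag(R) - 1) > 1e-8)) {
    stopf("target_correlation must be symmetric with unit diagonal")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stopf("target_correlation is not positive semi-definite (min eigenvalue %.3g)", min(ev))
  vars <- colnames(R)
  if (is.null(vars)) vars <- names(marginals)
  if (is.null(vars) || length(vars) != p) stopf("variable names required on the correlation matrix or marginals")
  if (!all(vars %in% names(marginals))) stopf("marginals missing for: %s",
                                              paste(setdiff(vars, names(marginals)), collapse = ", "))
  z <- with_seed(sub_seed(seed, "cohort"),
                 MASS::mvrnorm(n_subjects, mu = rep(0, p), Sigma = R))
  z <- matrix(z, nrow = n_subjects)   # mvrnorm drops dim when n = 1
  out <- data.frame(case_id = seq_len(n_subjects))
  for (j in seq_len(p)) {
    ms <- marginals[[vars[j]]]
    v <- ms[1] + ms[2] * z[, j]
    if (grepl("^mjoa", vars[j])) v <- pmin(18, pmax(0, round(v)))
    out[[vars[j]]] <- v
  }
  out
}
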