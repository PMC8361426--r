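# End-to-end orchestration: synthesize a cohort with known association
# structure, run morphometry, reliability, GLM + ROI extraction, then the
# correlation battery, with JSON sidecars and a run manifest.

#' Default end-to-end pipeline configuration
#'
#' A compact synthetic study: per-subject compressed-cord phantoms whose
#' compression depth follows a latent severity variable, a rater
#' reliability simulation, per-subject BOLD phantoms whose contralateral
#' M1 percent signal tracks the same severity, ROI extraction, and the
#' cohort correlation battery. Every stage parameter the analysis depends
#' on is explicit here and echoed into the output sidecars.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed driving every random component.
#' @param n_subjects Number of synthetic patients.
#' @param bold_shape BOLD phantom grid (kept small; activation geometry,
#'   not anatomy, is what downstream stages consume).
#' @param n_perm Sign-flip permutations for cluster correction.
#' @param severity_activation_r Target correlation between compression
#'   volume and M1 percent BOLD across subjects.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, n_subjects = 8,
                            bold_shape = c(14, 14, 10), n_perm = 200,
                            severity_activation_r = 0.56) {
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), n_subjects = n_subjects,
    bold_shape = bold_shape, n_perm = n_perm,
    severity_activation_r = severity_activation_r,
    morphometry = list(window = 3, slope_threshold = 0.05, min_extent = 3),
    glm = list(z_threshold = 3.1, alpha = 0.05, correction = "permutation",
               fwhm = 0),
    paradigm = list(n_segments = 11, segment_duration = 30, tr = 1),
    # rater noise reflects a semi-automated measurement: small bias and
    # repeat error relative to the between-subject spread of deficits
    raters = list(n_raters = 2, n_repeats = 3, rater_bias_sd = 5,
                  residual_sd = 12)
  ), class = "pipeline_config")
}

write_sidecar <- function(path, params, seed, inputs = character()) {
  side <- list(parameters = params, seed = seed,
               software = paste0("cordmotor ",
                                 as.character(utils::packageVersion("cordmotor"))),
               input_hashes = vapply(inputs, function(f) {
                 if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_
               }, character(1)))
  jsonlite::write_json(side, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes the stages in dependency order (synthesis, morphometry,
#' reliability, GLM + ROI extraction, association), writing each stage's
#' tables under `out_dir/{morphometry,reliability,glm,roi,association}/`
#' together with a JSON sidecar (parameters, seed, software version,
#' input hashes), and a top-level `manifest.json` linking every output.
#' Re-running with the same config and seed reproduces all tabular
#' outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (list of stage output paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  stages <- c("morphometry", "reliability", "glm", "roi", "association")
  for (s in stages) dir.create(file.path(out, s), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  seed <- config$seed

  ## -- synthesis: latent severity drives compression depth and M1 signal
  sev <- with_seed(sub_seed(seed, "severity"), stats::rnorm(config$n_subjects))
  rho <- config$severity_activation_r
  noise <- with_seed(sub_seed(seed, "sev_noise"), stats::rnorm(config$n_subjects))
  act_lat <- rho * sev + sqrt(1 - rho^2) * noise
  reduction <- pmin(0.75, pmax(0.15, 0.45 + 0.15 * sev))
  psc_true <- pmax(0.3, 2 + 0.5 * act_lat)

  ## -- morphometry on per-subject cord phantoms
  morph_rows <- list()
  profiles <- list()
  for (i in seq_len(config$n_subjects)) {
    spec <- cord_phantom_spec(
      n_slices = 48, compressions = list(list(center_slice = 24,
                                              extent_slices = 7,
                                              max_area_reduction = reduction[i],
                                              shape = "box")),
      surface_noise_sd = 0.05, seed = sub_seed(seed, "cord") + i)
    ph <- make_cord_phantom(spec)
    mm <- measure_compression(ph$mask, window = config$morphometry$window,
                              slope_threshold = config$morphometry$slope_threshold,
                              min_extent = config$morphometry$min_extent)
    morph_rows[[i]] <- cbind(case_id = i, mm$summary)
    profiles[[i]] <- mm
  }
  morph <- do.call(rbind, morph_rows)
  morph_path <- file.path(out, "morphometry", "compression_volumes.csv")
  utils::write.csv(morph, morph_path, row.names = FALSE)
  write_sidecar(file.path(out, "morphometry", "sidecar.json"),
                config$morphometry, seed)
  manifest$stages$morphometry <- morph_path

  ## -- reliability: two raters, three repeats of the volume measurement
  rt <- make_rater_table(morph$total_volume_deficit_mm3 + 500,
                        n_raters = config$raters$n_raters,
                        n_repeats = config$raters$n_repeats,
                        rater_bias_sd = config$raters$rater_bias_sd,
                        residual_sd = config$raters$residual_sd,
                        seed = sub_seed(seed, "raters"))
  inter <- icc_inter(rt)
  intras <- lapply(unique(rt$rater_id), function(r) icc_intra(rt, r))
  rel <- data.frame(
    measure = c("inter", paste0("intra_", unique(rt$rater_id))),
    icc = c(inter$icc, vapply(intras, `[[`, numeric(1), "icc")),
    model = c(inter$model_label, vapply(intras, `[[`, character(1), "model_label")))
  rel_path <- file.path(out, "reliability", "icc.csv")
  utils::write.csv(rel, rel_path, row.names = FALSE)
  rt_path <- file.path(out, "reliability", "rater_table.csv")
  utils::write.csv(rt, rt_path, row.names = FALSE)
  write_sidecar(file.path(out, "reliability", "sidecar.json"), config$raters,
                seed, rt_path)
  manifest$stages$reliability <- rel_path

  ## -- GLM + ROI extraction per subject (right-hand tapping; the
  ##    contralateral/left M1 carries the subject's true percent signal)
  rois <- demo_roi_set(config$bold_shape)
  roi_rows <- list()
  for (i in seq_len(config$n_subjects)) {
    bspec <- bold_phantom_spec(
      volume_shape = config$bold_shape,
      n_segments = config$paradigm$n_segments,
      segment_duration = config$paradigm$segment_duration,
      tr = config$paradigm$tr,
      active_rois = list(list(mask = rois$rois$M1_left$mask,
                              true_percent_signal = psc_true[i])),
      noise_sd = 5, seed = sub_seed(seed, "bold") + i)
    ph <- make_bold_phantom(bspec)
    des <- design_matrix(build_task_regressor(ph$paradigm), ph$motion)
    sm <- fit_glm(ph$run, des)
    cl <- cluster_threshold(sm, z_threshold = config$glm$z_threshold,
                            alpha = config$glm$alpha,
                            method = config$glm$correction,
                            n_perm = config$n_perm,
                            seed = sub_seed(seed, "perm") + i)
    met <- extract_all(sm, cl, rois, hand = "right")
    roi_rows[[i]] <- cbind(case_id = i, met)
  }
  roi_tab <- do.call(rbind, roi_rows)
  roi_path <- file.path(out, "roi", "roi_metrics.csv")
  utils::write.csv(roi_tab, roi_path, row.names = FALSE)
  write_sidecar(file.path(out, "glm", "sidecar.json"), config$glm, seed)
  write_sidecar(file.path(out, "roi", "sidecar.json"),
                list(atlas = "synthetic", hand = "right"), seed)
  manifest$stages$roi <- roi_path

  ## -- association battery on the merged cohort
  wide <- stats::reshape(
    roi_tab[, c("case_id", "roi", "percent_bold", "voa_mm3")],
    idvar = "case_id", timevar = "roi", direction = "wide", sep = "_")
  names(wide) <- sub("^percent_bold_", "pb_", names(wide))
  names(wide) <- sub("^voa_mm3_", "voa_", names(wide))
  names(wide)[-1] <- paste0(names(wide)[-1], "_right")
  cohort <- merge(morph[, c("case_id", "total_volume_deficit_mm3")], wide, by = "case_id")
  names(cohort)[2] <- "compression_volume"
  pairs <- data.frame(x = "compression_volume",
                      y = grep("^(pb|voa)_", names(cohort), value = TRUE))
  battery <- format_battery(correlation_battery(cohort, pairs))
  assoc_path <- file.path(out, "association", "battery.csv")
  utils::write.csv(battery, assoc_path, row.names = FALSE)
  cohort_path <- file.path(out, "association", "cohort.csv")
  utils::write.csv(cohort, cohort_path, row.names = FALSE)
  write_sidecar(file.path(out, "association", "sidecar.json"),
                list(pairs = nrow(pairs)), seed, cohort_path)
  manifest$stages$association <- assoc_path

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Synthetic motor-network ROI set for phantom studies
#'
#' Eight small block ROIs on a given grid: lateralized M1, S1, SMA, PMC
#' (left in the left half of the grid, right in the right half) and
#' bilateral cerebellum, putamen, caudate, thalamus.
#'
#' @param volume_shape Grid dimensions (length 3).
#' @return A [roi_set()].
#' @export
demo_roi_set <- function(volume_shape = c(14, 14, 10)) {
  d <- volume_shape
  block <- function(x, y, z) {
    m <- array(0, d)
    m[x, y, z] <- 1
    m
  }
  half <- floor(d[1] / 2)
  lx <- 1:max(2, half - 1)
  rx <- min(d[1] - 1, half + 2):d[1]
  ys <- seq(2, d[2] - 1, length.out = 4)
  yband <- function(k) max(1, round(ys[k]) - 1):min(d[2], round(ys[k]) + 1)
  top <- max(1, d[3] - 2):d[3]
  mid <- max(1, round(d[3] / 2) - 1):min(d[3], round(d[3] / 2) + 1)
  bot <- 1:min(3, d[3])
  rois <- list()
  for (k in seq_along(cortical_roi_names)) {
    nm <- cortical_roi_names[k]
    rois[[paste0(nm, "_left")]] <- list(mask = block(lx, yband(k), top), laterality = "left")
    rois[[paste0(nm, "_right")]] <- list(mask = block(rx, yband(k), top), laterality = "right")
  }
  for (k in seq_along(subcortical_roi_names)) {
    nm <- subcortical_roi_names[k]
    zb <- if (nm == "cerebellum") bot else mid
    rois[[nm]] <- list(mask = block(1:d[1], yband(k), zb), laterality = "bilateral")
  }
  roi_set(rois, provenance = "synthetic")
}
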