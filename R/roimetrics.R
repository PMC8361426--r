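# Per-ROI activation summaries: percent BOLD signal and volume of
# activation (VOA) inside atlas-defined cortical and subcortical ROIs.

#' Region-of-interest set on the statistic grid
#'
#' @param rois Named list; each element a list with `mask` (3-D 0/1 or
#'   logical array on the stat-map grid) and `laterality` (`"left"`,
#'   `"right"` or `"bilateral"`).
#' @param provenance Free-text provenance label (e.g.
#'   `"probabilistic-atlas"`, `"label-atlas"`, `"synthetic"`).
#' @return A `roi_set`.
#' @export
roi_set <- function(rois, provenance = "synthetic") {
  if (is.null(names(rois)) || any(names(rois) == "")) stopf("ROIs must be named")
  dims <- NULL
  for (nm in names(rois)) {
    r <- rois[[nm]]
    if (sum(r$mask > 0) == 0) stopf("ROI '%s' is empty", nm)
    if (!r$laterality %in% c("left", "right", "bilateral")) {
      stopf("ROI '%s': laterality must be left, right or bilateral", nm)
    }
    if (is.null(dims)) dims <- dim(r$mask)
    else if (!all(dim(r$mask) == dims)) stopf("ROI '%s' is on a different grid", nm)
  }
  structure(list(rois = rois, provenance = provenance), class = "roi_set")
}

#' Threshold a probabilistic atlas map into a binary ROI mask
#'
#' @param prob_map 3-D array of probabilities in percent (0-100).
#' @param threshold Inclusion threshold in percent (default 25, a common
#'   atlas-thresholding convention).
#' @param target_dim Optional grid to resample to (nearest neighbour).
#' @param name ROI name used in error messages.
#' @return Logical 3-D mask.
#' @export
threshold_probabilistic_roi <- function(prob_map, threshold = 25,
                                        target_dim = NULL, name = "roi") {
  if (min(prob_map) < 0 || max(prob_map) > 100) {
    stopf("probabilities must lie in [0, 100]")
  }
  # at threshold 0 the mask is the map's support, not the whole grid
  mask <- if (threshold > 0) prob_map >= threshold else prob_map > 0
  if (!is.null(target_dim) && !all(dim(mask) == target_dim)) {
    mask <- resample_nearest(mask, target_dim)
  }
  if (sum(mask) == 0) stopf("ROI '%s' is empty after thresholding at %g%%", name, threshold)
  mask
}

# Nearest-neighbour resampling of a 3-D array onto a new grid, aligning
# voxel centres of the two fields of view.
resample_nearest <- function(arr, target_dim) {
  d <- dim(arr)
  idx <- lapply(1:3, function(ax) {
    pmin(d[ax], pmax(1, round((seq_len(target_dim[ax]) - 0.5) * d[ax] / target_dim[ax] + 0.5)))
  })
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Percent BOLD signal within an ROI
#'
#' Mean `percent_signal` over the suprathreshold (active) voxels inside
#' the ROI. An empty intersection returns 0 with `flag =
#' "empty-intersection"` rather than a missing value, so that cohort
#' correlations keep one value per patient ("no significant activation"
#' encodes as 0, flagged for audit). The whole-ROI mean is also returned
#' for sensitivity analyses.
#'
#' @param stat A `stat_map`.
#' @param cluster A `cluster_result` on the same grid.
#' @param roi Logical/0-1 mask on the same grid.
#' @return List: `percent_bold`, `percent_bold_whole_roi`,
#'   `n_suprathreshold`, `flag` (`""` or `"empty-intersection"`).
#' @export
roi_percent_bold <- function(stat, cluster, roi) {
  if (!all(dim(stat$percent_signal) == dim(roi))) stopf("ROI grid does not match the stat map")
  sel <- (roi > 0) & cluster$active_mask
  n <- sum(sel)
  list(percent_bold = if (n > 0) mean(stat$percent_signal[sel]) else 0,
       percent_bold_whole_roi = mean(stat$percent_signal[roi > 0]),
       n_suprathreshold = n,
       flag = if (n > 0) "" else "empty-intersection")
}

#' Volume of activation within an ROI
#'
#' @param cluster A `cluster_result`.
#' @param roi Logical/0-1 mask on the same grid.
#' @param voxel_volume Voxel volume in mm^3.
#' @return List: `voa_voxels`, `voa_mm3`.
#' @export
roi_voa <- function(cluster, roi, voxel_volume) {
  if (!all(dim(cluster$active_mask) == dim(roi))) stopf("ROI grid does not match the active mask")
  n <- sum((roi > 0) & cluster$active_mask)
  list(voa_voxels = n, voa_mm3 = n * voxel_volume)
}

# Required ROI families for the motor-network analysis.
cortical_roi_names <- c("M1", "S1", "SMA", "PMC")
subcortical_roi_names <- c("cerebellum", "putamen", "caudate", "thalamus")

#' Extract the full motor-network ROI metric set for one hand
#'
#' Cortical metrics (M1, S1, SMA, PMC) are taken from the hemisphere
#' contralateral to the tapping hand; subcortical metrics (cerebellum,
#' putamen, caudate, thalamus) from bilateral masks. Lateralized ROIs
#' must be present in the set as `<name>_left` / `<name>_right`.
#'
#' @param stat A `stat_map`.
#' @param cluster A `cluster_result`.
#' @param rois A [roi_set()] containing the eight required ROIs.
#' @param hand Tapping hand, `"left"` or `"right"`.
#' @return Data frame with one row per ROI: `roi`, `hand`, `side`,
#'   `percent_bold`, `percent_bold_whole_roi`, `voa_voxels`, `voa_mm3`,
#'   `n_suprathreshold`, `flag`.
#' @export
extract_all <- function(stat, cluster, rois, hand = c("left", "right")) {
  hand <- match.arg(hand)
  stopifnot(inherits(rois, "roi_set"))
  contra <- if (hand == "left") "right" else "left"
  wanted <- c(stats::setNames(paste0(cortical_roi_names, "_", contra), cortical_roi_names),
              stats::setNames(subcortical_roi_names, subcortical_roi_names))
  missing <- setdiff(unname(wanted), names(rois$rois))
  if (length(missing) > 0) stopf("ROI set is missing: %s", paste(missing, collapse = ", "))
  vox_vol <- prod(stat$voxel_dims)
  rows <- lapply(names(wanted), function(short) {
    key <- wanted[[short]]
    mask <- rois$rois[[key]]$mask
    pb <- roi_percent_bold(stat, cluster, mask)
    va <- roi_voa(cluster, mask, vox_vol)
    data.frame(roi = short, hand = hand,
               side = if (short %in% cortical_roi_names) contra else "bilateral",
               percent_bold = pb$percent_bold,
               percent_bold_whole_roi = pb$percent_bold_whole_roi,
               voa_voxels = va$voa_voxels, voa_mm3 = va$voa_mm3,
               n_suprathreshold = pb$n_suprathreshold, flag = pb$flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
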