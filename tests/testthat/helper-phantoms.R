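# Shared fixture builders (all generated in code; nothing on disk).

# Digital-disk lattice-count oracle: number of voxel centres with
# x^2 + y^2 <= r^2 (in voxel units).
lattice_disk_count <- function(r_vox) {
  g <- expand.grid(x = -ceiling(r_vox):ceiling(r_vox),
                   y = -ceiling(r_vox):ceiling(r_vox))
  sum(g$x^2 + g$y^2 <= r_vox^2)
}

# One-box-compression phantom spec with sensible defaults.
box_phantom <- function(extent, reduction, n_slices = 60, center = 30,
                        noise = 0, seed = 1) {
  cord_phantom_spec(
    n_slices = n_slices,
    compressions = list(list(center_slice = center, extent_slices = extent,
                             max_area_reduction = reduction, shape = "box")),
    surface_noise_sd = noise, seed = seed)
}

# Small BOLD phantom with one cubic active ROI, defaulting to the full
# study paradigm (11 x 30 s at TR 1 s).
cube_roi <- function(shape, lo = 3, hi = 5) {
  m <- array(0, shape)
  m[lo:hi, lo:hi, pmin(lo:hi, shape[3])] <- 1
  m
}

small_bold_phantom <- function(psc = 2, noise_sd = 0, shape = c(10, 10, 6),
                               seed = 1, ...) {
  roi <- cube_roi(shape)
  spec <- bold_phantom_spec(volume_shape = shape,
                            active_rois = list(list(mask = roi,
                                                    true_percent_signal = psc)),
                            noise_sd = noise_sd, seed = seed, ...)
  list(spec = spec, roi = roi, phantom = make_bold_phantom(spec))
}
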