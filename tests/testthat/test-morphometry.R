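# Area profiles, compression detection and volume metrics.

test_that("slice area equals voxel count times in-plane area (digital disk oracle)", {
  # radius-4-voxel disk: 49 lattice points with x^2 + y^2 <= 16
  expect_equal(lattice_disk_count(4), 49)
  ph <- make_cord_phantom(cord_phantom_spec(n_slices = 5, voxel_dims = c(0.9, 0.9, 0.9),
                                            baseline_radius = 4 * 0.9))
  prof <- compute_area_profile(ph$mask)
  expect_equal(unname(prof$areas), rep(49 * 0.81, 5))
  expect_length(prof$areas, 5)
})

test_that("all-zero slices yield zero area and non-binary input is rejected", {
  vox <- array(0, c(6, 6, 4)); vox[3:4, 3:4, 2] <- 1
  prof <- compute_area_profile(cord_mask(vox, c(1, 1, 1)))
  expect_equal(unname(prof$areas), c(0, 4, 0, 0))
  vox[1, 1, 1] <- 0.5
  expect_error(cord_mask(vox, c(1, 1, 1)), "binary")
})

test_that("volume conservation: profile sums to mask voxel volume exactly", {
  ph <- make_cord_phantom(box_phantom(7, 0.5, noise = 0.2, seed = 3))
  prof <- compute_area_profile(ph$mask)
  expect_equal(sum(prof$areas) * prof$slice_thickness,
               sum(ph$mask$voxels) * prod(ph$mask$voxel_dims))
})

test_that("scaling in-plane voxel dims by k scales areas by k^2", {
  vox <- array(0, c(8, 8, 3)); vox[3:6, 3:6, ] <- 1
  a1 <- compute_area_profile(cord_mask(vox, c(1, 1, 2)))$areas
  a2 <- compute_area_profile(cord_mask(vox, c(2.5, 2.5, 2)))$areas
  expect_equal(a2, a1 * 2.5^2)
})

test_that("moving-average smoothing: identity, constancy, and a hand-computed case", {
  prof <- structure(list(areas = c(10, 20, 30, 20, 10), smoothed_areas = NULL,
                         slice_thickness = 1, source_id = ""),
                    class = "area_profile")
  expect_equal(smooth_profile(prof, 1)$smoothed_areas, prof$areas)
  expect_error(smooth_profile(prof, 2), "odd")
  # triangular profile, window 3, shrinking edge windows
  expect_equal(smooth_profile(prof, 3)$smoothed_areas,
               c(15, 20, 70 / 3, 20, 15))
  cst <- prof; cst$areas <- rep(7, 5)
  expect_equal(smooth_profile(cst, 3)$smoothed_areas, rep(7, 5))
})

test_that("constant profile yields no detected compression", {
  ph <- make_cord_phantom(cord_phantom_spec(n_slices = 30))
  prof <- smooth_profile(compute_area_profile(ph$mask))
  expect_length(detect_compression(prof), 0)
})

test_that("box compression limits are recovered within one slice of the analytic edges", {
  for (extent in c(3, 8, 15)) {
    for (red in c(0.2, 0.6)) {
      spec <- box_phantom(extent, red)
      ph <- make_cord_phantom(spec)
      gt <- ph$ground_truth[[1]]
      regs <- detect_compression(smooth_profile(compute_area_profile(ph$mask)))
      expect_length(regs, 1)
      expect_lte(abs(regs[[1]]$z_lo - gt$z_lo), 1)
      expect_lte(abs(regs[[1]]$z_hi - gt$z_hi), 1)
    }
  }
})

test_that("two disjoint notches yield two regions in ascending slice order", {
  spec <- cord_phantom_spec(
    n_slices = 80,
    compressions = list(
      list(center_slice = 55, extent_slices = 7, max_area_reduction = 0.5, shape = "box"),
      list(center_slice = 20, extent_slices = 5, max_area_reduction = 0.4, shape = "box")))
  ph <- make_cord_phantom(spec)
  regs <- detect_compression(smooth_profile(compute_area_profile(ph$mask)))
  expect_length(regs, 2)
  expect_lt(regs[[1]]$z_lo, regs[[2]]$z_lo)
  expect_lte(abs(regs[[1]]$z_lo - 18), 1)
  expect_lte(abs(regs[[2]]$z_hi - 58), 1)
})

test_that("gaussian compression is detected near its inflection-point interval", {
  spec <- cord_phantom_spec(
    n_slices = 60,
    compressions = list(list(center_slice = 30, extent_slices = 8,
                             max_area_reduction = 0.5, shape = "gaussian")))
  ph <- make_cord_phantom(spec)
  gt <- ph$ground_truth[[1]]
  regs <- detect_compression(smooth_profile(compute_area_profile(ph$mask)))
  expect_length(regs, 1)
  expect_lte(abs(regs[[1]]$z_lo - gt$z_lo), 2)
  expect_lte(abs(regs[[1]]$z_hi - gt$z_hi), 2)
})

test_that("compression_volume matches the direct slice-sum arithmetic", {
  prof <- structure(list(areas = c(rep(60, 3), 50, 40, 50, rep(60, 3)),
                         smoothed_areas = NULL, slice_thickness = 0.9,
                         source_id = ""), class = "area_profile")
  reg <- structure(list(z_lo = 4, z_hi = 6, cord_volume_in_region = NA,
                        baseline_area = 60, volume_deficit = NA,
                        detection_params = list()),
                   class = "compression_region")
  out <- compression_volume(prof, reg)
  expect_equal(out$cord_volume_in_region, (50 + 40 + 50) * 0.9)
  expect_equal(out$volume_deficit, (10 + 20 + 10) * 0.9)
  # region at baseline everywhere: zero deficit
  reg2 <- reg; reg2$z_lo <- 1; reg2$z_hi <- 3
  expect_equal(compression_volume(prof, reg2)$volume_deficit, 0)
  # out-of-bounds region rejected
  reg3 <- reg; reg3$z_hi <- 99
  expect_error(compression_volume(prof, reg3), "outside")
})

test_that("deficit is robust to surface noise (CV < 10% across seeds)", {
  defs <- vapply(1:20, function(s) {
    ph <- make_cord_phantom(box_phantom(7, 0.5, noise = 0.2, seed = s))
    measure_compression(ph$mask)$summary$total_volume_deficit_mm3
  }, numeric(1))
  expect_lt(sd(defs) / mean(defs), 0.10)
})

test_that("degenerate profiles are rejected with clear errors", {
  empty <- structure(list(areas = rep(0, 10), smoothed_areas = rep(0, 10),
                          slice_thickness = 1, source_id = ""),
                     class = "area_profile")
  expect_error(detect_compression(empty), "nonzero")
  short <- structure(list(areas = rep(5, 4), smoothed_areas = rep(5, 4),
                          slice_thickness = 1, source_id = ""),
                     class = "area_profile")
  expect_error(detect_compression(short, min_extent = 3), "nonzero slices")
})
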