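# ROI extraction: probabilistic thresholding, percent BOLD, VOA,
# laterality handling.

# Build a stat_map/cluster_result pair by hand on a small grid.
fake_stat <- function(psc_vol, z_vol, voxel_dims = c(2.3, 2.3, 2.3)) {
  structure(list(beta = psc_vol, percent_signal = psc_vol, z = z_vol,
                 residual_variance = array(1, dim(psc_vol)), dof = 100,
                 voxel_dims = voxel_dims, tr = 1),
            class = "stat_map")
}
fake_cluster <- function(active) {
  structure(list(active_mask = active, clusters = data.frame(),
                 z_threshold = 3.1, alpha = 0.05, method = "permutation",
                 connectivity = 26),
            class = "cluster_result")
}

test_that("probabilistic ROI thresholding: support, counts, empty rejection", {
  pm <- array(0, c(6, 6, 2))
  pm[1:5, 1:4, 1] <- 30; pm[1:5, 5, 1] <- 10
  expect_equal(sum(threshold_probabilistic_roi(pm, 0)), sum(pm > 0))
  expect_equal(sum(threshold_probabilistic_roi(pm, 25)), 20)
  expect_error(threshold_probabilistic_roi(pm, 100, name = "M1_left"), "M1_left")
  expect_error(threshold_probabilistic_roi(pm * 10), "\\[0, 100\\]")
  # synthetic map with 40 voxels >= 25 -> 40-voxel mask at threshold 25
  pm2 <- array(0, c(10, 10, 1)); pm2[1:8, 1:5, 1] <- 25
  expect_equal(sum(threshold_probabilistic_roi(pm2, 25)), 40)
})

test_that("percent BOLD averages active voxels only; empty intersection flags 0", {
  d <- c(6, 6, 2)
  psc <- array(0, d); psc[1:3, 1:3, 1] <- 2
  act <- array(FALSE, d); act[1:3, 1:3, 1] <- TRUE
  roi <- array(0, d); roi[1:3, 1:6, 1] <- 1     # half active at 2%, half inactive
  st <- fake_stat(psc, psc)
  out <- roi_percent_bold(st, fake_cluster(act), roi)
  expect_equal(out$percent_bold, 2.0)
  expect_equal(out$n_suprathreshold, 9)
  expect_equal(out$flag, "")
  expect_equal(out$percent_bold_whole_roi, mean(psc[roi == 1]))
  # empty intersection
  roi2 <- array(0, d); roi2[4:6, 4:6, 2] <- 1
  out2 <- roi_percent_bold(st, fake_cluster(act), roi2)
  expect_equal(out2$percent_bold, 0)
  expect_equal(out2$flag, "empty-intersection")
})

test_that("VOA arithmetic and set inequality over disjoint ROIs", {
  d <- c(6, 6, 3)
  act <- array(FALSE, d); act[2:4, 2:4, 2] <- TRUE   # 9 active voxels
  cl <- fake_cluster(act)
  roi <- array(0, d); roi[2:4, 2:4, ] <- 1
  vv <- 2.3^3
  out <- roi_voa(cl, roi, vv)
  expect_equal(out$voa_voxels, 9)
  expect_equal(out$voa_mm3, 9 * vv)
  expect_equal(roi_voa(cl, roi, vv)$voa_mm3 / vv, out$voa_voxels)
  # empty active mask -> 0
  expect_equal(roi_voa(fake_cluster(array(FALSE, d)), roi, vv)$voa_voxels, 0)
  # VOA summed over disjoint ROIs <= total active voxels
  roiA <- array(0, d); roiA[2:3, 2:4, 2] <- 1
  roiB <- array(0, d); roiB[4, 2:4, 2] <- 1
  tot <- roi_voa(cl, roiA, vv)$voa_voxels + roi_voa(cl, roiB, vv)$voa_voxels
  expect_lte(tot, sum(act))
})

test_that("raising the cluster-forming threshold never increases VOA", {
  hp <- small_bold_phantom(psc = 3, noise_sd = 3, shape = c(8, 8, 4), seed = 41,
                           n_segments = 11, segment_duration = 10)
  des <- design_matrix(build_task_regressor(hp$phantom$paradigm), hp$phantom$motion)
  sm <- fit_glm(hp$phantom$run, des)
  roi <- array(1, dim(sm$z))
  voas <- vapply(c(1.5, 2.3, 3.1, 4), function(zt) {
    cl <- cluster_threshold(sm, z_threshold = zt, alpha = 1, n_perm = 30, seed = 1)
    roi_voa(cl, roi, 1)$voa_voxels
  }, numeric(1))
  expect_true(all(diff(voas) <= 0))
})

test_that("extract_all reports contralateral cortical and bilateral subcortical metrics", {
  d <- c(14, 14, 10)
  rois <- demo_roi_set(d)
  psc <- array(0, d)
  m1r <- rois$rois$M1_right$mask
  psc[m1r == 1] <- 2
  act <- array(FALSE, d); act[m1r == 1] <- TRUE
  st <- fake_stat(psc, psc)
  cl <- fake_cluster(act)
  # left-hand tapping: cortical metrics from the right hemisphere
  out <- extract_all(st, cl, rois, hand = "left")
  expect_equal(nrow(out), 8)
  expect_equal(out$side[out$roi == "M1"], "right")
  expect_equal(out$percent_bold[out$roi == "M1"], 2)
  expect_equal(out$voa_voxels[out$roi == "M1"], sum(m1r))
  # right-hand tapping on a right-M1-only activation: contralateral M1 VOA = 0
  out2 <- extract_all(st, cl, rois, hand = "right")
  expect_equal(out2$voa_voxels[out2$roi == "M1"], 0)
  expect_equal(out2$flag[out2$roi == "M1"], "empty-intersection")
})

test_that("swapping the hand label swaps hemispheres bit-exactly", {
  d <- c(14, 14, 10)
  rois <- demo_roi_set(d)
  set.seed(3)
  psc <- array(rnorm(prod(d)), d)
  act <- array(runif(prod(d)) > 0.5, d)
  st <- fake_stat(psc, psc)
  cl <- fake_cluster(act)
  left <- extract_all(st, cl, rois, hand = "left")
  right <- extract_all(st, cl, rois, hand = "right")
  for (nm in cortical_names <- c("M1", "S1", "SMA", "PMC")) {
    lrow <- left[left$roi == nm, ]
    # recompute directly from the opposite-hemisphere mask
    mask <- rois$rois[[paste0(nm, "_right")]]$mask
    expect_identical(lrow$voa_voxels, sum(mask > 0 & act))
  }
  # subcortical rows identical across hands
  subc <- c("cerebellum", "putamen", "caudate", "thalamus")
  expect_identical(left[left$roi %in% subc, -2], right[right$roi %in% subc, -2])
  expect_error(extract_all(st, cl, roi_set(rois$rois["M1_left"]), hand = "left"),
               "missing")
})

test_that("nearest-neighbour resampling maps a probabilistic map onto the stat grid", {
  pm <- array(0, c(8, 8, 4)); pm[1:4, , ] <- 80
  mask <- threshold_probabilistic_roi(pm, 25, target_dim = c(4, 4, 2))
  expect_equal(dim(mask), c(4, 4, 2))
  expect_true(all(mask[1:2, , ]))
  expect_false(any(mask[3:4, , ]))
})
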