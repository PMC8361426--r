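# Paradigm construction, HRF, convolution, smoothing, GLM and clustering.

test_that("study paradigm boxcar: 330 samples, 150 active, alternation from rest", {
  par <- paradigm()          # 11 x 30 s at TR 1 s, starting at rest
  bc <- build_paradigm_boxcar(par)
  expect_length(bc, 330)
  expect_equal(sum(bc), 150)       # five active segments of 30 volumes
  expect_equal(bc[1:30], rep(0, 30))
  expect_equal(bc[31:60], rep(1, 30))
})

test_that("boxcar counting identity and start_state handling", {
  par <- paradigm(n_segments = 2, segment_duration = 10, start_state = "active",
                  tr = 2)
  expect_equal(build_paradigm_boxcar(par), c(rep(1, 5), rep(0, 5)))
  for (ns in c(3, 7, 11)) {
    par <- paradigm(n_segments = ns, segment_duration = 12, tr = 3)
    bc <- build_paradigm_boxcar(par)
    expect_equal(sum(bc), (ns %/% 2) * 12 / 3)
  }
  expect_error(paradigm(segment_duration = 10, tr = 3), "integer multiple")
})

test_that("double-gamma HRF has the canonical shape", {
  tr <- 0.1
  h <- double_gamma_hrf(tr)
  t <- seq(0, 32, by = tr)
  expect_equal(h[1], 0)                       # gamma density with shape > 1
  expect_equal(max(h), 1)                     # unit peak
  pk <- t[which.max(h)]
  expect_gt(pk, 4); expect_lt(pk, 7)
  # exactly one sign change: positive lobe then undershoot
  signs <- sign(h[abs(h) > 1e-10])
  expect_equal(sum(diff(signs) != 0), 1)
  expect_error(double_gamma_hrf(1, peak_time = -2), "positive")
})

test_that("convolution identities: zero input, unit impulse, steady state", {
  h <- double_gamma_hrf(1)
  expect_equal(convolve_task(rep(0, 100), h), rep(0, 100))
  imp <- c(1, rep(0, 99))
  expect_equal(convolve_task(imp, h)[seq_along(h)], h, tolerance = 1e-12)
  # sustained boxcar approaches the kernel sum (cumulative-sum oracle)
  resp <- convolve_task(rep(1, 200), h)
  expect_equal(resp[200], sum(h), tolerance = 1e-8)
  expect_equal(resp[seq_along(h)], cumsum(h), tolerance = 1e-8)
  expect_error(convolve_task(rep(1, 10), h), "shorter")
})

test_that("gaussian smoothing: identity at 0, mean preservation, kernel values", {
  img <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  expect_identical(smooth_volume(img, c(2.3, 2.3, 2.3), fwhm = 0), img)
  cst <- array(3.5, c(16, 16, 4))
  expect_equal(smooth_volume(cst, c(2.3, 2.3, 2.3), fwhm = 6), cst)  # kernel normalization
  sm <- smooth_volume(img, c(2.3, 2.3, 2.3), fwhm = 6, mode = "inplane")
  expect_lt(abs(mean(sm) - mean(img)), 0.005)     # reflection keeps the mean near-exact
  # delta image: response matches the sampled Gaussian with sigma fwhm/2.3548
  delta <- array(0, c(31, 31, 1)); delta[16, 16, 1] <- 1
  smd <- smooth_volume(delta, c(2.3, 2.3, 2.3), fwhm = 6, mode = "inplane")
  sigma_vox <- 6 / (2 * sqrt(2 * log(2))) / 2.3
  r <- ceiling(3 * sigma_vox)
  k <- dnorm(-r:r, sd = sigma_vox); k <- k / sum(k)
  expect_equal(smd[16 + (-r:r), 16, 1], k * k[r + 1], tolerance = 1e-10)
  # isotropic3d spreads along z, inplane does not
  delta3 <- array(0, c(11, 11, 11)); delta3[6, 6, 6] <- 1
  sm2 <- smooth_volume(delta3, c(2.3, 2.3, 2.3), fwhm = 6, mode = "inplane")
  sm3 <- smooth_volume(delta3, c(2.3, 2.3, 2.3), fwhm = 6, mode = "isotropic3d")
  expect_equal(sum(abs(sm2[, , 5])), 0)
  expect_gt(sum(abs(sm3[, , 5])), 0)
})

test_that("noiseless phantom recovers the true percent signal to solver tolerance", {
  hp <- small_bold_phantom(psc = 2, noise_sd = 0)
  des <- design_matrix(build_task_regressor(hp$phantom$paradigm), hp$phantom$motion)
  sm <- fit_glm(hp$phantom$run, des)
  expect_equal(max(abs(sm$percent_signal[hp$roi == 1] - 2)), 0, tolerance = 1e-6)
  expect_equal(max(abs(sm$percent_signal[hp$roi == 0])), 0, tolerance = 1e-6)
  expect_equal(sm$dof, 330 - 8)
})

test_that("GLM linearity: adding a constant moves only the intercept", {
  hp <- small_bold_phantom(psc = 1.5, noise_sd = 4, seed = 21)
  des <- design_matrix(build_task_regressor(hp$phantom$paradigm), hp$phantom$motion)
  sm1 <- fit_glm(hp$phantom$run, des)
  run2 <- hp$phantom$run
  run2$data <- run2$data + 250
  sm2 <- fit_glm(run2, des)
  expect_equal(sm2$beta, sm1$beta, tolerance = 1e-9)
  expect_equal(sm2$z, sm1$z, tolerance = 1e-9)
})

test_that("GLM estimator is unbiased over noisy replicates", {
  n_rep <- 60
  betas <- vapply(seq_len(n_rep), function(s) {
    hp <- small_bold_phantom(psc = 2, noise_sd = 10, shape = c(6, 6, 4),
                             seed = s, n_segments = 11, segment_duration = 10)
    des <- design_matrix(build_task_regressor(hp$phantom$paradigm),
                         hp$phantom$motion)
    sm <- fit_glm(hp$phantom$run, des, keep_fit = FALSE)
    mean(sm$percent_signal[hp$roi[, , 1:4] == 1])
  }, numeric(1))
  se <- sd(betas) / sqrt(n_rep)
  expect_lt(abs(mean(betas) - 2), 2.5 * se + 0.02)
})

test_that("rank-deficient designs are rejected naming the collinear columns", {
  x <- build_task_regressor(paradigm(n_segments = 5, segment_duration = 10))
  motion <- cbind(x, x, rnorm(50), rnorm(50), rnorm(50), rnorm(50))
  expect_error(design_matrix(x, motion), "rank deficient")
})

test_that("z is monotone in beta at fixed residual variance", {
  par <- paradigm(n_segments = 5, segment_duration = 10)
  x <- build_task_regressor(par)
  noise <- withr::with_seed(5, rnorm(50, 0, 3))
  zs <- vapply(c(0.5, 1, 2, 4), function(b) {
    y <- array(100 + b * x + noise, c(1, 1, 1, 50))
    fit_glm(y, design_matrix(x), voxel_dims = c(1, 1, 1), keep_fit = FALSE)$z[1, 1, 1]
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("26-connectivity component labelling matches hand-built cases", {
  m <- array(FALSE, c(5, 5, 3))
  m[1:2, 1:2, 1] <- TRUE          # cluster 1 (4 voxels)
  m[4, 4, 1] <- TRUE; m[5, 5, 2] <- TRUE   # diagonal in 3-D: one 26-cluster
  lab <- cordmotor:::label_components(m, 26)
  expect_equal(max(lab), 2)
  expect_equal(sum(lab == lab[1, 1, 1]), 4)
  expect_equal(lab[4, 4, 1], lab[5, 5, 2])
  lab6 <- cordmotor:::label_components(m, 6)
  expect_equal(max(lab6), 3)      # the diagonal pair splits under 6-connectivity
})

test_that("cluster thresholding: empty maps, recovery, and scale invariance", {
  # all-subthreshold map -> empty result
  hp <- small_bold_phantom(psc = 0, noise_sd = 2, shape = c(8, 8, 4), seed = 31,
                           n_segments = 11, segment_duration = 10)
  des <- design_matrix(build_task_regressor(hp$phantom$paradigm), hp$phantom$motion)
  sm <- fit_glm(hp$phantom$run, des)
  sm0 <- sm; sm0$z <- array(0, dim(sm$z))
  expect_equal(nrow(cluster_threshold(sm0, method = "rft")$clusters), 0)
  expect_false(any(cluster_threshold(sm0, method = "rft")$active_mask))

  # strong signal: surviving cluster overlaps the seeded ROI (Dice > 0.5)
  hp2 <- small_bold_phantom(psc = 3, noise_sd = 2, shape = c(8, 8, 4), seed = 32,
                            n_segments = 11, segment_duration = 10)
  roi <- hp2$roi[, , 1:4]
  des2 <- design_matrix(build_task_regressor(hp2$phantom$paradigm), hp2$phantom$motion)
  sm2 <- fit_glm(hp2$phantom$run, des2)
  cl <- cluster_threshold(sm2, n_perm = 200, seed = 1)
  dice <- 2 * sum(cl$active_mask & roi == 1) / (sum(cl$active_mask) + sum(roi))
  expect_gt(dice, 0.5)

  # z is scale-free: multiplying the data leaves the cluster table unchanged
  run3 <- hp2$phantom$run; run3$data <- run3$data * 4.2
  sm3 <- fit_glm(run3, des2)
  cl3 <- cluster_threshold(sm3, n_perm = 200, seed = 1)
  expect_equal(cl3$clusters$size_voxels, cl$clusters$size_voxels)
  expect_equal(cl3$clusters$peak_z, cl$clusters$peak_z, tolerance = 1e-8)
})

test_that("permutation corrected p-values are super-uniform under the null", {
  pvals <- vapply(1:25, function(s) {
    hp <- small_bold_phantom(psc = 0, noise_sd = 5, shape = c(8, 8, 4), seed = 100 + s,
                             n_segments = 11, segment_duration = 10)
    des <- design_matrix(build_task_regressor(hp$phantom$paradigm), hp$phantom$motion)
    sm <- fit_glm(hp$phantom$run, des)
    cl <- cluster_threshold(sm, z_threshold = 2.3, alpha = 1, n_perm = 60, seed = s)
    if (nrow(cl$clusters) == 0) 1 else min(cl$clusters$corrected_p)
  }, numeric(1))
  # under the null, P(min corrected p <= 0.2) <= 0.2; allow binomial slack
  expect_lte(mean(pvals <= 0.2), 0.2 + 2 * sqrt(0.2 * 0.8 / 25))
})
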