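test_that("brain mask applies the total-tissue threshold inclusively", {
  mk <- function(g, w, c) structure(list(
    p_gm = volume_grid(array(g, c(7, 7, 1))),
    p_wm = volume_grid(array(w, c(7, 7, 1))),
    p_csf = volume_grid(array(c, c(7, 7, 1)))), class = "tissue_probmaps")
  expect_equal(unique(as.vector(brain_mask(mk(0.10, 0.10, 0.05))$data)), 0)
  expect_equal(unique(as.vector(brain_mask(mk(0.20, 0.15, 0.00))$data)), 1)
  expect_equal(unique(as.vector(brain_mask(mk(0.15, 0.15, 0.00))$data)), 1)
  expect_equal(unique(as.vector(brain_mask(mk(0, 0, 0))$data)), 0)
  expect_error(brain_mask(mk(1, 0, 0), threshold = 0), "threshold")
  expect_error(brain_mask(mk(1, 0, 0), threshold = 1.5), "threshold")
})

test_that("noiseless mixture is recovered to machine precision", {
  pm <- random_probmaps(c(9, 9, 1), seed = 3)
  img <- vg <- pm$p_gm
  img$data <- 100 * pm$p_gm$data + 50 * pm$p_wm$data + 20 * pm$p_csf$data
  mask <- volume_grid(array(1, c(9, 9, 1)))
  fit <- local_regression(img, list(pm$p_gm, pm$p_wm, pm$p_csf), mask)
  ok <- fit$valid$data != 0
  expect_gt(sum(ok), 0)
  expect_lt(max(abs(fit$coef[[1]]$data[ok] - 100)), 1e-8)
  expect_lt(max(abs(fit$coef[[2]]$data[ok] - 50)), 1e-8)
  expect_lt(max(abs(fit$coef[[3]]$data[ok] - 20)), 1e-8)
})

test_that("pure-tissue windows are flagged invalid with the determined coefficient recovered", {
  shape <- c(9, 9, 1)
  pm <- structure(list(p_gm = volume_grid(array(1, shape)),
                       p_wm = volume_grid(array(0, shape)),
                       p_csf = volume_grid(array(0, shape))),
                  class = "tissue_probmaps")
  img <- volume_grid(array(80, shape))
  mask <- volume_grid(array(1, shape))
  fit <- local_regression(img, list(pm$p_gm, pm$p_wm, pm$p_csf), mask)
  expect_equal(unique(as.vector(fit$valid$data)), 0)
  expect_equal(unique(as.vector(fit$coef[[1]]$data)), 80, tolerance = 1e-10)
})

test_that("coefficients equal a brute-force per-voxel OLS oracle on noisy fixtures", {
  for (seed in c(11, 12)) {
    pm <- random_probmaps(c(9, 9, 3), seed = seed)
    set.seed(seed + 100)
    img <- volume_grid(array(60 * pm$p_gm$data + 25 * pm$p_wm$data +
                               rnorm(9 * 9 * 3, sd = 2), c(9, 9, 3)))
    mask <- volume_grid(array(rbinom(9 * 9 * 3, 1, 0.9), c(9, 9, 3)))
    regs <- list(pm$p_gm, pm$p_wm, pm$p_csf)
    fit <- local_regression(img, regs, mask, kernel = c(5, 5, 1))
    oracle <- brute_force_local_ols(img, regs, mask, c(5, 5, 1))
    ok <- fit$valid$data != 0
    expect_gt(sum(ok), 50)
    for (q in 1:3)
      expect_lt(max(abs(fit$coef[[q]]$data[ok] - oracle[[q]][ok]),
                    na.rm = TRUE), 1e-8)
  }
})

test_that("n_neighbors counts masked window voxels, capped by the kernel size", {
  pm <- random_probmaps(c(9, 9, 1), seed = 5)
  img <- pm$p_gm
  mask <- volume_grid(array(1, c(9, 9, 1)))
  fit <- local_regression(img, list(pm$p_gm, pm$p_wm), mask)
  expect_equal(max(fit$n_neighbors$data), 49)   # 7x7x1 interior window
  expect_equal(fit$n_neighbors$data[1, 1, 1], 16)  # truncated corner
})

test_that("local regression rejects even kernels and empty masks", {
  pm <- random_probmaps(c(9, 9, 1))
  mask0 <- volume_grid(array(0, c(9, 9, 1)))
  expect_error(local_regression(pm$p_gm, list(pm$p_wm), mask0), "empty mask")
  mask1 <- volume_grid(array(1, c(9, 9, 1)))
  expect_error(local_regression(pm$p_gm, list(pm$p_wm), mask1,
                                kernel = c(6, 7, 1)), "odd")
})

test_that("homogeneity: scaling the image scales all coefficient maps", {
  pm <- random_probmaps(c(9, 9, 1), seed = 8)
  set.seed(8)
  img <- volume_grid(array(rnorm(81, mean = 50, sd = 10), c(9, 9, 1)))
  img3 <- img; img3$data <- 3 * img$data
  mask <- volume_grid(array(1, c(9, 9, 1)))
  f1 <- local_regression(img, list(pm$p_gm, pm$p_wm), mask)
  f3 <- local_regression(img3, list(pm$p_gm, pm$p_wm), mask)
  ok <- f1$valid$data != 0
  expect_equal(f3$coef[[1]]$data[ok], 3 * f1$coef[[1]]$data[ok],
               tolerance = 1e-10)
  expect_equal(f3$coef[[2]]$data[ok], 3 * f1$coef[[2]]$data[ok],
               tolerance = 1e-10)
})

test_that("pvec_correct recovers generator magnetizations and delta-M on a noiseless phantom", {
  pm <- small_probmaps(shape = c(16, 16, 4), seed = 2)
  tr <- perfusion_truth(pm, asymmetry_factor = 1)
  acq <- acq_params(noise_sd = 0, n_pairs = 2)
  ser <- simulate_series(pm, tr, acq = acq, seed = 1)
  pv <- pvec_correct(ser$control, ser$label, pm)
  ok <- pv$valid$data != 0
  expect_gt(sum(ok), 100)
  expect_lt(max(abs(pv$m_gm$data[ok] - 100)), 1e-6)
  expect_lt(max(abs(pv$m_wm$data[ok] - 70)), 1e-6)
  expect_lt(max(abs(pv$m_csf$data[ok] - 120)), 1e-6)
  # dm maps equal the forward kinetic signal per slice
  for (k in 1:4) {
    okk <- ok[, , k]
    if (!any(okk)) next
    dm_exp <- forward_delta_m(60, 100, adjusted_pld(k, acq), acq)
    expect_lt(max(abs(pv$dm_gm$data[, , k][okk] - dm_exp)), 1e-8)
  }
})

test_that("pvec_correct runs on a single pair and rejects mismatched frame counts", {
  pm <- small_probmaps(shape = c(12, 12, 2), seed = 3)
  tr <- perfusion_truth(pm, asymmetry_factor = 1)
  ser <- simulate_series(pm, tr, acq = acq_params(noise_sd = 2, n_pairs = 1),
                         seed = 2)
  pv <- pvec_correct(ser$control, ser$label, pm)
  expect_gt(sum(pv$valid$data), 0)
  bad <- ser$label
  bad$data <- bad$data[, , , c(1, 1)]
  dim(bad$data) <- c(12, 12, 2, 2)
  expect_error(pvec_correct(ser$control, bad, pm), "frame-count")
})

test_that("PVEc homogenizes quantified GM flow within an ROI relative to uncorrected quantification", {
  pm <- build_probmaps(c(32, 32, 12), seed = 1)
  tr <- perfusion_truth(pm, asymmetry_factor = 1)  # spatially constant GM flow
  acq <- acq_params(noise_sd = 0)
  ser <- simulate_series(pm, tr, acq = acq, seed = 1)
  pv <- pvec_correct(ser$control, ser$label, pm)
  cm <- quantify_volume(pv, acq)
  at <- build_roi_atlas(pm)
  roi <- at$m1_left$data != 0 | at$m1_right$data != 0
  use <- roi & pv$valid$data != 0 & pm$p_gm$data >= 0.3
  cov_pvec <- sd(cm$cbf_gm$data[use]) / mean(cm$cbf_gm$data[use])
  # uncorrected: voxel ratio of mean difference to mean control
  mean_c <- rowMeans(ser$control$data, dims = 3)
  mean_d <- rowMeans(ser$control$data - ser$label$data, dims = 3)
  shape <- dim(mean_c)
  pld_vox <- array(rep(adjusted_pld(seq_len(shape[3]), acq),
                       each = shape[1] * shape[2]), shape)
  cbf_raw <- cbf_from_ratio(mean_d / mean_c, pld_vox, acq)
  cov_raw <- sd(cbf_raw[use]) / mean(cbf_raw[use])
  expect_lt(cov_pvec, cov_raw)
})
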