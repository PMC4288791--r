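test_that("clip rescales into the window with saturation", {
  w <- intensity_window(100, 200)
  expect_equal(clip_intensity(150, w), 0.5)
  expect_equal(clip_intensity(50, w), 0)
  expect_equal(clip_intensity(250, w), 1)
  expect_equal(clip_intensity(120, w), 0.2)
})

test_that("the integral is the weighted sum of clipped differences", {
  # 3 voxels, D = 2: hand evaluation
  g_b <- volume_grid(array(c(140, 140, 190, rep(100, 24)), c(3, 3, 3)),
                     voxel_size = c(2, 1, 1))
  g_r <- volume_grid(array(c(100, 100, 100, rep(100, 24)), c(3, 3, 3)),
                     voxel_size = c(2, 1, 1))
  w <- intensity_window(100, 200)
  region <- gbsi:::new_boundary_region(
    array(c(1, 0.5, 0, rep(0, 24)), c(3, 3, 3)), "binary_xor")
  # clip diffs: 0.4, 0.4, 0.9 weighted by 1, 0.5, 0 -> 2 * 0.6 = 1.2
  expect_equal(integrate_bsi(g_b, g_r, region, w), 1.2)
  expect_equal(integrate_bsi(g_b, g_b, region, w), 0)
})

test_that("single-voxel integral has the voxel-volume scale and sign", {
  g_b <- volume_grid(array(c(250, rep(100, 7)), c(2, 2, 2)))
  g_r <- volume_grid(array(c(50, rep(100, 7)), c(2, 2, 2)))
  region <- gbsi:::new_boundary_region(
    array(c(1, rep(0, 7)), c(2, 2, 2)), "binary_xor")
  w <- intensity_window(100, 200)
  expect_equal(integrate_bsi(g_b, g_r, region, w), 1)   # atrophy: positive
  expect_equal(integrate_bsi(g_r, g_b, region, w), -1)  # growth: negative
})

test_that("per-voxel contributions are bounded by the voxel volume", {
  p <- random_mask_pair(seed = 41)
  set.seed(42)
  g_b <- volume_grid(array(stats::runif(9^3, 0, 300), c(9, 9, 9)),
                     voxel_size = c(1.3, 1.1, 0.9))
  g_r <- volume_grid(array(stats::runif(9^3, 0, 300), c(9, 9, 9)),
                     voxel_size = c(1.3, 1.1, 0.9))
  region <- gbsi_region(p$A, p$B)
  w <- intensity_window(100, 200)
  d <- clip_intensity(g_b$data, w) - clip_intensity(g_r$data, w)
  contrib <- g_b$voxel_volume * region$weights * d
  expect_true(all(abs(contrib) <= g_b$voxel_volume + 1e-12))
})

test_that("the integral is additive over a split of the region", {
  p <- random_mask_pair(seed = 43)
  set.seed(44)
  g_b <- volume_grid(array(stats::runif(9^3, 50, 250), c(9, 9, 9)))
  g_r <- volume_grid(array(stats::runif(9^3, 50, 250), c(9, 9, 9)))
  region <- gbsi_region(p$A, p$B)
  w <- intensity_window(100, 200)
  half <- array(rep(c(TRUE, FALSE), length.out = 9^3), c(9, 9, 9))
  r1 <- region; r1$weights <- region$weights * half
  r2 <- region; r2$weights <- region$weights * !half
  expect_equal(integrate_bsi(g_b, g_r, r1, w) + integrate_bsi(g_b, g_r, r2, w),
               integrate_bsi(g_b, g_r, region, w), tolerance = 1e-12)
})

test_that("swapping time points negates the integral exactly", {
  p <- random_mask_pair(seed = 47)
  set.seed(48)
  g_b <- volume_grid(array(stats::runif(9^3, 50, 250), c(9, 9, 9)))
  g_r <- volume_grid(array(stats::runif(9^3, 50, 250), c(9, 9, 9)))
  w <- intensity_window(100, 200)
  region_ab <- gbsi_region(p$A, p$B)
  region_ba <- gbsi_region(p$B, p$A)
  expect_equal(integrate_bsi(g_b, g_r, region_ab, w),
               -integrate_bsi(g_r, g_b, region_ba, w), tolerance = 1e-12)
})

test_that("pbvc annualizes against the binarized baseline volume", {
  g <- toy_grid(c(10, 10, 10))
  mask <- prob_mask(array(1, c(10, 10, 10)), g)  # 1000 mm^3
  expect_equal(pbvc(10, mask, 1), 1.0)
  expect_equal(pbvc(10, mask, 2), 0.5)
  expect_equal(pbvc(-5, mask, 0.5), -1.0)
  empty <- prob_mask(array(0, c(10, 10, 10)), g)
  expect_error(pbvc(10, empty, 1), "empty")
})

test_that("an identical pair yields exactly zero for every variant", {
  ph <- small_phantom(atrophy = 0)
  for (variant in c("gbsi", "kn", "pbsi1", "pbsig")) {
    res <- run_bsi(ph$pair, pipeline_config(variant = variant, dbc = FALSE))
    expect_equal(res$bsi_mm3, 0, info = variant)
    expect_equal(res$pbvc_percent_per_year, 0, info = variant)
  }
})

test_that("the pipeline recovers known loss on a coarse phantom", {
  ph <- small_phantom(atrophy = 0.04)
  res <- run_bsi(ph$pair, pipeline_config(dbc = FALSE))
  expect_lt(abs(res$pbvc_percent_per_year - 4) / 4, 0.15)
  expect_true(res$kappa > 0 && res$kappa <= 1)
  expect_gt(res$region_voxels, 0)
})

test_that("measured atrophy is monotone across variants and loss levels", {
  losses <- c(0.01, 0.02, 0.04)
  for (variant in c("gbsi", "kn")) {
    vals <- vapply(losses, function(f) {
      run_bsi(small_phantom(atrophy = f)$pair,
              pipeline_config(variant = variant, dbc = FALSE))$bsi_mm3
    }, numeric(1))
    expect_true(all(diff(vals) > 0), info = variant)
  }
})

test_that("forcing kappa 1 on binarized masks equals KN with no morphology", {
  ph <- small_phantom(atrophy = 0.02)
  p <- ph$pair
  bin_pair <- scan_pair(p$baseline, p$repeat_,
                        binarize(p$baseline_mask, 0.5),
                        binarize(p$repeat_mask, 0.5),
                        interval_years = p$interval_years)
  res_g <- run_bsi(bin_pair, pipeline_config(variant = "gbsi", dbc = FALSE,
                                             kappa_override = 1))
  res_k <- run_bsi(bin_pair, pipeline_config(variant = "kn", dbc = FALSE,
                                             xor_dilate = 0, xor_erode = 0))
  expect_equal(res_g$bsi_mm3, res_k$bsi_mm3, tolerance = 1e-12)
})

test_that("double-window integration counts loss at both borders", {
  # identical pair: zero
  ph0 <- make_phantom(phantom_spec(grid_shape = c(48, 48, 48), voxel_size = 2,
                                   structure = "shell", atrophy_fraction = 0))
  res0 <- run_bsi(ph0$pair, pipeline_config(window_mode = "double",
                                            dbc = FALSE))
  expect_equal(res0$bsi_mm3, 0)

  # shell structure losing at both borders: double window sees the full
  # loss, the single window only the CSF-facing half
  ph <- make_phantom(phantom_spec(grid_shape = c(48, 48, 48), voxel_size = 2,
                                  structure = "shell",
                                  atrophy_fraction = 0.04))
  truth <- ph$truth$true_pbvc_percent_per_year
  res_d <- run_bsi(ph$pair, pipeline_config(window_mode = "double",
                                            dbc = FALSE))
  res_s <- run_bsi(ph$pair, pipeline_config(window_mode = "single",
                                            dbc = FALSE))
  expect_lt(abs(res_d$pbvc_percent_per_year - truth) / truth, 0.2)
  expect_equal(res_s$pbvc_percent_per_year / res_d$pbvc_percent_per_year,
               0.5, tolerance = 0.2)
})

test_that("stage failures are tagged with the stage name", {
  ph <- small_phantom(atrophy = 0)
  p <- ph$pair
  neg <- volume_grid(p$baseline$data - 1000, p$baseline$voxel_size)
  bad_pair <- scan_pair(neg, neg, p$baseline_mask, p$repeat_mask)
  expect_error(run_bsi(bad_pair, pipeline_config(dbc = TRUE)), "\\[dbc\\]")
})

test_that("bsi_report flattens every result field", {
  ph <- small_phantom(atrophy = 0.02)
  res <- run_bsi(ph$pair, pipeline_config(dbc = FALSE))
  rep <- bsi_report(res)
  expect_true(all(c("variant", "bsi_mm3", "pbvc_percent_per_year", "kappa",
                    "window_csf_gm_low", "window_csf_gm_high",
                    "baseline_volume_mm3", "region_voxels",
                    "config_variant") %in% names(rep)))
  expect_equal(rep$pbvc_percent_per_year, res$pbvc_percent_per_year)
})
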