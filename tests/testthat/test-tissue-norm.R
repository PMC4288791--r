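test_that("kmeans_region binarizes then dilates with 6-connectivity", {
  g <- toy_grid(c(7, 7, 7))
  single <- mask_from_predicate(g, function(i, j, k) i == 4 & j == 4 & k == 4)
  expect_equal(sum(kmeans_region(single, 0)$prob), 1)
  expect_equal(sum(kmeans_region(single, 1)$prob), 7)
  expect_equal(sum(kmeans_region(single, 2)$prob), 25)
  empty <- prob_mask(array(0, c(7, 7, 7)), g)
  expect_error(kmeans_region(empty, 1), "empty")
})

test_that("tissue means recover separated point masses exactly", {
  # region of three constant blocks at 100 / 200 / 300
  dat <- array(100, c(6, 6, 6))
  dat[, , 3:4] <- 200
  dat[, , 5:6] <- 300
  g <- volume_grid(dat)
  region <- prob_mask(array(1, c(6, 6, 6)), g)
  tm <- estimate_tissue_means(g, region)
  expect_equal(c(tm$csf_mean, tm$gm_mean, tm$wm_mean), c(100, 200, 300))
  expect_equal(c(tm$csf_sd, tm$gm_sd, tm$wm_sd), c(0, 0, 0))
})

test_that("fewer than 3 distinct intensities is a degenerate input", {
  dat <- array(rep(c(100, 300), each = 108), c(6, 6, 6))
  g <- volume_grid(dat)
  region <- prob_mask(array(1, c(6, 6, 6)), g)
  expect_error(estimate_tissue_means(g, region), "distinct")
})

test_that("tissue means recover a 3-component Gaussian mixture", {
  set.seed(101)
  n <- 1000
  vals <- c(stats::rnorm(n, 100, 10), stats::rnorm(n, 200, 10),
            stats::rnorm(n, 300, 10))
  # oracle: assignment by nearest true mean
  truth <- c(100, 200, 300)
  assign <- apply(abs(outer(vals, truth, "-")), 1, which.min)
  oracle_means <- tapply(vals, assign, mean)
  shape <- c(15, 15, 15)
  dat <- array(c(vals, rep(200, prod(shape) - 3 * n)), shape)
  g <- volume_grid(dat)
  region <- prob_mask(array(1, shape), g)
  tm <- estimate_tissue_means(g, region)
  got <- c(tm$csf_mean, tm$gm_mean, tm$wm_mean)
  expect_true(all(abs(got - truth) < 2))
  expect_true(all(abs(got - oracle_means) < 1))
})

test_that("cluster labels are sorted by mean regardless of start order", {
  # blocks arranged so the 10th percentile start lands on the top cluster
  dat <- array(c(rep(300, 40), rep(100, 100), rep(200, 76)), c(6, 6, 6))
  g <- volume_grid(dat)
  region <- prob_mask(array(1, c(6, 6, 6)), g)
  tm <- estimate_tissue_means(g, region)
  expect_true(tm$csf_mean < tm$gm_mean && tm$gm_mean < tm$wm_mean)
})

test_that("normalization is identity for matching statistics", {
  tm <- tissue_means(100, 10, 200, 15, 300, 12, interior_mean = 250)
  g <- toy_grid(c(4, 4, 4), data = array(stats::runif(64, 50, 350), c(4, 4, 4)))
  res <- normalize_pair(g, g, tm, tm)
  expect_equal(res$slope, 1)
  expect_equal(res$intercept, 0, tolerance = 1e-10)
  expect_equal(res$repeat_norm$data, g$data)
})

test_that("normalization inverts an exact linear intensity relation", {
  tm_base <- tissue_means(100, 10, 200, 15, 300, 12, interior_mean = 250)
  tm_rep <- tissue_means(200, 20, 400, 30, 600, 24, interior_mean = 500)
  g <- toy_grid(c(4, 4, 4), data = array(200, c(4, 4, 4)))
  res <- normalize_pair(g, g, tm_base, tm_rep)
  expect_equal(res$slope, 0.5)
  expect_equal(res$intercept, 0, tolerance = 1e-9)
})

test_that("normalization equals closed-form OLS on the four tissue points", {
  x <- c(110, 205, 321, 248)  # repeat means: csf, gm, wm, interior
  y <- c(100, 200, 300, 240)  # baseline means
  tm_base <- tissue_means(y[1], 1, y[2], 1, y[3], 1, interior_mean = y[4])
  tm_rep <- tissue_means(x[1], 1, x[2], 1, x[3], 1, interior_mean = x[4])
  g <- toy_grid(c(3, 3, 3), data = array(1, c(3, 3, 3)))
  res <- normalize_pair(g, g, tm_base, tm_rep)
  a_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b_hat <- mean(y) - a_hat * mean(x)
  expect_equal(res$slope, a_hat, tolerance = 1e-12)
  expect_equal(res$intercept, b_hat, tolerance = 1e-12)
})

test_that("normalization is scale-consistent end to end", {
  ph <- small_phantom(atrophy = 0)
  base <- ph$pair$baseline
  scaled <- volume_grid(1.7 * base$data, base$voxel_size)
  region <- kmeans_region(ph$pair$baseline_mask, 3)
  tm_b <- estimate_tissue_means(base, region, mask = ph$pair$baseline_mask)
  tm_s <- estimate_tissue_means(scaled, region, mask = ph$pair$baseline_mask)
  res <- normalize_pair(base, scaled, tm_b, tm_s)
  expect_equal(res$repeat_norm$data, base$data, tolerance = 1e-6)
})

test_that("single window applies the CSF/GM rule and detects collapse", {
  tm <- tissue_means(100, 20, 200, 30, 300, 25)
  w <- single_window(tm)
  expect_equal(c(w$low, w$high), c(120, 170))
  tm0 <- tissue_means(100, 0, 200, 0, 300, 0)
  w0 <- single_window(tm0)
  expect_equal(c(w0$low, w0$high), c(100, 200))
  tm_bad <- tissue_means(100, 60, 200, 50, 300, 25)
  expect_error(single_window(tm_bad), "CSF-GM window collapse")
})

test_that("single window is monotone in the CSF spread", {
  base <- tissue_means(100, 10, 200, 30, 300, 25)
  wider <- tissue_means(100, 25, 200, 30, 300, 25)
  expect_gt(single_window(wider)$low, single_window(base)$low)
  expect_equal(single_window(wider)$high, single_window(base)$high)
})

test_that("double window adds the GM/WM border window", {
  tm <- tissue_means(100, 20, 200, 30, 300, 25)
  w <- double_window(tm)
  expect_equal(c(w$csf_gm$low, w$csf_gm$high), c(120, 170))
  expect_equal(c(w$gm_wm$low, w$gm_wm$high), c(230, 275))
  tm0 <- tissue_means(100, 0, 200, 0, 300, 0)
  w0 <- double_window(tm0)
  expect_equal(c(w0$gm_wm$low, w0$gm_wm$high), c(200, 300))
  tm_bad <- tissue_means(100, 20, 200, 60, 300, 50)
  expect_error(double_window(tm_bad), "GM-WM")
})

test_that("averaging tissue statistics equals averaging window bounds", {
  tm_a <- tissue_means(100, 20, 200, 30, 300, 25)
  tm_b <- tissue_means(110, 10, 220, 20, 310, 15)
  w_avg <- single_window(average_tissue_means(tm_a, tm_b))
  wa <- single_window(tm_a); wb <- single_window(tm_b)
  expect_equal(w_avg$low, (wa$low + wb$low) / 2)
  expect_equal(w_avg$high, (wa$high + wb$high) / 2)
})
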