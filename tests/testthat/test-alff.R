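test_that("compute_alff has the stated analytic normalization", {
  tr <- 2; t_len <- 230
  tt <- (seq_len(t_len) - 1) * tr
  expect_equal(compute_alff(numeric(t_len), tr), 0)
  # sinusoid of amplitude 2 at exactly one in-band bin
  bins <- band_bins(t_len, tr, c(0.01, 0.08))
  f0 <- bins[3] / (t_len * tr)
  s <- 2 * sin(2 * pi * f0 * tt + 0.7)
  expect_equal(compute_alff(s, tr), 2 / length(bins), tolerance = 1e-10)
  # out-of-band sinusoid contributes nothing
  expect_lt(compute_alff(sin(2 * pi * 0.2 * tt), tr), 1e-10)
  # band with no bins errors, naming the resolution
  expect_error(compute_alff(rnorm(16), tr = 0.5, band = c(0.01, 0.08)),
               "resolution")
})

test_that("windowed ALFF matches window-count arithmetic and the DFT oracle", {
  expect_equal(n_windows(230, 30, 1), 201L)
  expect_equal(n_windows(230, 50, 1), 181L)
  expect_equal(n_windows(230, 80, 1), 151L)

  tr <- 2; t_len <- 120
  tt <- (seq_len(t_len) - 1) * tr
  series <- 1.3 * sin(2 * pi * 0.04 * tt + 0.2) + 0.5 * sin(2 * pi * 0.02 * tt)
  b <- bold_image(array(rep(series, each = 4), c(2, 2, 1, t_len)), tr = tr)
  st <- compute_windowed_alff(b, window = 30, step = 3)
  expect_equal(nrow(st$values), n_windows(t_len, 30, 3))
  # independent per-window fft oracle
  oracle <- oracle_windowed_alff(series, tr, 30, 3, c(0.01, 0.08))
  expect_equal(st$values[, 1], oracle, tolerance = 1e-10)
  # stationary sinusoid with full periods per window: all windows identical
  # (exact with detrending off; detrending introduces phase-dependent
  # leakage at the percent level, so only a loose bound holds there)
  s2 <- sin(2 * pi * 0.05 * tt)   # 4 full cycles per 40-TR window
  b2 <- bold_image(array(rep(s2, each = 4), c(2, 2, 1, t_len)), tr = tr)
  v <- compute_windowed_alff(b2, window = 40, detrend_window = FALSE)$values[, 1]
  expect_lt(max(v) - min(v), 1e-8)
  v2 <- compute_windowed_alff(b2, window = 40)$values[, 1]
  expect_lt((max(v2) - min(v2)) / mean(v2), 0.25)
  expect_gt((max(v2) - min(v2)), (max(v) - min(v)))
  # window too short for the band errors
  expect_error(compute_windowed_alff(b, window = 6), "bin")
})

test_that("CV is the sample-SD/mean and behaves at degenerate voxels", {
  expect_equal(oracle_cv(c(1, 2, 3)), 0.5)
  st <- list(values = rbind(c(5, 1), c(5, 2), c(5, 3)),
             voxel_idx = 1:2, dims = c(2, 1, 1),
             mask = array(TRUE, c(2, 1, 1)), affine = diag(4),
             window = 3L, step = 1L, tr = 2, band = c(0.01, 0.08))
  class(st) <- "windowed_alff_stack"
  dm <- compute_dalff_cv(st)
  expect_equal(dm$cv[1, 1, 1], 0)
  expect_equal(dm$cv[2, 1, 1], 0.5)
  # zero-mean voxel flagged, not an error
  st$values[, 1] <- c(-1, 0, 1)
  dm2 <- compute_dalff_cv(st)
  expect_true(dm2$flagged[1, 1, 1])
  expect_equal(dm2$cv[1, 1, 1], 0)
})

test_that("scale equivariance: ALFF scales with c, CV does not", {
  tr <- 2; t_len <- 100
  set.seed(11)
  series <- as.numeric(arima.sim(list(ar = 0.3), t_len)) +
    sin(2 * pi * 0.03 * (1:t_len) * tr)
  a1 <- compute_alff(series, tr)
  a2 <- compute_alff(5 * series, tr)
  expect_equal(a2, 5 * a1, tolerance = 1e-10)
  w1 <- oracle_windowed_alff(series, tr, 40, 5, c(0.01, 0.08))
  w2 <- oracle_windowed_alff(5 * series, tr, 40, 5, c(0.01, 0.08))
  expect_equal(oracle_cv(w2), oracle_cv(w1), tolerance = 1e-10)
})

test_that("standardize_map z-transforms within the mask and is idempotent", {
  mask <- array(TRUE, c(2, 1, 1))
  m <- array(c(1, 3), c(2, 1, 1))
  z <- standardize_map(m, mask)
  expect_equal(as.numeric(z), c(-1, 1) / sqrt(2), tolerance = 1e-10)
  expect_error(standardize_map(array(2, c(2, 1, 1)), mask), "zero")
  set.seed(4)
  mm <- array(rnorm(60), c(5, 4, 3))
  msk <- array(runif(60) > 0.3, c(5, 4, 3))
  z1 <- standardize_map(mm, msk)
  z2 <- standardize_map(z1, msk)
  expect_equal(z1, z2, tolerance = 1e-10)
  expect_equal(mean(z1[msk]), 0, tolerance = 1e-10)
  expect_equal(sd(z1[msk]), 1, tolerance = 1e-10)
  expect_true(all(z1[!msk] == 0))
})
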