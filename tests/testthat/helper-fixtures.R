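# Shared builders for small deterministic fixtures. Everything is generated
# in code; no binary fixtures on disk.

# A tiny 4D image with reproducible noise-free structure plus optional noise.
tiny_bold <- function(dims = c(6, 5, 4), t_len = 64, tr = 2, noise = 0,
                      seed = 1) {
  set.seed(seed)
  tt <- (seq_len(t_len) - 1) * tr
  base <- sin(2 * pi * 0.03 * tt)
  data <- array(0, c(dims, t_len))
  nvox <- prod(dims)
  amp <- matrix(runif(nvox, 0.5, 2), nvox, 1)
  flat <- amp %*% matrix(base, 1, t_len)
  if (noise > 0) flat <- flat + matrix(rnorm(nvox * t_len, sd = noise),
                                       nvox, t_len)
  bold_image(array(flat, c(dims, t_len)), affine = diag(c(3, 3, 3, 1)),
             tr = tr)
}

# Independent windowed-ALFF oracle: per window, linear detrend by explicit
# least squares then plain stats::fft; mean one-sided amplitude over band
# bins. Used to cross-check the matrix-DFT fast path.
oracle_windowed_alff <- function(series, tr, window, step, band,
                                 detrend_window = TRUE) {
  t_len <- length(series)
  W <- floor((t_len - window) / step) + 1
  out <- numeric(W)
  for (i in seq_len(W)) {
    seg <- series[((i - 1) * step + 1):((i - 1) * step + window)]
    if (detrend_window) {
      x <- seq_along(seg)
      seg <- stats::residuals(stats::lm(seg ~ x))
    }
    X <- stats::fft(seg)
    kmax <- floor(window / 2)
    f <- seq_len(kmax) / (window * tr)
    idx <- which(f >= band[1] - 1e-12 & f <= band[2] + 1e-12)
    amp <- 2 * Mod(X[idx + 1]) / window
    amp[idx == window / 2] <- amp[idx == window / 2] / 2
    out[i] <- mean(amp)
  }
  out
}

# Independent CV oracle.
oracle_cv <- function(x) stats::sd(x) / mean(x)

# Small two-group cohort of smooth 3D maps (not via the generator): used for
# inference-module calibration tests where only map-level distribution
# matters.
smooth_null_maps <- function(n, dims, fwhm_mm = 6, voxel = 3, seed = 1) {
  set.seed(seed)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel
  lapply(seq_len(n), function(i) {
    dalff:::.smooth3d(array(rnorm(prod(dims)), dims), rep(sig, 3))
  })
}

fake_covariates <- function(n1, n2, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  data.frame(subject_id = sprintf("s%03d", seq_len(n)),
             group = rep(c("patient", "control"), c(n1, n2)),
             age = runif(n, 20, 80), sex = rbinom(n, 1, 0.5),
             score = rpois(n, 4), stringsAsFactors = FALSE)
}
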