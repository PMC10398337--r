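#' Frequency bins of a discrete spectrum inside an analysis band
#'
#' For a length-`T` series sampled every `tr` seconds, returns the indices
#' `k` (in cycles per series, `k >= 1`) whose frequency `k/(T*tr)` lies in
#' `[f_lo, f_hi]`, both ends included.
#'
#' @param t_len series length (samples).
#' @param tr sampling interval, seconds.
#' @param band `c(f_lo, f_hi)` in Hz, inside `(0, 1/(2*tr))`.
#' @return integer vector of bin indices (may not be empty: errors instead).
#' @export
band_bins <- function(t_len, tr, band) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1])
    stop("band must be c(f_lo, f_hi) with 0 < f_lo < f_hi")
  nyq <- 1 / (2 * tr)
  if (band[2] >= nyq + 1e-12)
    stop("band upper edge ", band[2], " Hz must be below Nyquist ", nyq, " Hz")
  kmax <- floor(t_len / 2)
  f <- seq_len(kmax) / (t_len * tr)
  idx <- which(f >= band[1] - 1e-12 & f <= band[2] + 1e-12)
  if (length(idx) == 0)
    stop(sprintf(
      "no frequency bin falls in [%g, %g] Hz: resolution is 1/(T*tr) = %g Hz for T = %d",
      band[1], band[2], 1 / (t_len * tr), t_len))
  idx
}

#' ALFF of a single time series
#'
#' Amplitude of low-frequency fluctuations: the one-sided amplitude spectrum
#' is computed from the DFT with the normalization that a pure sinusoid of
#' amplitude `A` at bin frequency `f0` yields spectrum value `A` at that bin;
#' ALFF is the mean amplitude over the bins inside `band` (closed on both
#' ends).
#'
#' @param series numeric vector, length >= 8.
#' @param tr sampling interval, seconds.
#' @param band analysis band in Hz (default 0.01-0.08).
#' @return scalar ALFF (same units as the series).
#' @export
compute_alff <- function(series, tr, band = c(0.01, 0.08)) {
  t_len <- length(series)
  if (t_len < 8) stop("series too short (need >= 8 samples)")
  idx <- band_bins(t_len, tr, band)
  x <- stats::fft(series)
  amp <- 2 * Mod(x[idx + 1]) / t_len
  # a bin exactly at Nyquist (even T) is not doubled
  amp[idx == t_len / 2] <- amp[idx == t_len / 2] / 2
  mean(amp)
}

# Precompute the real/imag DFT weight matrices (bins x w), folded with the
# within-window detrending projector when requested, plus per-bin amplitude
# factors.
.window_dft <- function(w, tr, band, detrend_window = TRUE) {
  idx <- band_bins(w, tr, band)
  t0 <- 0:(w - 1)
  ang <- 2 * pi * outer(idx, t0) / w
  C <- cos(ang)
  S <- sin(ang)
  if (detrend_window) {
    X <- cbind(1, t0)
    P <- diag(w) - X %*% solve(crossprod(X), t(X))
    C <- C %*% P
    S <- S %*% P
  }
  fac <- rep(2 / w, length(idx))
  fac[idx == w / 2] <- 1 / w
  list(idx = idx, C = C, S = S, fac = fac)
}

#' Sliding-window ALFF stack
#'
#' Computes window-wise ALFF for every in-mask voxel: window `i` covers
#' volumes `[(i-1)*s + 1, (i-1)*s + w]`, giving `W = floor((T - w)/s) + 1`
#' windows. Each window segment is linearly detrended before its DFT by
#' default (standard practice for windowed spectral estimates).
#'
#' @param bold a [bold_image].
#' @param window window length in TR units.
#' @param step step in TR units (default 1).
#' @param band analysis band in Hz (default 0.01-0.08).
#' @param detrend_window remove a linear trend inside each window (default
#'   TRUE).
#' @return an object of class `windowed_alff_stack`: list with `values`
#'   (W x V matrix, V = in-mask voxels), `voxel_idx` (linear indices into
#'   the 3D grid), `dims`, `mask`, `affine`, `window`, `step`, `tr`, `band`.
#' @export
compute_windowed_alff <- function(bold, window, step = 1L, band = c(0.01, 0.08),
                                  detrend_window = TRUE) {
  t_len <- n_volumes(bold)
  if (window > t_len) stop("window (", window, ") exceeds series length (", t_len, ")")
  if (step < 1) stop("step must be >= 1")
  W <- floor((t_len - window) / step) + 1L
  dft <- .window_dft(window, bold$tr, band, detrend_window)
  d <- dim(bold$data)
  vidx <- which(bold$mask)
  M <- matrix(bold$data, prod(d[1:3]), d[4])[vidx, , drop = FALSE]
  tC <- t(dft$C)
  tS <- t(dft$S)
  values <- matrix(0, W, length(vidx))
  wts <- dft$fac / length(dft$idx)  # amplitude factor folded with band mean
  for (i in seq_len(W)) {
    a <- (i - 1L) * step + 1L
    X <- M[, a:(a + window - 1L), drop = FALSE]
    re <- X %*% tC
    im <- X %*% tS
    values[i, ] <- sqrt(re^2 + im^2) %*% wts
  }
  structure(list(values = values, voxel_idx = vidx, dims = d[1:3],
                 mask = bold$mask, affine = bold$affine,
                 window = as.integer(window), step = as.integer(step),
                 tr = bold$tr, band = band),
            class = "windowed_alff_stack")
}

#' @export
print.windowed_alff_stack <- function(x, ...) {
  cat(sprintf("<windowed_alff_stack> %d windows x %d voxels (w=%d, s=%d, TR=%.3g s)\n",
              nrow(x$values), ncol(x$values), x$window, x$step, x$tr))
  invisible(x)
}

#' Number of sliding windows
#'
#' `W = floor((T - w)/s) + 1` for a length-`T` series.
#'
#' @param t_len series length (volumes).
#' @param window window length (TR units).
#' @param step step (TR units).
#' @return integer window count.
#' @export
n_windows <- function(t_len, window, step = 1L) {
  if (window > t_len) stop("window exceeds series length")
  as.integer(floor((t_len - window) / step) + 1L)
}

#' Coefficient of variation across values
#'
#' Sample standard deviation (denominator n-1) divided by the mean.
#'
#' @param x numeric vector.
#' @return scalar CV; 0 with a warning-free flag when the mean is 0 (see
#'   [compute_dalff_cv]).
#' @export
cv <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}

#' dALFF variability map: CV of windowed ALFF
#'
#' Per voxel, the coefficient of variation (sample SD / mean) of the
#' window-wise ALFF values. Voxels whose across-window mean is zero (or
#' numerically negligible) are set to 0 and flagged rather than producing
#' division errors.
#'
#' @param stack a [compute_windowed_alff] result.
#' @return object of class `dalff_map`: list with `cv` (3D array, 0 outside
#'   mask), `flagged` (3D logical: zero-mean voxels), `window`, `step`,
#'   `affine`, `mask`, `tr`.
#' @export
compute_dalff_cv <- function(stack) {
  W <- nrow(stack$values)
  if (W < 2) stop("need at least 2 windows for a CV")
  mu <- colMeans(stack$values)
  sdv <- sqrt(colSums(sweep(stack$values, 2, mu)^2) / (W - 1))
  eps <- .Machine$double.eps * 100
  zero <- abs(mu) <= eps
  cvv <- numeric(length(mu))
  cvv[!zero] <- sdv[!zero] / mu[!zero]
  cv3d <- array(0, stack$dims)
  cv3d[stack$voxel_idx] <- cvv
  fl <- array(FALSE, stack$dims)
  fl[stack$voxel_idx[zero]] <- TRUE
  structure(list(cv = cv3d, flagged = fl, window = stack$window,
                 step = stack$step, affine = stack$affine, mask = stack$mask,
                 tr = stack$tr),
            class = "dalff_map")
}

#' @export
print.dalff_map <- function(x, ...) {
  cat(sprintf("<dalff_map> w=%d s=%d, %d mask voxels, %d flagged\n",
              x$window, x$step, sum(x$mask), sum(x$flagged)))
  invisible(x)
}

#' Static ALFF map
#'
#' Whole-series ALFF per in-mask voxel (no windowing).
#'
#' @inheritParams compute_windowed_alff
#' @return 3D array, 0 outside the mask.
#' @export
compute_alff_map <- function(bold, band = c(0.01, 0.08)) {
  stack <- compute_windowed_alff(bold, window = n_volumes(bold), step = 1L,
                                 band = band, detrend_window = FALSE)
  out <- array(0, stack$dims)
  out[stack$voxel_idx] <- stack$values[1, ]
  out
}

#' Z-standardize a map within a mask
#'
#' `(v - mean)/sd` over in-mask voxels (sample SD); out-of-mask voxels are
#' set to 0. Applying the transform twice is idempotent.
#'
#' @param map 3D array, or a `dalff_map` (its `cv` field is standardized).
#' @param mask 3D logical mask (required for bare arrays; taken from the
#'   object otherwise).
#' @return same type as the input.
#' @export
standardize_map <- function(map, mask = NULL) {
  if (inherits(map, "dalff_map")) {
    map$cv <- standardize_map(map$cv, map$mask)
    return(map)
  }
  if (is.null(mask)) stop("mask required")
  v <- map[mask]
  if (sum(mask) < 2) stop("need >= 2 in-mask voxels")
  s <- stats::sd(v)
  if (s == 0) stop("cannot standardize: zero within-mask standard deviation")
  out <- array(0, dim(map))
  out[mask] <- (v - mean(v)) / s
  out
}

#' Stack subject 3D maps into a subjects x voxels matrix
#'
#' @param maps list of 3D arrays (or `dalff_map`s) on a shared grid.
#' @param mask 3D logical mask.
#' @return matrix with one row per subject, one column per in-mask voxel.
#' @export
maps_to_matrix <- function(maps, mask) {
  vidx <- which(mask)
  do.call(rbind, lapply(maps, function(m) {
    if (inherits(m, "dalff_map")) m <- m$cv
    m[vidx]
  }))
}

#' Unflatten an in-mask voxel vector to a 3D array
#' @param v numeric vector over in-mask voxels.
#' @param mask 3D logical mask.
#' @param fill value outside the mask (default 0).
#' @return 3D array.
#' @export
vector_to_map <- function(v, mask, fill = 0) {
  out <- array(fill, dim(mask))
  out[which(mask)] <- v
  out
}
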