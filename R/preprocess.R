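#' Discard initial volumes
#'
#' Removes the first `n` time points of a BOLD series (scanner equilibration
#' volumes). Affine, TR and mask are unchanged.
#'
#' @param bold a [bold_image].
#' @param n number of leading volumes to drop (default 10).
#' @return a [bold_image] with `t - n` volumes.
#' @export
discard_initial_volumes <- function(bold, n = 10L) {
  t_len <- n_volumes(bold)
  if (n < 0) stop("n must be >= 0")
  if (n >= t_len) stop("cannot discard ", n, " of ", t_len, " volumes")
  if (n == 0) return(bold)
  bold$data <- bold$data[, , , -(seq_len(n)), drop = FALSE]
  bold
}

# Polynomial design for t time points, orders 0..order, orthonormal columns.
.poly_design <- function(t_len, order) {
  x <- seq_len(t_len)
  if (order == 0) return(matrix(1 / sqrt(t_len), t_len, 1))
  cbind(1 / sqrt(t_len), stats::poly(x, degree = order))
}

# Remove the projection of each row of mat (voxels x t) onto design columns.
.residualize_rows <- function(mat, design) {
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- setdiff(seq_len(ncol(design)), qr_d$pivot[seq_len(qr_d$rank)])
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qr_d, t(mat))
  mat - t(design %*% coefs)
}

#' Detrend voxel time series
#'
#' Removes a least-squares polynomial of the given order (including the
#' constant term) from every voxel's time series.
#'
#' @param bold a [bold_image].
#' @param order polynomial order >= 0 (0 = demean only; default 1).
#' @return detrended [bold_image].
#' @export
detrend <- function(bold, order = 1L) {
  t_len <- n_volumes(bold)
  if (order < 0) stop("order must be >= 0")
  if (order >= t_len) stop("order must be < number of volumes")
  d <- dim(bold$data)
  mat <- matrix(bold$data, prod(d[1:3]), d[4])
  mat <- .residualize_rows(mat, .poly_design(t_len, order))
  bold$data <- array(mat, d)
  bold
}

#' Regress nuisance covariates out of voxel time series
#'
#' Per voxel, replaces the series by the residual of an OLS projection onto
#' `[1, confounds]`. Residuals are orthogonal to every confound column.
#'
#' @param bold a [bold_image].
#' @param confounds t x q numeric matrix of nuisance regressors.
#' @return residualized [bold_image].
#' @export
regress_nuisance <- function(bold, confounds) {
  confounds <- as.matrix(confounds)
  t_len <- n_volumes(bold)
  if (nrow(confounds) != t_len)
    stop("confounds must have ", t_len, " rows, got ", nrow(confounds))
  if (ncol(confounds) < 1) stop("need at least one confound column")
  design <- cbind(intercept = 1, confounds)
  d <- dim(bold$data)
  mat <- matrix(bold$data, prod(d[1:3]), d[4])
  mat <- .residualize_rows(mat, design)
  bold$data <- array(mat, d)
  bold
}

# Reflective (symmetric, edge-repeating) boundary index for position i on 1..n.
.reflect_index <- function(i, n) {
  period <- 2L * n
  i <- ((i - 1L) %% period + period) %% period + 1L
  ifelse(i > n, period - i + 1L, i)
}

# n x n smoothing matrix for a 1D Gaussian with sd sigma (voxels), reflective
# padding; rows sum to exactly 1 so flat fields are invariant.
.gauss_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  offs <- (-r):r
  w <- exp(-offs^2 / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- .reflect_index(i + offs, n)
    for (j in seq_along(idx)) K[i, idx[j]] <- K[i, idx[j]] + w[j]
  }
  K
}

# Apply separable Gaussian smoothing (sigma in voxels per axis) to a 3D array.
.smooth3d <- function(vol, sigma_vox) {
  d <- dim(vol)
  if (sigma_vox[1] > 0) {
    K <- .gauss_matrix(d[1], sigma_vox[1])
    vol <- array(K %*% matrix(vol, d[1], d[2] * d[3]), d)
  }
  if (sigma_vox[2] > 0) {
    K <- .gauss_matrix(d[2], sigma_vox[2])
    vol <- aperm(array(K %*% matrix(aperm(vol, c(2, 1, 3)), d[2], d[1] * d[3]),
                       c(d[2], d[1], d[3])), c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    K <- .gauss_matrix(d[3], sigma_vox[3])
    vol <- aperm(array(K %*% matrix(aperm(vol, c(3, 1, 2)), d[3], d[1] * d[2]),
                       c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  vol
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Spatially smooth each volume with a Gaussian kernel
#'
#' Per-volume separable 3D Gaussian smoothing with reflective boundary
#' handling (flat fields are preserved exactly). FWHM is given in mm and
#' converted to voxels through the voxel size.
#'
#' @param bold a [bold_image] or a 3D array wrapped as [nifti_image].
#' @param fwhm_mm scalar or length-3 FWHM in mm (0 = no smoothing).
#' @return smoothed object of the same class.
#' @export
smooth_bold <- function(bold, fwhm_mm = 6) {
  if (any(fwhm_mm < 0)) stop("fwhm must be >= 0")
  fwhm_mm <- rep(fwhm_mm, length.out = 3)
  if (all(fwhm_mm == 0)) return(bold)
  vs <- sqrt(colSums(bold$affine[1:3, 1:3]^2))
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / vs
  if (inherits(bold, "bold_image")) {
    d <- dim(bold$data)
    for (t in seq_len(d[4])) {
      bold$data[, , , t] <- .smooth3d(bold$data[, , , t], sigma_vox)
    }
  } else {
    bold$data <- .smooth3d(bold$data, sigma_vox)
  }
  bold
}

#' Fixed-order preprocessing chain
#'
#' Applies, in this order: discard initial volumes, polynomial detrend,
#' optional nuisance regression, spatial smoothing. The order is fixed; each
#' step can be disabled by its argument.
#'
#' @param bold a [bold_image].
#' @param n_discard leading volumes to drop (default 10).
#' @param detrend_order polynomial order (default 1; `NA` to skip).
#' @param confounds optional t x q confound matrix (after discarding), or NULL.
#' @param fwhm_mm smoothing FWHM in mm (default 6; 0 to skip).
#' @return preprocessed [bold_image].
#' @export
preprocess_bold <- function(bold, n_discard = 10L, detrend_order = 1L,
                            confounds = NULL, fwhm_mm = 6) {
  bold <- discard_initial_volumes(bold, n_discard)
  if (!is.na(detrend_order)) bold <- detrend(bold, detrend_order)
  if (!is.null(confounds)) bold <- regress_nuisance(bold, confounds)
  smooth_bold(bold, fwhm_mm)
}
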