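#' Label connected components of a 3D binary mask
#'
#' Flood-fill labeling under 6-, 18- or 26-neighbour connectivity
#' (26 = faces, edges and corners, the common fMRI toolbox convention).
#'
#' @param mask 3D logical array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return 3D integer array; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  deg <- abs(offs$di) + abs(offs$dj) + abs(offs$dk)
  keep <- switch(as.character(connectivity),
                 "6" = deg == 1, "18" = deg >= 1 & deg <= 2, "26" = deg >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  offs <- offs[keep, ]
  lab <- array(0L, d)
  lab[mask] <- -1L
  idx <- which(mask)
  d12 <- d[1] * d[2]
  next_label <- 0L
  stack <- integer(length(idx))
  for (seed in idx) {
    if (lab[seed] != -1L) next
    next_label <- next_label + 1L
    top <- 1L
    stack[1L] <- seed
    lab[seed] <- next_label
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      v0 <- v - 1L
      k <- v0 %/% d12
      r <- v0 - k * d12
      j <- r %/% d[1]
      i <- r - j * d[1]
      for (o in seq_len(nrow(offs))) {
        ii <- i + offs$di[o]; jj <- j + offs$dj[o]; kk <- k + offs$dk[o]
        if (ii < 0L || ii >= d[1] || jj < 0L || jj >= d[2] ||
            kk < 0L || kk >= d[3]) next
        w <- ii + jj * d[1] + kk * d12 + 1L
        if (lab[w] == -1L) {
          lab[w] <- next_label
          top <- top + 1L
          stack[top] <- w
        }
      }
    }
  }
  lab
}

# Build the [intercept, group, covariates...] design. Group is coded
# patient = 1, control = 0 so the contrast is patient - control; age is
# mean-centered, sex passed through as 0/1.
.group_design <- function(covariates, use_covariates = c("age", "sex")) {
  grp_levels <- unique(covariates$group)
  patient_level <- if ("patient" %in% grp_levels) "patient" else grp_levels[1]
  g <- as.numeric(covariates$group == patient_level)
  X <- cbind(intercept = 1, group = g)
  for (v in use_covariates) {
    col <- as.numeric(covariates[[v]])
    if (v == "age") col <- col - mean(col)
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- v
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qr_x$pivot[seq_len(qr_x$rank)])]
    stop("design is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  if (any(sds == 0))
    stop("constant covariate column(s): ",
         paste(names(sds)[sds == 0], collapse = ", "))
  list(X = X, patient_level = patient_level)
}

# t statistics for one design column across all voxels of Y (n x V).
.glm_tstats <- function(X, Y, col) {
  n <- nrow(X); p <- ncol(X)
  XtX_inv <- solve(crossprod(X))
  B <- XtX_inv %*% crossprod(X, Y)
  resid <- Y - X %*% B
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(XtX_inv[col, col] * sigma2)
  tval <- numeric(ncol(Y))
  ok <- se > 0
  tval[ok] <- B[col, ok] / se[ok]
  list(t = tval, df = df, residuals = resid, se_zero = !ok)
}

#' Voxelwise two-group GLM with covariates
#'
#' Per voxel, OLS on `[intercept, group, covariates]` with the t statistic
#' for the group column (contrast patient - control); `df = n - p`.
#'
#' @param maps subjects x voxels matrix (e.g. [maps_to_matrix]), rows in
#'   covariate-table order.
#' @param covariates validated covariate data.frame (see
#'   [validate_covariates]).
#' @param use_covariates names of nuisance covariate columns (default age
#'   and sex; use `character(0)` for a plain two-sample t-test).
#' @param mask,affine optional geometry carried along for cluster reporting.
#' @return object of class `group_glm_result`: list with `t` (voxel vector),
#'   `df`, `design`, `residuals` (n x V), `contrast`, `mask`, `affine`.
#' @export
fit_voxelwise_glm <- function(maps, covariates, use_covariates = c("age", "sex"),
                              mask = NULL, affine = NULL) {
  covariates <- validate_covariates(covariates)
  if (nrow(maps) != nrow(covariates))
    stop("maps rows (", nrow(maps), ") must match covariate rows (",
         nrow(covariates), ")")
  if (min(table(covariates$group)) < 3)
    stop("need at least 3 subjects per group")
  des <- .group_design(covariates, use_covariates)
  fit <- .glm_tstats(des$X, maps, col = 2L)
  structure(list(t = fit$t, df = fit$df, residuals = fit$residuals,
                 design = des$X,
                 contrast = paste0(des$patient_level, " - other"),
                 mask = mask, affine = affine),
            class = "group_glm_result")
}

#' One-sample t map
#'
#' Per-voxel mean / standard error with `df = n - 1`. Zero-variance voxels
#' do not produce infinities: zero-mean ones return 0, nonzero-mean ones are
#' capped at `t_cap`; both are flagged.
#'
#' @param maps subjects x voxels matrix.
#' @param t_cap cap for infinite t (default 1e6).
#' @return list with `t`, `df`, `flagged` (logical vector).
#' @export
one_sample_tmap <- function(maps, t_cap = 1e6) {
  n <- nrow(maps)
  if (n < 2) stop("need at least 2 subjects")
  mu <- colMeans(maps)
  se <- sqrt(apply(maps, 2, stats::var) / n)
  tval <- numeric(length(mu))
  flagged <- se == 0
  ok <- !flagged
  tval[ok] <- mu[ok] / se[ok]
  tval[flagged & mu != 0] <- sign(mu[flagged & mu != 0]) * t_cap
  list(t = tval, df = n - 1L, flagged = flagged)
}

#' Estimate spatial smoothness (FWHM) of residual maps
#'
#' Per-axis FWHM of the effective Gaussian smoothness, from the variance of
#' lag-1 spatial differences of globally standardized residual maps: for a
#' Gaussian autocorrelation `rho(delta) = exp(-delta^2/(4 sigma^2))`,
#' `E[(z(x+1)-z(x))^2] = 2 (1 - rho(1))`, inverted for `sigma` and converted
#' to mm. Correlations are clamped so unsmoothed noise reports a voxel-scale
#' lower bound rather than zero.
#'
#' @param residuals n x V matrix over in-mask voxels, or list of 3D arrays.
#' @param mask 3D logical mask.
#' @param voxel_size length-3 voxel size in mm.
#' @return length-3 FWHM in mm.
#' @export
estimate_smoothness <- function(residuals, mask, voxel_size) {
  if (is.list(residuals))
    residuals <- do.call(rbind, lapply(residuals, function(m) m[which(mask)]))
  if (nrow(residuals) < 2) stop("need >= 2 residual maps")
  if (sum(mask) == 0) stop("empty mask")
  d <- dim(mask)
  vidx <- which(mask)
  pos <- arrayInd(vidx, d)
  row_of <- array(0L, d)
  row_of[vidx] <- seq_along(vidx)
  fwhm <- numeric(3)
  for (ax in 1:3) {
    nb <- pos
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    nb_lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    j <- row_of[nb_lin]
    pair_i <- which(ok)[j > 0]
    pair_j <- j[j > 0]
    if (length(pair_i) == 0) stop("mask too thin along axis ", ax)
    num <- 0; den <- 0
    for (r in seq_len(nrow(residuals))) {
      z <- residuals[r, ]
      s <- stats::sd(z)
      if (s == 0) stop("flat residual map ", r, ": smoothness undefined")
      z <- z / s
      num <- num + mean((z[pair_i] - z[pair_j])^2)
      den <- den + 1
    }
    rho <- 1 - (num / den) / 2
    rho <- min(max(rho, 0.05), 1 - 1e-6)
    sigma_vox <- sqrt(-1 / (4 * log(rho)))
    fwhm[ax] <- 2 * sqrt(2 * log(2)) * sigma_vox * voxel_size[ax]
  }
  fwhm
}

# Random-field expected number of clusters above z in a 3D search region of
# `resels` resels (leading EC-density term), and the corrected cluster-level
# p for an extent of k voxels.
.rft_expected_clusters <- function(z, resels) {
  resels * (4 * log(2))^1.5 * (2 * pi)^-2 * (z^2 - 1) * exp(-z^2 / 2)
}

.rft_cluster_p <- function(k_voxels, z, resels, n_mask_voxels) {
  Em <- max(.rft_expected_clusters(z, resels), .Machine$double.xmin)
  EV <- n_mask_voxels * stats::pnorm(z, lower.tail = FALSE)
  nbar <- max(EV / Em, .Machine$double.xmin)
  beta <- (gamma(5 / 2) / nbar)^(2 / 3)
  p_extent <- exp(-beta * k_voxels^(2 / 3))
  1 - exp(-Em * p_extent)
}

#' Cluster table from a thresholded statistic map
#'
#' One row per connected component: size in voxels, peak statistic (max
#' absolute value), its world (mm) coordinates through the affine, the sign
#' of the component, and an optional atlas label looked up at the peak.
#'
#' @param stat_map 3D statistic array.
#' @param supra_mask 3D logical array of suprathreshold voxels.
#' @param affine 4x4 voxel-to-world matrix.
#' @param atlas optional integer-labeled 3D atlas.
#' @param connectivity component connectivity (default 26).
#' @return data.frame (class `cluster_table`) with columns cluster_id,
#'   n_voxels, peak_stat, peak_x/y/z (mm), sign, label; the integer label
#'   map is attached as attribute `label_map`.
#' @export
extract_cluster_table <- function(stat_map, supra_mask, affine, atlas = NULL,
                                  connectivity = 26L) {
  lab <- label_components(supra_mask, connectivity)
  n_cl <- max(lab)
  rows <- vector("list", n_cl)
  for (cl in seq_len(n_cl)) {
    vidx <- which(lab == cl)
    vals <- stat_map[vidx]
    peak_i <- vidx[which.max(abs(vals))]
    peak_val <- stat_map[peak_i]
    ijk <- arrayInd(peak_i, dim(stat_map))
    xyz <- voxel_to_world(ijk, affine)
    rows[[cl]] <- data.frame(
      cluster_id = cl, n_voxels = length(vidx), peak_stat = peak_val,
      peak_x = xyz[1], peak_y = xyz[2], peak_z = xyz[3],
      sign = if (peak_val >= 0) "+" else "-",
      label = if (is.null(atlas)) NA_integer_ else atlas[peak_i])
  }
  out <- if (n_cl == 0) {
    data.frame(cluster_id = integer(0), n_voxels = integer(0),
               peak_stat = numeric(0), peak_x = numeric(0),
               peak_y = numeric(0), peak_z = numeric(0),
               sign = character(0), label = integer(0))
  } else do.call(rbind, rows)
  attr(out, "label_map") <- lab
  class(out) <- c("cluster_table", class(out))
  out
}

# t -> z by matching tail probabilities, sign-safe for moderate df.
t_to_z <- function(tval, df) {
  sign(tval) * stats::qnorm(stats::pt(abs(tval), df, lower.tail = FALSE),
                            lower.tail = FALSE)
}

#' Gaussian-random-field cluster-level correction
#'
#' Converts the group t map to z, thresholds each tail at `voxel_p/2`
#' (two-tailed default), forms connected components separately for positive
#' and negative excursions, converts the mask volume to resels with the
#' estimated per-axis FWHM, computes the random-field corrected cluster p
#' (expected-cluster-count and extent-tail approximation) and keeps clusters
#' with corrected p below `cluster_p`.
#'
#' @param result a `group_glm_result` (or any list with `t`, `df`).
#' @param mask 3D logical analysis mask.
#' @param affine 4x4 voxel-to-world matrix.
#' @param voxel_p voxel-level threshold (default 0.05, two-tailed).
#' @param cluster_p cluster-level corrected threshold (default 0.05).
#' @param fwhm per-axis smoothness in mm; estimated from `result$residuals`
#'   when NULL.
#' @param two_tailed correct positive and negative excursions separately at
#'   `voxel_p/2` each (default TRUE).
#' @param connectivity component connectivity (default 26).
#' @param atlas optional labeled atlas for peak lookup.
#' @return `cluster_table` with extra columns `p_corrected` and `method`;
#'   attribute `label_map` holds the surviving-cluster labels, attribute
#'   `details` the threshold, FWHM and resel count.
#' @export
grf_cluster_correct <- function(result, mask, affine, voxel_p = 0.05,
                                cluster_p = 0.05, fwhm = NULL,
                                two_tailed = TRUE, connectivity = 26L,
                                atlas = NULL) {
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1)
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (is.null(fwhm)) {
    if (is.null(result$residuals))
      stop("no FWHM given and no residuals available to estimate it")
    fwhm <- estimate_smoothness(result$residuals, mask, voxel_size)
  }
  fwhm <- rep(fwhm, length.out = 3)
  if (any(fwhm < voxel_size)) {
    warning("estimated FWHM below voxel size on some axis; ",
            "falling back to voxel-sized resels there")
    fwhm <- pmax(fwhm, voxel_size)
  }
  n_mask <- sum(mask)
  resels <- n_mask * prod(voxel_size / fwhm)
  z <- t_to_z(result$t, result$df)
  z_map <- vector_to_map(z, mask)
  tail_p <- if (two_tailed) voxel_p / 2 else voxel_p
  z_thr <- stats::qnorm(tail_p, lower.tail = FALSE)

  collect <- function(supra, sign_label) {
    ct <- extract_cluster_table(z_map, supra, affine, atlas, connectivity)
    if (nrow(ct) == 0) return(ct)
    ct$sign <- sign_label
    ct$p_corrected <- vapply(ct$n_voxels, .rft_cluster_p, numeric(1),
                             z = z_thr, resels = resels,
                             n_mask_voxels = n_mask)
    ct
  }
  pos <- collect(vector_to_map(z, mask, fill = -Inf) >= z_thr & mask, "+")
  tabs <- list(pos)
  if (two_tailed) {
    tabs <- c(tabs, list(collect(vector_to_map(z, mask, fill = Inf) <= -z_thr & mask, "-")))
  }
  lab_maps <- lapply(tabs, attr, "label_map")
  out <- do.call(rbind, lapply(tabs, function(x) { attr(x, "label_map") <- NULL; x }))
  keep <- out$p_corrected < cluster_p
  # rebuild a label map holding only surviving clusters, renumbered
  final_lab <- array(0L, dim(mask))
  new_id <- 0L
  kept_rows <- list()
  row_i <- 0L
  for (ti in seq_along(tabs)) {
    tab <- tabs[[ti]]
    for (r in seq_len(nrow(tab))) {
      row_i <- row_i + 1L
      if (!keep[row_i]) next
      new_id <- new_id + 1L
      final_lab[lab_maps[[ti]] == tab$cluster_id[r]] <- new_id
      row <- out[row_i, ]
      row$cluster_id <- new_id
      kept_rows[[new_id]] <- row
    }
  }
  res <- if (new_id == 0) out[0, ] else do.call(rbind, kept_rows)
  res$method <- rep("GRF", nrow(res))
  rownames(res) <- NULL
  attr(res, "label_map") <- final_lab
  attr(res, "details") <- list(z_threshold = z_thr, fwhm = fwhm,
                               resels = resels, voxel_p = voxel_p,
                               cluster_p = cluster_p, two_tailed = two_tailed)
  class(res) <- c("cluster_table", class(res))
  res
}

#' Permutation-based cluster correction (oracle for the GRF route)
#'
#' Permutes group labels (covariates kept with their subjects), rebuilds the
#' voxelwise GLM each time, and records the maximum cluster size over both
#' excursion tails at the voxel threshold; observed clusters are kept when
#' their size exceeds the permutation-null `(1 - cluster_p)` quantile
#' (p computed with the add-one convention).
#'
#' @inheritParams grf_cluster_correct
#' @param maps subjects x voxels matrix.
#' @param covariates covariate data.frame.
#' @param use_covariates nuisance covariate columns (default age, sex).
#' @param n_perm number of permutations (>= 100; capped with a warning at
#'   the number of distinct group relabelings).
#' @param seed RNG seed for the permutations.
#' @return `cluster_table` with `p_corrected` and `method = "permutation"`;
#'   attribute `label_map` as in [grf_cluster_correct], attribute `details`
#'   holds the null maximum-size distribution.
#' @export
permutation_cluster_correct <- function(maps, covariates,
                                        use_covariates = c("age", "sex"),
                                        mask, affine,
                                        voxel_p = 0.05, cluster_p = 0.05,
                                        n_perm = 1000L, seed = 1L,
                                        two_tailed = TRUE, connectivity = 26L,
                                        atlas = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  covariates <- validate_covariates(covariates)
  n <- nrow(covariates)
  n1 <- sum(covariates$group == covariates$group[1])
  distinct <- choose(n, n1)
  if (distinct < 10)
    stop("degenerate design: only ", distinct, " distinct group relabelings")
  if (n_perm > distinct) {
    warning("n_perm capped at ", distinct, " distinct relabelings")
    n_perm <- distinct
  }
  obs <- fit_voxelwise_glm(maps, covariates, use_covariates,
                           mask = mask, affine = affine)
  tail_p <- if (two_tailed) voxel_p / 2 else voxel_p
  t_thr <- stats::qt(tail_p, obs$df, lower.tail = FALSE)

  cluster_sizes <- function(tvec) {
    tm <- vector_to_map(tvec, mask, fill = 0)
    pos <- label_components(tm >= t_thr & mask, connectivity)
    sizes <- if (max(pos) > 0) tabulate(pos[pos > 0]) else integer(0)
    if (two_tailed) {
      neg <- label_components(tm <= -t_thr & mask, connectivity)
      if (max(neg) > 0) sizes <- c(sizes, tabulate(neg[neg > 0]))
    }
    sizes
  }

  set.seed(seed)
  null_max <- numeric(n_perm)
  perm_cov <- covariates
  des <- .group_design(covariates, use_covariates)
  for (p in seq_len(n_perm)) {
    perm_cov$group <- covariates$group[sample.int(n)]
    Xp <- .group_design(perm_cov, use_covariates)$X
    tp <- .glm_tstats(Xp, maps, col = 2L)$t
    s <- cluster_sizes(tp)
    null_max[p] <- if (length(s)) max(s) else 0
  }

  tm <- vector_to_map(obs$t, mask, fill = 0)
  tabs <- list(extract_cluster_table(tm, tm >= t_thr & mask, affine, atlas,
                                     connectivity))
  if (two_tailed)
    tabs <- c(tabs, list(extract_cluster_table(tm, tm <= -t_thr & mask,
                                               affine, atlas, connectivity)))
  lab_maps <- lapply(tabs, attr, "label_map")
  signs <- c("+", "-")
  final_lab <- array(0L, dim(mask))
  new_id <- 0L
  kept <- list()
  for (ti in seq_along(tabs)) {
    tab <- tabs[[ti]]
    for (r in seq_len(nrow(tab))) {
      pval <- (1 + sum(null_max >= tab$n_voxels[r])) / (n_perm + 1)
      if (pval >= cluster_p) next
      new_id <- new_id + 1L
      final_lab[lab_maps[[ti]] == tab$cluster_id[r]] <- new_id
      row <- tab[r, ]
      row$cluster_id <- new_id
      row$sign <- signs[ti]
      row$p_corrected <- pval
      kept[[new_id]] <- row
    }
  }
  res <- if (new_id == 0) {
    cbind(tabs[[1]][0, ], p_corrected = numeric(0))
  } else do.call(rbind, kept)
  res$method <- rep("permutation", nrow(res))
  rownames(res) <- NULL
  attr(res, "label_map") <- final_lab
  attr(res, "details") <- list(t_threshold = t_thr, null_max = null_max,
                               n_perm = n_perm, voxel_p = voxel_p,
                               cluster_p = cluster_p)
  class(res) <- c("cluster_table", unique(class(res)))
  res
}

#' Dice overlap of two binary masks
#' @param a,b logical arrays of equal shape.
#' @return `2|A∩B| / (|A|+|B|)`; `NA` when both are empty.
#' @export
dice <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}
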