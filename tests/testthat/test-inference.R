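test_that("GLM group t equals the textbook pooled two-sample t", {
  set.seed(21)
  n1 <- 6; n2 <- 6; V <- 40
  maps <- matrix(rnorm((n1 + n2) * V), n1 + n2, V)
  cov <- fake_covariates(n1, n2, seed = 21)
  fit <- fit_voxelwise_glm(maps, cov, use_covariates = character(0))
  expect_equal(fit$df, n1 + n2 - 2)
  # oracle: direct pooled-variance two-sample t, patient - control
  g1 <- maps[cov$group == "patient", , drop = FALSE]
  g2 <- maps[cov$group == "control", , drop = FALSE]
  sp <- sqrt(((n1 - 1) * apply(g1, 2, var) + (n2 - 1) * apply(g2, 2, var)) /
               (n1 + n2 - 2))
  t_oracle <- (colMeans(g1) - colMeans(g2)) / (sp * sqrt(1 / n1 + 1 / n2))
  expect_equal(fit$t, t_oracle, tolerance = 1e-10)
})

test_that("GLM nulls are calibrated and degenerate designs are rejected", {
  set.seed(22)
  n <- 30; V <- 4000
  maps <- matrix(rnorm(n * V), n, V)
  cov <- fake_covariates(15, 15, seed = 22)
  fit <- fit_voxelwise_glm(maps, cov)
  p <- 2 * pt(abs(fit$t), fit$df, lower.tail = FALSE)
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / V))
  # group duplicated as covariate -> collinear
  cov2 <- cov; cov2$age <- as.numeric(cov2$group == "patient")
  expect_error(fit_voxelwise_glm(maps, cov2), "rank deficient|constant")
  # t invariant to affine rescaling of covariates (years vs decades)
  cov3 <- cov; cov3$age <- cov3$age / 10
  fit3 <- fit_voxelwise_glm(maps, cov3)
  expect_equal(fit$t, fit3$t, tolerance = 1e-8)
})

test_that("one_sample_tmap matches the direct formula and guards df0", {
  z <- matrix(0, 5, 3)
  r0 <- one_sample_tmap(z)
  expect_true(all(r0$t == 0) && all(r0$flagged))
  cmat <- matrix(2, 5, 3)
  rc <- one_sample_tmap(cmat)
  expect_true(all(rc$flagged) && all(rc$t == 1e6))
  set.seed(23)
  m <- matrix(rnorm(20 * 50), 20, 50)
  rt <- one_sample_tmap(m)
  oracle <- apply(m, 2, function(x) mean(x) / (sd(x) / sqrt(20)))
  expect_equal(rt$t, oracle, tolerance = 1e-10)
  expect_equal(rt$df, 19)
  expect_error(one_sample_tmap(m[1, , drop = FALSE]), "2 subjects")
})

test_that("smoothness estimation recovers a known kernel", {
  dims <- c(40, 40, 40)
  mask <- array(TRUE, dims)
  maps <- smooth_null_maps(12, dims, fwhm_mm = 8, voxel = 2, seed = 24)
  fw <- estimate_smoothness(maps, mask, c(2, 2, 2))
  expect_true(all(abs(fw - 8) / 8 < 0.15))
  # unsmoothed white noise: voxel-scale lower bound on a 2 mm grid
  set.seed(25)
  wn <- lapply(1:6, function(i) array(rnorm(prod(dims)), dims))
  fw0 <- estimate_smoothness(wn, mask, c(2, 2, 2))
  expect_true(all(fw0 < 4))
  # units equivariance
  fw2 <- estimate_smoothness(maps, mask, c(4, 4, 4))
  expect_equal(fw2, 2 * fw, tolerance = 1e-12)
  flat <- lapply(1:3, function(i) array(1, dims))
  expect_error(estimate_smoothness(flat, mask, c(2, 2, 2)), "flat")
})

test_that("connected components respect connectivity and conserve counts", {
  m <- array(FALSE, c(4, 4, 3))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE   # touch only diagonally
  expect_equal(max(label_components(m, 26)), 1)
  expect_equal(max(label_components(m, 6)), 2)
  set.seed(26)
  big <- array(runif(20 * 20 * 10) > 0.7, c(20, 20, 10))
  lab <- label_components(big, 26)
  expect_equal(sum(lab > 0), sum(big))
  expect_equal(sum(tabulate(lab[lab > 0])), sum(big))
})

test_that("extract_cluster_table reproduces the reference row schema", {
  # a 59-voxel component with a known peak t and world coordinate, shaped
  # like a left-putamen cluster-table row (values injected as a fixture)
  dims <- c(20, 20, 12)
  voxel <- 3
  aff <- diag(c(voxel, voxel, voxel, 1))
  aff[1:3, 4] <- c(-33, -21, -15)  # chosen so voxel (6, 11, 6) is (-18, 9, 0)
  stat <- array(0, dims)
  supra <- array(FALSE, dims)
  set.seed(27)
  block <- as.matrix(expand.grid(i = 4:8, j = 9:13, k = 5:7))  # 75 voxels
  block <- block[1:59, ]
  for (r in seq_len(59)) {
    stat[block[r, 1], block[r, 2], block[r, 3]] <- runif(1, 2, 4)
    supra[block[r, 1], block[r, 2], block[r, 3]] <- TRUE
  }
  stat[6, 11, 6] <- 4.1322
  ct <- extract_cluster_table(stat, supra, aff)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$n_voxels, 59)
  expect_equal(ct$peak_stat, 4.1322)
  expect_equal(c(ct$peak_x, ct$peak_y, ct$peak_z), c(-18, 9, 0))
  expect_equal(ct$sign, "+")
  # two disjoint components conserve the suprathreshold count
  supra2 <- supra
  supra2[15:17, 2:4, 9:11] <- TRUE
  stat[15:17, 2:4, 9:11] <- -3
  ct2 <- extract_cluster_table(stat, supra2, aff)
  expect_equal(nrow(ct2), 2)
  expect_equal(sum(ct2$n_voxels), sum(supra2))
  expect_true("-" %in% ct2$sign)
  neg <- ct2[ct2$sign == "-", ]
  expect_equal(neg$peak_stat, -3)
})

test_that("grf_cluster_correct handles null maps and planted effects", {
  dims <- c(14, 14, 10)
  mask <- array(TRUE, dims)
  aff <- diag(c(3, 3, 3, 1))
  null_res <- list(t = numeric(sum(mask)), df = 20,
                   residuals = do.call(rbind, smooth_null_maps(
                     6, dims, 6, 3, seed = 28) |> lapply(as.vector)))
  ct <- grf_cluster_correct(null_res, mask, aff)
  expect_equal(nrow(ct), 0)
  # planted effect in smooth maps: the block survives, dice >= 0.5
  set.seed(29)
  block <- array(FALSE, dims); block[5:9, 5:9, 4:7] <- TRUE
  maps <- smooth_null_maps(30, dims, 6, 3, seed = 29)
  for (i in 1:15) maps[[i]] <- maps[[i]] + 2 * block
  cov <- fake_covariates(15, 15, seed = 29)
  fit <- fit_voxelwise_glm(maps_to_matrix(maps, mask), cov,
                           mask = mask, affine = aff)
  ct2 <- grf_cluster_correct(fit, mask, aff)
  expect_gt(nrow(ct2), 0)
  lab <- attr(ct2, "label_map")
  pos <- array(FALSE, dims)
  for (i in ct2$cluster_id[ct2$sign == "+"]) pos[lab == i] <- TRUE
  expect_gte(dice(pos, block), 0.5)
  # permutation oracle agrees on the surviving region
  pt <- permutation_cluster_correct(maps_to_matrix(maps, mask), cov,
                                    mask = mask, affine = aff,
                                    n_perm = 199, seed = 30)
  expect_gte(dice(attr(pt, "label_map") > 0, lab > 0), 0.7)
  # degenerate and invalid permutation requests
  expect_error(permutation_cluster_correct(maps_to_matrix(maps, mask), cov,
                                           mask = mask, affine = aff,
                                           n_perm = 10), ">= 100")
})
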