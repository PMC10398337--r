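test_that("config invariants are enforced", {
  expect_error(synthetic_config(envelope_freq = 0.02), "envelope_freq")
  expect_error(synthetic_config(ar1_coef = 1), "ar1")
  P_bad <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2, byrow = TRUE)
  expect_error(synthetic_config(state_transition_matrix = P_bad), "sum to 1")
  expect_error(synthetic_config(carrier_band = c(0.01, 0.3), tr = 2), "Nyquist")
  expect_error(synthetic_config(effect_regions = list(
    list(corner = c(1, 1, 1), size = c(99, 2, 2),
         m_patient = 1, m_control = 0))), "grid")
})

test_that("same seed gives bit-identical subjects; different seeds differ", {
  cfg <- synthetic_config(grid_shape = c(8, 8, 6),
                          n_per_group = c(patient = 2, control = 2),
                          n_volumes = 60, seed = 9)
  b1 <- generate_subject(cfg, 1)
  b2 <- generate_subject(cfg, 1)
  expect_identical(b1$data, b2$data)
  cfg2 <- synthetic_config(grid_shape = c(8, 8, 6),
                           n_per_group = c(patient = 2, control = 2),
                           n_volumes = 60, seed = 10)
  expect_false(identical(generate_subject(cfg2, 1)$data, b1$data))
  # cohort-level determinism, covariates included
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(c1$subjects[[3]]$bold$data, c2$subjects[[3]]$bold$data)
})

test_that("no modulation and no noise means zero dALFF CV", {
  cfg <- synthetic_config(grid_shape = c(6, 6, 4), mask_type = "box",
                          n_per_group = c(patient = 1, control = 1),
                          n_volumes = 90, noise_sd = 0,
                          background_modulation = 0, drift_amplitude = 0,
                          effect_regions = list(list(
                            corner = c(2, 2, 2), size = c(2, 2, 2),
                            m_patient = 0, m_control = 0)),
                          seed = 2)
  b <- generate_subject(cfg, 1)
  # 25-TR (50 s) windows hold an integer number of cycles of every default
  # carrier tone (multiples of 0.02 Hz), so windowed ALFF is leakage-free
  # and exactly constant; drift is off because any detrending route leaves
  # window-position-dependent leakage (see the methods vignette)
  st <- compute_windowed_alff(preprocess_bold(b, n_discard = 0,
                                              detrend_order = NA,
                                              fwhm_mm = 0),
                              window = 25, detrend_window = FALSE)
  dm <- compute_dalff_cv(st)
  expect_lt(max(abs(dm$cv)), 1e-8)
})

test_that("windowed-ALFF CV rises with modulation depth (oracle check)", {
  ms <- c(0, 0.4, 0.8)
  mean_cv <- vapply(ms, function(m) {
    cfg <- synthetic_config(grid_shape = c(6, 6, 4), mask_type = "box",
                            n_per_group = c(patient = 1, control = 1),
                            n_volumes = 180, noise_sd = 0.2,
                            background_modulation = m,
                            effect_regions = list(list(
                              corner = c(2, 2, 2), size = c(3, 3, 2),
                              m_patient = m, m_control = m)),
                            smooth_fwhm = 0, seed = 31)
    b <- generate_subject(cfg, 1)
    pp <- preprocess_bold(b, n_discard = 0, fwhm_mm = 0)
    # independent oracle path: per-voxel windowed fft + direct CV
    vox <- which(b$mask)[1:20]
    flat <- matrix(pp$data, prod(dim(pp$data)[1:3]), dim(pp$data)[4])
    mean(vapply(vox, function(v) {
      oracle_cv(oracle_windowed_alff(flat[v, ], 2, 30, 1, c(0.01, 0.08)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cv) > 0))
  # patients vs controls differ in the planted block in the right direction
  cfg <- synthetic_config(grid_shape = c(8, 8, 6), mask_type = "box",
                          n_per_group = c(patient = 4, control = 4),
                          n_volumes = 180, noise_sd = 0.2, seed = 5)
  coh <- generate_cohort(cfg)
  em <- coh$ground_truth$effect_mask
  block_cv <- vapply(coh$subjects, function(s) {
    st <- compute_windowed_alff(preprocess_bold(s$bold, n_discard = 0,
                                                fwhm_mm = 0), window = 30)
    mean(compute_dalff_cv(st)$cv[em])
  }, numeric(1))
  grp <- coh$covariates$group
  expect_gt(mean(block_cv[grp == "patient"]), mean(block_cv[grp == "control"]))
})

test_that("state cohorts follow the Markov ground truth", {
  # absorbing chain: identity matrix, fixed initial state
  cfg <- synthetic_config(grid_shape = c(6, 6, 4),
                          n_per_group = c(patient = 1, control = 1),
                          n_volumes = 120, state_epoch = 20,
                          state_transition_matrix = diag(2), seed = 3)
  cfg$state_prototypes <- make_state_prototypes(cfg, 2)
  coh <- generate_state_cohort(cfg, init_state = 1)
  expect_true(all(unlist(coh$ground_truth$state_sequences) == 1))
  # switching fraction matches the off-diagonal probability
  P <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  set.seed(8)
  s <- simulate_markov_chain(P, 2000)
  frac <- mean(s[-1] != s[-length(s)])
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  # uniform chain: long-run occupancy about 1/3 each
  P3 <- matrix(1 / 3, 3, 3)
  s3 <- simulate_markov_chain(P3, 3000)
  expect_true(all(abs(tabulate(s3, 3) / 3000 - 1 / 3) < 0.05))
  # degenerate k rejected
  cfg_bad <- synthetic_config(grid_shape = c(6, 6, 4),
                              n_per_group = c(patient = 1, control = 1),
                              n_volumes = 120,
                              state_transition_matrix = matrix(1, 1, 1),
                              seed = 3)
  cfg_bad$state_prototypes <- list(array(1, c(6, 6, 4)))
  expect_error(generate_state_cohort(cfg_bad), "degenerate")
})

test_that("generate_atlas labels blocks and rejects overlap", {
  cfg <- synthetic_config(grid_shape = c(10, 10, 6),
                          n_per_group = c(patient = 1, control = 1))
  regions <- list(list(corner = c(1, 1, 1), size = c(5, 5, 3)),
                  list(corner = c(6, 6, 4), size = c(5, 5, 3)))
  atlas <- generate_atlas(cfg, regions)
  expect_equal(sort(unique(as.vector(atlas))), c(0, 1, 2))
  expect_equal(sum(atlas > 0), 2 * 5 * 5 * 3)
  expect_equal(sum(atlas == 1), 75)
  expect_true(all(generate_atlas(cfg, list()) == 0))
  overlap <- list(list(corner = c(1, 1, 1), size = c(5, 5, 3)),
                  list(corner = c(3, 3, 2), size = c(5, 5, 3)))
  expect_error(generate_atlas(cfg, overlap), "overlap")
})

test_that("write_cohort emits NIfTI + CSV that read back consistently", {
  cfg <- synthetic_config(grid_shape = c(6, 6, 4),
                          n_per_group = c(patient = 2, control = 2),
                          n_volumes = 40, seed = 6)
  coh <- generate_cohort(cfg)
  dir <- tempfile("cohort_")
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  img <- read_nifti(file.path(dir, "sub-001_bold.nii.gz"))
  expect_equal(img$data, coh$subjects[[1]]$bold$data, tolerance = 1e-6)
  expect_equal(img$tr, 2)
  cov <- read_covariates(file.path(dir, "covariates.csv"))
  expect_identical(cov$subject_id, coh$covariates$subject_id)
  unlink(dir, recursive = TRUE)
})
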