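#' Configuration for the synthetic BOLD cohort generator
#'
#' The generator emulates an 8-minute resting-state acquisition (240 volumes
#' at TR = 2 s on a 64x64x30 grid, scaled down spatially for desk-scale
#' testing): band-limited carrier oscillations inside 0.01-0.08 Hz whose
#' slow amplitude envelope differs in modulation depth between groups inside
#' planted regions, AR(1) Gaussian noise with spatial smoothness, and
#' low-order polynomial drift. Modulation depth `m` controls window-to-window
#' ALFF variability and therefore the dALFF CV.
#'
#' @param grid_shape 3 positive integers, voxels per axis (default 24,24,16).
#' @param voxel_size mm per axis (default 3).
#' @param n_volumes acquired volumes (default 240).
#' @param tr repetition time, seconds (default 2).
#' @param n_per_group named counts `c(patient=, control=)` (default 23/24,
#'   the reference cohort shape).
#' @param effect_regions list of planted blocks; each a list with `corner`
#'   (1-based voxel), `size` (3 ints), `m_patient`, `m_control` (>= 0).
#' @param background_modulation envelope modulation depth outside planted
#'   regions, both groups (default 0.2).
#' @param carrier_freqs carrier tone frequencies in Hz, all inside
#'   `carrier_band` (default 0.02, 0.04, 0.06).
#' @param carrier_band analysis band c(f_lo, f_hi) in Hz (default 0.01-0.08).
#' @param envelope_freq slow amplitude-envelope frequency in Hz, strictly
#'   below `f_lo` (default 0.005).
#' @param ar1_coef temporal noise AR(1) coefficient in `[0, 1)` (default 0.3).
#' @param noise_sd innovation SD of the noise, signal units (default 0.5).
#' @param drift_order polynomial drift order (default 1).
#' @param drift_amplitude peak drift excursion, signal units (default 1).
#' @param baseline mean image intensity inside the brain (default 100).
#' @param smooth_fwhm mm FWHM of the Gaussian blur applied to the noise
#'   field only (signal blocks stay geometrically exact; default 6).
#' @param mask_type `"ellipsoid"` (inscribed brain-like mask) or `"box"`.
#' @param state_prototypes optional list of k 3D amplitude maps for
#'   Markov-switching cohorts.
#' @param state_transition_matrix optional k x k row-stochastic matrix.
#' @param state_epoch epoch length in TR for state switching (default 30).
#' @param seed RNG seed (default 1).
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(24L, 24L, 16L),
                             voxel_size = c(3, 3, 3),
                             n_volumes = 240L, tr = 2,
                             n_per_group = c(patient = 23L, control = 24L),
                             effect_regions = NULL,
                             background_modulation = 0.2,
                             carrier_freqs = c(0.02, 0.04, 0.06),
                             carrier_band = c(0.01, 0.08),
                             envelope_freq = 0.005,
                             ar1_coef = 0.3, noise_sd = 0.5,
                             drift_order = 1L, drift_amplitude = 1,
                             baseline = 100,
                             smooth_fwhm = 6,
                             mask_type = c("ellipsoid", "box"),
                             state_prototypes = NULL,
                             state_transition_matrix = NULL,
                             state_epoch = 30L,
                             seed = 1L) {
  mask_type <- match.arg(mask_type)
  if (is.null(effect_regions)) {
    # one centered block, a quarter of the grid per axis, 0.8 vs 0.1 depth
    size <- pmax(2L, floor(grid_shape / 4))
    corner <- pmax(1L, floor((grid_shape - size) / 2) + 1L)
    effect_regions <- list(list(corner = as.integer(corner),
                                size = as.integer(size),
                                m_patient = 0.8, m_control = 0.1))
  }
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            length(voxel_size) == 3, all(voxel_size > 0),
            n_volumes >= 16, tr > 0,
            length(n_per_group) == 2, all(n_per_group >= 1))
  nyq <- 1 / (2 * tr)
  if (!(0 < carrier_band[1] && carrier_band[1] < carrier_band[2] &&
        carrier_band[2] < nyq))
    stop("need 0 < f_lo < f_hi < Nyquist = ", nyq, " Hz")
  if (any(carrier_freqs <= carrier_band[1] - 1e-12) ||
      any(carrier_freqs >= carrier_band[2] + 1e-12))
    stop("carrier_freqs must lie inside carrier_band")
  if (envelope_freq >= carrier_band[1])
    stop("envelope_freq (", envelope_freq, " Hz) must be below f_lo (",
         carrier_band[1], " Hz): a faster envelope would leak modulation into the analysis band")
  if (!(ar1_coef >= 0 && ar1_coef < 1)) stop("ar1_coef must be in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (background_modulation < 0) stop("modulation depths must be >= 0")
  for (r in effect_regions) {
    if (r$m_patient < 0 || r$m_control < 0)
      stop("modulation depths must be >= 0")
    if (any(r$corner < 1) || any(r$corner + r$size - 1 > grid_shape))
      stop("effect region exceeds the grid")
  }
  if (!is.null(state_transition_matrix)) {
    P <- state_transition_matrix
    if (nrow(P) != ncol(P)) stop("transition matrix must be square")
    if (any(abs(rowSums(P) - 1) > 1e-12))
      stop("transition matrix rows must each sum to 1 (tolerance 1e-12)")
    if (any(P < 0)) stop("transition probabilities must be >= 0")
  }
  if (is.null(names(n_per_group))) names(n_per_group) <- c("patient", "control")
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 n_volumes = as.integer(n_volumes), tr = tr,
                 n_per_group = n_per_group, effect_regions = effect_regions,
                 background_modulation = background_modulation,
                 carrier_freqs = carrier_freqs, carrier_band = carrier_band,
                 envelope_freq = envelope_freq, ar1_coef = ar1_coef,
                 noise_sd = noise_sd, drift_order = as.integer(drift_order),
                 drift_amplitude = drift_amplitude, baseline = baseline,
                 smooth_fwhm = smooth_fwhm, mask_type = mask_type,
                 state_prototypes = state_prototypes,
                 state_transition_matrix = state_transition_matrix,
                 state_epoch = as.integer(state_epoch),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Brain mask for a config: inscribed ellipsoid or full box.
synthetic_mask <- function(config) {
  d <- config$grid_shape
  if (config$mask_type == "box") return(array(TRUE, d))
  ctr <- (d + 1) / 2
  rad <- d / 2 - 0.5
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  inside <- ((g$i - ctr[1]) / rad[1])^2 + ((g$j - ctr[2]) / rad[2])^2 +
    ((g$k - ctr[3]) / rad[3])^2 <= 1
  array(inside, d)
}

# Per-group modulation-depth maps and the planted-effect mask.
.modulation_maps <- function(config, mask) {
  d <- config$grid_shape
  mp <- array(config$background_modulation, d)
  mc <- array(config$background_modulation, d)
  for (r in config$effect_regions) {
    ii <- r$corner[1]:(r$corner[1] + r$size[1] - 1)
    jj <- r$corner[2]:(r$corner[2] + r$size[2] - 1)
    kk <- r$corner[3]:(r$corner[3] + r$size[3] - 1)
    mp[ii, jj, kk] <- r$m_patient
    mc[ii, jj, kk] <- r$m_control
  }
  mp[!mask] <- 0
  mc[!mask] <- 0
  list(patient = mp, control = mc,
       effect_mask = (abs(mp - mc) > 1e-12) & mask)
}

.affine_from_config <- function(config) {
  A <- diag(c(config$voxel_size, 1))
  # center the grid on the world origin, MNI-style
  A[1:3, 4] <- -config$voxel_size * (config$grid_shape - 1) / 2
  A
}

.subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 131071 + i * 7919) %% 2147483629)
}

# AR(1) spatially smoothed noise for all in-mask voxels: V x T matrix.
.gen_noise <- function(config, mask, t_len) {
  vidx <- which(mask)
  if (config$noise_sd == 0) return(matrix(0, length(vidx), t_len))
  d <- config$grid_shape
  sig_vox <- fwhm_to_sigma(config$smooth_fwhm) / config$voxel_size
  E <- matrix(0, length(vidx), t_len)
  for (t in seq_len(t_len)) {
    vol <- array(stats::rnorm(prod(d), sd = config$noise_sd), d)
    if (config$smooth_fwhm > 0) vol <- .smooth3d(vol, sig_vox)
    E[, t] <- vol[vidx]
  }
  if (config$ar1_coef > 0) {
    for (t in 2:t_len) E[, t] <- E[, t] + config$ar1_coef * E[, t - 1]
  }
  E
}

# One subject's 4D series given its modulation-depth map (V vector) or an
# amplitude series (V x T) for state cohorts.
.gen_subject_data <- function(config, mask, amplitude_vt) {
  d <- config$grid_shape
  t_len <- config$n_volumes
  tt <- (seq_len(t_len) - 1) * config$tr
  carrier <- rowSums(vapply(config$carrier_freqs, function(f) {
    sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
  }, numeric(t_len)))
  vidx <- which(mask)
  sig <- amplitude_vt * matrix(carrier, length(vidx), t_len, byrow = TRUE)
  drift <- 0
  if (config$drift_order > 0 && config$drift_amplitude > 0) {
    tn <- seq(-1, 1, length.out = t_len)
    drift_t <- numeric(t_len)
    for (p in seq_len(config$drift_order)) {
      drift_t <- drift_t + stats::rnorm(1, sd = config$drift_amplitude) * tn^p
    }
    drift <- matrix(drift_t, length(vidx), t_len, byrow = TRUE)
  }
  noise <- .gen_noise(config, mask, t_len)
  mat <- config$baseline + sig + drift + noise
  data <- array(0, c(d, t_len))
  flat <- matrix(data, prod(d), t_len)
  flat[vidx, ] <- mat
  array(flat, c(d, t_len))
}

#' Synthetic subject covariates
#'
#' Age uniform on 20-80 years, sex Bernoulli(0.5) coded 0/1, and a small
#' non-negative integer clinical score (Poisson, mean 4, mimicking HAMA).
#' Covariates are independent of the planted imaging effect, so clinical
#' correlations are null by construction.
#'
#' @param config a [synthetic_config].
#' @return data.frame: subject_id, group, age, sex, score.
#' @export
generate_covariates <- function(config) {
  set.seed(.subject_seed(config$seed, 0L))
  n <- sum(config$n_per_group)
  grp <- rep(names(config$n_per_group), config$n_per_group)
  data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = grp,
    age = round(stats::runif(n, 20, 80), 1),
    sex = stats::rbinom(n, 1, 0.5),
    score = stats::rpois(n, 4),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic two-group BOLD cohort with planted dALFF effects
#'
#' Every voxel time series is `baseline + drift + a(t) * carrier(t) + AR(1)
#' noise` where the envelope `a(t) = 1 + m * sin(2*pi*f_env*t + psi)` has a
#' region- and group-specific modulation depth `m`; patients and controls
#' are generated by the identical process except for `m` inside the planted
#' effect regions. Fully reproducible from the config seed; subjects can be
#' generated independently (streaming) via [generate_subject].
#'
#' @param config a [synthetic_config].
#' @param keep_data if FALSE, subject images are not retained in the return
#'   value (use [generate_subject] to stream them); default TRUE.
#' @return list with `subjects` (list of `list(id, group, bold)`),
#'   `covariates` (data.frame), `mask`, and `ground_truth` (list with
#'   `effect_mask`, per-group modulation maps, `config`).
#' @export
generate_cohort <- function(config, keep_data = TRUE) {
  mask <- synthetic_mask(config)
  mm <- .modulation_maps(config, mask)
  cov <- generate_covariates(config)
  subjects <- vector("list", nrow(cov))
  for (i in seq_len(nrow(cov))) {
    subjects[[i]] <- list(id = cov$subject_id[i], group = cov$group[i])
    if (keep_data) {
      subjects[[i]]$bold <- generate_subject(config, i, mask = mask,
                                             modulation = mm)
    }
  }
  list(subjects = subjects, covariates = cov, mask = mask,
       ground_truth = list(effect_mask = mm$effect_mask,
                           modulation = mm[c("patient", "control")],
                           config = config))
}

#' Generate one subject of a synthetic cohort
#'
#' Deterministic given `(config$seed, i)`; used by [generate_cohort] and by
#' streaming pipelines that do not want the whole cohort in memory.
#'
#' @param config a [synthetic_config].
#' @param i subject index (1-based, patients first).
#' @param mask,modulation optional precomputed [synthetic_mask] and
#'   modulation maps (recomputed when NULL).
#' @return a [bold_image].
#' @export
generate_subject <- function(config, i, mask = NULL, modulation = NULL) {
  if (is.null(mask)) mask <- synthetic_mask(config)
  if (is.null(modulation)) modulation <- .modulation_maps(config, mask)
  grp <- rep(names(config$n_per_group), config$n_per_group)[i]
  m_map <- modulation[[grp]]
  set.seed(.subject_seed(config$seed, i))
  t_len <- config$n_volumes
  tt <- (seq_len(t_len) - 1) * config$tr
  g <- sin(2 * pi * config$envelope_freq * tt + stats::runif(1, 0, 2 * pi))
  vidx <- which(mask)
  amp <- 1 + outer(m_map[vidx], g)   # V x T envelope
  data <- .gen_subject_data(config, mask, amp)
  bold_image(data, affine = .affine_from_config(config), tr = config$tr,
             mask = mask)
}

#' Simulate a first-order Markov state sequence
#'
#' @param P k x k row-stochastic transition matrix.
#' @param n sequence length.
#' @param init initial state (default: uniform draw).
#' @return integer vector in 1..k.
#' @export
simulate_markov_chain <- function(P, n, init = NULL) {
  k <- nrow(P)
  s <- integer(n)
  s[1] <- if (is.null(init)) sample.int(k, 1) else init
  for (t in seq_len(n - 1)) {
    s[t + 1] <- sample.int(k, 1, prob = P[s[t], ])
  }
  s
}

#' Default spatial amplitude prototypes for state cohorts
#'
#' Prototype `j` has carrier amplitude `high` inside its own block and
#' `base` elsewhere; blocks are disjoint slabs along the first axis.
#'
#' @param config a [synthetic_config].
#' @param k number of states (>= 2).
#' @param base,high amplitudes (default 1 and 2.5).
#' @return list of k 3D arrays.
#' @export
make_state_prototypes <- function(config, k, base = 1, high = 2.5) {
  d <- config$grid_shape
  slab <- floor(d[1] / k)
  lapply(seq_len(k), function(j) {
    a <- array(base, d)
    i0 <- (j - 1) * slab + 1
    a[i0:min(j * slab, d[1]), , ] <- high
    a
  })
}

#' Generate a Markov-switching state cohort
#'
#' The spatial carrier-amplitude pattern is piecewise constant over epochs
#' of `state_epoch` TRs and follows a first-order Markov chain over the k
#' prototypes; the true epoch-level state labels are returned per subject.
#'
#' @param config a [synthetic_config] with `state_prototypes` and
#'   `state_transition_matrix` set.
#' @param init_state optional fixed initial state for every subject.
#' @return list as [generate_cohort] plus `ground_truth$state_sequences`
#'   (list per subject, epoch-level labels in 1..k) and
#'   `ground_truth$epoch_length`.
#' @export
generate_state_cohort <- function(config, init_state = NULL) {
  protos <- config$state_prototypes
  P <- config$state_transition_matrix
  if (is.null(protos) || is.null(P))
    stop("config must set state_prototypes and state_transition_matrix")
  k <- length(protos)
  if (k < 2)
    stop("k = 1 is degenerate: state analysis needs at least 2 prototypes")
  if (nrow(P) != k) stop("transition matrix size must match prototype count")
  mask <- synthetic_mask(config)
  cov <- generate_covariates(config)
  vidx <- which(mask)
  proto_v <- vapply(protos, function(p) p[vidx], numeric(length(vidx)))
  t_len <- config$n_volumes
  n_epochs <- floor(t_len / config$state_epoch)
  if (n_epochs < 2) stop("n_volumes too short for state epochs")
  epoch_of_t <- pmin(rep(seq_len(n_epochs), each = config$state_epoch,
                         length.out = t_len), n_epochs)
  subjects <- vector("list", nrow(cov))
  seqs <- vector("list", nrow(cov))
  for (i in seq_len(nrow(cov))) {
    set.seed(.subject_seed(config$seed, i))
    s <- simulate_markov_chain(P, n_epochs, init = init_state)
    amp <- proto_v[, s[epoch_of_t], drop = FALSE]  # V x T
    data <- .gen_subject_data(config, mask, amp)
    subjects[[i]] <- list(id = cov$subject_id[i], group = cov$group[i],
                          bold = bold_image(data,
                                            affine = .affine_from_config(config),
                                            tr = config$tr, mask = mask))
    seqs[[i]] <- s
  }
  list(subjects = subjects, covariates = cov, mask = mask,
       ground_truth = list(state_sequences = seqs,
                           epoch_length = config$state_epoch,
                           prototypes = protos, transition_matrix = P,
                           config = config))
}

#' Generate a labeled block atlas
#'
#' Integer-labeled, non-overlapping rectangular regions on the config grid;
#' label 0 is background. Stands in for an anatomical atlas when naming
#' clusters.
#'
#' @param config a [synthetic_config].
#' @param regions list of `list(corner, size)` blocks (default: the config's
#'   effect regions).
#' @return 3D integer array.
#' @export
generate_atlas <- function(config, regions = config$effect_regions) {
  d <- config$grid_shape
  atlas <- array(0L, d)
  for (lab in seq_along(regions)) {
    r <- regions[[lab]]
    if (any(r$corner < 1) || any(r$corner + r$size - 1 > d))
      stop("region ", lab, " exceeds the grid")
    ii <- r$corner[1]:(r$corner[1] + r$size[1] - 1)
    jj <- r$corner[2]:(r$corner[2] + r$size[2] - 1)
    kk <- r$corner[3]:(r$corner[3] + r$size[3] - 1)
    if (any(atlas[ii, jj, kk] != 0L))
      stop("region ", lab, " overlaps an earlier region")
    atlas[ii, jj, kk] <- lab
  }
  atlas
}

#' Write a synthetic cohort to disk
#'
#' Per-subject 4D NIfTI images (TR in the header), the covariates CSV, the
#' brain mask and planted-effect mask as NIfTI, and state sequences (if any)
#' as CSV.
#'
#' @param cohort result of [generate_cohort] or [generate_state_cohort].
#' @param dir output directory (created).
#' @return character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  aff <- cohort$subjects[[1]]$bold$affine
  for (s in cohort$subjects) {
    p <- file.path(dir, paste0(s$id, "_bold.nii.gz"))
    write_nifti(as_nifti(s$bold), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "covariates.csv")
  write_covariates(cohort$covariates, p)
  paths <- c(paths, p)
  p <- file.path(dir, "brain_mask.nii.gz")
  write_nifti(nifti_image(array(as.numeric(cohort$mask), dim(cohort$mask)),
                          affine = aff), p)
  paths <- c(paths, p)
  if (!is.null(cohort$ground_truth$effect_mask)) {
    p <- file.path(dir, "effect_mask.nii.gz")
    em <- cohort$ground_truth$effect_mask
    write_nifti(nifti_image(array(as.numeric(em), dim(em)), affine = aff), p)
    paths <- c(paths, p)
  }
  if (!is.null(cohort$ground_truth$state_sequences)) {
    seqs <- cohort$ground_truth$state_sequences
    df <- data.frame(subject_id = rep(cohort$covariates$subject_id,
                                      vapply(seqs, length, 1L)),
                     epoch = unlist(lapply(seqs, seq_along)),
                     state = unlist(seqs))
    p <- file.path(dir, "state_sequences.csv")
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
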