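#' Pipeline run configuration
#'
#' Assembles and validates the configuration for a full study run:
#' generation/ingestion, preprocessing, sliding-window dALFF at each window
#' length, group inference, state dynamics, classification and clinical
#' correlation.
#'
#' @param mode `"synthetic"` (generate a cohort) or `"nifti"` (read 4D
#'   images and a covariate CSV from `input_dir`).
#' @param input_dir directory of `*_bold.nii(.gz)` files plus
#'   `covariates.csv` and `brain_mask.nii(.gz)` (`"nifti"` mode).
#' @param output_dir artifact directory.
#' @param windows sliding-window lengths in TR (default 30, 50, 80).
#' @param step window step in TR (default 1).
#' @param band analysis band in Hz (default 0.01-0.08).
#' @param n_discard leading volumes dropped (default 10).
#' @param detrend_order detrending polynomial order (default 1).
#' @param fwhm preprocessing smoothing FWHM in mm (default 6).
#' @param standardize z-standardize CV maps within the mask before group
#'   statistics (default TRUE).
#' @param voxel_p,cluster_p inference thresholds (defaults 0.05, 0.05).
#' @param correction `"grf"` (default), `"permutation"` or `"both"`.
#' @param n_perm permutations for the permutation route (default 199).
#' @param connectivity cluster connectivity (default 26).
#' @param k states per window length: `"auto"` (elbow from [select_k]) or a
#'   single integer applied to every window length.
#' @param k_range candidate k for `"auto"` (default 2:5).
#' @param svm_scheme outer evaluation scheme (default `"loo"`).
#' @param svm_grid_by exponent step of the hyperparameter grid (default 4).
#' @param write_subject_maps write per-subject CV maps as NIfTI (default
#'   TRUE).
#' @param seed master seed; all stage seeds derive from it.
#' @param synthetic list of [synthetic_config] overrides (synthetic mode).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "nifti"), input_dir = NULL,
                       output_dir = tempfile("dalff_run_"),
                       windows = c(30L, 50L, 80L), step = 1L,
                       band = c(0.01, 0.08), n_discard = 10L,
                       detrend_order = 1L, fwhm = 6, standardize = TRUE,
                       voxel_p = 0.05, cluster_p = 0.05,
                       correction = c("grf", "permutation", "both"),
                       n_perm = 199L, connectivity = 26L,
                       k = "auto", k_range = 2:5,
                       svm_scheme = "loo", svm_grid_by = 4,
                       write_subject_maps = TRUE,
                       seed = 1L, synthetic = list()) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  stopifnot(all(windows >= 8), step >= 1,
            voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1)
  if (mode == "nifti" && is.null(input_dir))
    stop("nifti mode requires input_dir")
  cfg <- list(mode = mode, input_dir = input_dir, output_dir = output_dir,
              windows = as.integer(windows), step = as.integer(step),
              band = band, n_discard = as.integer(n_discard),
              detrend_order = as.integer(detrend_order), fwhm = fwhm,
              standardize = standardize, voxel_p = voxel_p,
              cluster_p = cluster_p, correction = correction,
              n_perm = as.integer(n_perm),
              connectivity = as.integer(connectivity),
              k = k, k_range = as.integer(k_range),
              svm_scheme = svm_scheme, svm_grid_by = svm_grid_by,
              write_subject_maps = write_subject_maps,
              seed = as.integer(seed), synthetic = synthetic)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file of [run_config] fields, validates field names and
#' types through `run_config()` and rejects unknown keys.
#'
#' @param path YAML file.
#' @param overrides named list overriding file values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

.log_stage <- function(stage, t0, ...) {
  message(sprintf("[dalff] stage=%s elapsed=%.2fs %s", stage,
                  as.numeric(Sys.time()) - t0,
                  paste(..., collapse = " ")))
}

#' Validate pipeline inputs
#'
#' Checks grid and TR consistency across subjects, mask coverage, covariate
#' completeness and group balance. With `strict = TRUE` (default) hard
#' problems (mixed TR/grid, empty mask, missing covariates) raise an error;
#' otherwise a report is returned and nothing is mutated.
#'
#' @param bold_paths character vector of 4D NIfTI paths (headers only are
#'   inspected).
#' @param covariates covariate data.frame.
#' @param mask 3D mask array (or NULL to skip mask checks).
#' @param strict stop on hard errors (default TRUE).
#' @return list with `errors`, `warnings`, `notes` character vectors.
#' @export
validate_inputs <- function(bold_paths, covariates, mask = NULL,
                            strict = TRUE) {
  errors <- character(0); warnings_ <- character(0); notes <- character(0)
  hdr <- lapply(bold_paths, function(p) {
    img <- read_nifti(p)
    list(dim = dim(img$data), tr = img$tr, path = p)
  })
  if (length(hdr)) {
    trs <- vapply(hdr, function(h) h$tr, numeric(1))
    if (length(unique(round(trs, 6))) > 1)
      errors <- c(errors, paste0("mixed TR across cohort: ",
                                 paste(unique(trs), collapse = ", ")))
    dims <- vapply(hdr, function(h) paste(h$dim[1:3], collapse = "x"), "")
    if (length(unique(dims)) > 1)
      errors <- c(errors, "mixed spatial grids across cohort")
  }
  cov_check <- tryCatch({ validate_covariates(covariates); NULL },
                        error = function(e) conditionMessage(e))
  if (!is.null(cov_check)) errors <- c(errors, cov_check)
  ids_from_files <- sub("_bold\\.nii(\\.gz)?$", "", basename(bold_paths))
  missing_cov <- setdiff(ids_from_files, covariates$subject_id)
  if (length(missing_cov))
    errors <- c(errors, paste0("missing covariates for subject(s): ",
                               paste(missing_cov, collapse = ", ")))
  if (!is.null(mask)) {
    if (sum(mask) == 0) errors <- c(errors, "empty brain mask")
    else if (mean(mask) < 0.01)
      warnings_ <- c(warnings_, "mask covers <1% of the grid")
  }
  tb <- table(covariates$group)
  if (length(tb) == 2 && max(tb) - min(tb) > 0 &&
      max(tb) / min(tb) < 1.5)
    notes <- c(notes, sprintf("group sizes %s vs %s: acceptably balanced",
                              tb[1], tb[2]))
  if (length(tb) == 2 && max(tb) / min(tb) >= 1.5)
    warnings_ <- c(warnings_, "groups are unbalanced (> 1.5:1)")
  rep <- list(errors = errors, warnings = warnings_, notes = notes)
  if (strict && length(errors))
    stop("input validation failed: ", paste(errors, collapse = "; "))
  rep
}

# Load cohort in nifti mode: list(subjects, covariates, mask).
.load_nifti_cohort <- function(input_dir) {
  paths <- sort(list.files(input_dir, "_bold\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (length(paths) == 0) stop("no *_bold.nii[.gz] files in ", input_dir)
  cov_path <- file.path(input_dir, "covariates.csv")
  if (!file.exists(cov_path)) stop("missing covariates.csv in ", input_dir)
  covariates <- read_covariates(cov_path)
  mask_path <- list.files(input_dir, "^brain_mask\\.nii(\\.gz)?$",
                          full.names = TRUE)
  mask <- NULL
  if (length(mask_path)) mask <- read_nifti(mask_path[1])$data > 0.5
  validate_inputs(paths, covariates, mask)
  ids <- sub("_bold\\.nii(\\.gz)?$", "", basename(paths))
  ord <- match(covariates$subject_id, ids)
  if (any(is.na(ord))) stop("bold file missing for subject(s): ",
                            paste(covariates$subject_id[is.na(ord)],
                                  collapse = ", "))
  subjects <- lapply(seq_along(ord), function(i) {
    img <- read_nifti(paths[ord[i]])
    m <- if (is.null(mask)) NULL else mask
    list(id = covariates$subject_id[i], group = covariates$group[i],
         bold = as_bold(img, mask = m))
  })
  list(subjects = subjects, covariates = covariates,
       mask = if (is.null(mask)) subjects[[1]]$bold$mask else mask,
       ground_truth = NULL)
}

#' Run the full dALFF study pipeline
#'
#' Sequencing: generate/ingest, preprocess (discard, detrend, smooth),
#' sliding-window ALFF and CV map per window length, two-group GLM with
#' age/sex covariates plus cluster-level correction, L1 k-means state
#' dynamics with group-compared temporal metrics, RBF-SVM classification on
#' differential-cluster features, and normality-routed clinical correlation
#' in the patient group. All artifacts are written under
#' `config$output_dir`; a JSON manifest records paths, md5 hashes, seeds
#' and the package version.
#'
#' @param config a [run_config].
#' @return the manifest, invisibly (list; also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  artifacts <- character(0)
  add_artifact <- function(p) artifacts <<- c(artifacts, p)

  stage <- function(name, expr) {
    ts <- as.numeric(Sys.time())
    r <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    .log_stage(name, ts)
    r
  }

  cohort <- stage("ingest", {
    if (config$mode == "synthetic") {
      syn <- do.call(synthetic_config,
                     c(config$synthetic, list(seed = config$seed)))
      n_after <- syn$n_volumes - config$n_discard
      if (any(config$windows >= n_after))
        stop("window length must be below n_volumes - discarded (",
             n_after, ")")
      generate_cohort(syn)
    } else {
      .load_nifti_cohort(config$input_dir)
    }
  })
  mask <- cohort$mask
  affine <- cohort$subjects[[1]]$bold$affine
  covariates <- cohort$covariates
  groups <- unique(covariates$group)
  patient_level <- if ("patient" %in% groups) "patient" else groups[1]

  cfg_path <- file.path(out, "config.yaml")
  cfg_export <- unclass(config)
  cfg_export$k_range <- as.integer(cfg_export$k_range)
  yaml::write_yaml(cfg_export, cfg_path)
  add_artifact(cfg_path)

  pp <- stage("preprocess", {
    lapply(cohort$subjects, function(s) {
      tryCatch(
        preprocess_bold(s$bold, n_discard = config$n_discard,
                        detrend_order = config$detrend_order,
                        fwhm_mm = config$fwhm),
        error = function(e) stop("subject ", s$id, ": ",
                                 conditionMessage(e), call. = FALSE))
    })
  })

  manifest_entries <- list()
  for (w in config$windows) {
    wtag <- paste0("w", w)
    wdir <- file.path(out, wtag)
    dir.create(wdir, showWarnings = FALSE)

    stacks <- stage(paste0("dalff_", wtag), {
      lapply(seq_along(pp), function(i) {
        compute_windowed_alff(pp[[i]], window = w, step = config$step,
                              band = config$band)
      })
    })
    dmaps <- lapply(stacks, compute_dalff_cv)
    if (config$write_subject_maps) {
      for (i in seq_along(dmaps)) {
        p <- file.path(wdir, sprintf("%s_dalff_%s.nii.gz",
                                     covariates$subject_id[i], wtag))
        write_nifti(nifti_image(dmaps[[i]]$cv, affine = affine), p)
        add_artifact(p)
      }
    }
    amaps <- if (config$standardize) {
      lapply(dmaps, standardize_map)
    } else dmaps
    M <- maps_to_matrix(amaps, mask)

    ctab <- stage(paste0("group_", wtag), {
      glm <- fit_voxelwise_glm(M, covariates, mask = mask, affine = affine)
      ct <- grf_cluster_correct(glm, mask, affine,
                                voxel_p = config$voxel_p,
                                cluster_p = config$cluster_p,
                                connectivity = config$connectivity)
      if (config$correction %in% c("permutation", "both")) {
        pt <- permutation_cluster_correct(
          M, covariates, mask = mask, affine = affine,
          voxel_p = config$voxel_p, cluster_p = config$cluster_p,
          n_perm = max(config$n_perm, 100L), seed = config$seed + w,
          connectivity = config$connectivity)
        ptab_path <- file.path(wdir, "clusters_permutation.csv")
        utils::write.csv(as.data.frame(pt), ptab_path, row.names = FALSE)
        add_artifact(ptab_path)
        if (config$correction == "permutation") ct <- pt
      }
      ct
    })
    ct_path <- file.path(wdir, "clusters.csv")
    utils::write.csv(as.data.frame(ctab), ct_path, row.names = FALSE)
    add_artifact(ct_path)
    labmap <- attr(ctab, "label_map")
    p <- file.path(wdir, "cluster_mask.nii.gz")
    write_nifti(nifti_image(array(as.numeric(labmap), dim(labmap)),
                            affine = affine), p)
    add_artifact(p)

    states <- stage(paste0("states_", wtag), {
      kw <- config$k
      if (identical(kw, "auto")) {
        kw <- select_k(stacks, k_range = config$k_range,
                       seed = config$seed + w)$k
      }
      model <- cluster_states(stacks, k = as.integer(kw),
                              seed = config$seed + w)
      metrics <- state_metrics_table(model, covariates)
      cmp <- compare_group_metrics(metrics)
      list(model = model, metrics = metrics, comparison = cmp)
    })
    mp <- file.path(wdir, "state_metrics.csv")
    utils::write.csv(states$metrics, mp, row.names = FALSE)
    add_artifact(mp)
    cp <- file.path(wdir, "state_group_comparison.csv")
    utils::write.csv(states$comparison, cp, row.names = FALSE)
    add_artifact(cp)
    ap <- file.path(wdir, "state_assignments.csv")
    utils::write.csv(data.frame(
      subject_id = rep(covariates$subject_id,
                       vapply(states$model$assignment, length, 1L)),
      window = unlist(lapply(states$model$assignment, seq_along)),
      state = unlist(states$model$assignment)), ap, row.names = FALSE)
    add_artifact(ap)

    svm_report <- NULL
    if (nrow(ctab) > 0) {
      svm_report <- stage(paste0("classify_", wtag), {
        ft <- extract_roi_features(amaps, labmap,
                                   labels = covariates$group,
                                   window_length = w)
        train_evaluate_svm(ft, scheme = config$svm_scheme,
                           grid = svm_grid(config$svm_grid_by),
                           seed = config$seed + w)
      })
      sp <- file.path(wdir, "svm_report.json")
      jsonlite::write_json(svm_report[c("accuracy", "sensitivity",
                                        "specificity", "auc", "chosen",
                                        "scheme")],
                           sp, auto_unbox = TRUE, digits = NA)
      add_artifact(sp)
      rp <- file.path(wdir, "roc.csv")
      utils::write.csv(svm_report$roc, rp, row.names = FALSE)
      add_artifact(rp)
    } else {
      .log_stage(paste0("classify_", wtag), as.numeric(Sys.time()),
                 "skipped: no surviving clusters")
    }

    corr_path <- NULL
    if (nrow(ctab) > 0) {
      corr <- stage(paste0("correlate_", wtag), {
        pos_ids <- ctab$cluster_id[ctab$sign == "+"]
        is_pat <- covariates$group == patient_level
        if (length(pos_ids) == 0 || sum(is_pat) < 4) NULL else {
          keep_lab <- array(0L, dim(labmap))
          for (cid in pos_ids) keep_lab[labmap == cid] <- cid
          ft <- extract_roi_features(amaps[is_pat], keep_lab,
                                     window_length = w)
          vals <- as.data.frame(ft$features)
          names(vals) <- paste0("cluster_", ft$cluster_ids)
          correlate_with_clinical(vals, covariates$score[is_pat])
        }
      })
      if (!is.null(corr)) {
        corr_path <- file.path(wdir, "clinical_correlation.csv")
        write_correlation_report(corr, corr_path)
        add_artifact(corr_path)
      }
    }

    manifest_entries[[wtag]] <- list(
      window = w, n_windows = nrow(stacks[[1]]$values),
      n_clusters = nrow(ctab), k_states = states$model$k,
      svm_accuracy = if (!is.null(svm_report)) svm_report$accuracy else NA,
      svm_auc = if (!is.null(svm_report)) svm_report$auc else NA)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dalff")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    windows = manifest_entries,
    artifacts = lapply(artifacts, function(p) {
      rel <- if (startsWith(p, out)) substring(p, nchar(out) + 2) else p
      list(path = rel, md5 = unname(tools::md5sum(p)))
    }))
  mpath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  .log_stage("run_pipeline", t0, paste0("artifacts=", length(artifacts)))
  invisible(manifest)
}
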