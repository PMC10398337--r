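#' Extract mean dALFF features from differential clusters
#'
#' Feature `(s, c)` is the mean CV of subject `s` inside cluster `c` of the
#' labeled cluster mask (one column per cluster label present).
#'
#' @param maps list of per-subject `dalff_map`s or 3D arrays on the mask
#'   grid.
#' @param cluster_labels integer-labeled 3D cluster mask (e.g. the
#'   `label_map` attribute of a [grf_cluster_correct] result).
#' @param labels subject class labels (length = number of maps).
#' @param window_length optional provenance tag.
#' @return object of class `feature_table`: `features` (subjects x clusters
#'   matrix), `labels`, `cluster_ids`, `window_length`.
#' @export
extract_roi_features <- function(maps, cluster_labels, labels = NULL,
                                 window_length = NA_integer_) {
  ids <- sort(setdiff(unique(as.vector(cluster_labels)), 0L))
  if (length(ids) == 0) stop("cluster mask contains no clusters")
  vox <- lapply(ids, function(cl) which(cluster_labels == cl))
  if (any(vapply(vox, length, 1L) == 0)) stop("empty cluster label")
  F <- t(vapply(maps, function(m) {
    if (inherits(m, "dalff_map")) m <- m$cv
    vapply(vox, function(v) mean(m[v]), numeric(1))
  }, numeric(length(ids))))
  F <- matrix(F, nrow = length(maps))
  colnames(F) <- paste0("cluster_", ids)
  if (any(!is.finite(F))) stop("non-finite feature values")
  structure(list(features = F, labels = labels, cluster_ids = ids,
                 window_length = window_length),
            class = "feature_table")
}

#' Default LIBSVM-style hyperparameter grid
#'
#' Powers of two: `C` in `2^seq(-5, 15, by)` and `gamma` in
#' `2^seq(-15, 3, by)`.
#'
#' @param by exponent step (default 4; 2 reproduces the classic dense grid).
#' @return list with numeric vectors `C` and `gamma`.
#' @export
svm_grid <- function(by = 4) {
  list(C = 2^seq(-5, 15, by = by), gamma = 2^seq(-15, 3, by = by))
}

#' Train and evaluate an RBF-SVM classifier on cluster features
#'
#' `(C, gamma)` are chosen by inner cross-validated accuracy over a
#' powers-of-two grid; the outer evaluation is leave-one-out by default
#' (`"kfold"` and the optimistic `"resubstitution"` mode are available).
#' Features are standardized with training-fold statistics only, so no
#' information from a held-out subject reaches its own prediction.
#'
#' @param features a `feature_table`, or a subjects x p matrix.
#' @param labels class labels (2 levels); taken from the feature table when
#'   NULL. The second sorted level is treated as the positive class unless
#'   one level is `"patient"`.
#' @param grid list with `C` and `gamma` vectors (default [svm_grid]).
#' @param scheme `"loo"` (default), `"kfold"`, or `"resubstitution"`.
#' @param k_outer outer folds for `"kfold"` (default 5).
#' @param inner_folds inner CV folds for the grid search (default 5).
#' @param seed RNG seed (fold shuffling).
#' @return object of class `classifier_report`: `accuracy` (percent),
#'   `sensitivity`, `specificity`, `auc`, `roc` (data.frame), `chosen`
#'   (modal (C, gamma) over outer folds), `scheme`, `seed`, `predictions`
#'   (per-subject decision value and predicted class).
#' @export
train_evaluate_svm <- function(features, labels = NULL, grid = svm_grid(),
                               scheme = c("loo", "kfold", "resubstitution"),
                               k_outer = 5L, inner_folds = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (inherits(features, "feature_table")) {
    if (is.null(labels)) labels <- features$labels
    X <- features$features
  } else X <- as.matrix(features)
  if (is.null(labels)) stop("labels required")
  y <- factor(labels)
  if (nlevels(y) != 2) stop("need exactly 2 classes")
  if (min(table(y)) < 3) stop("need at least 3 subjects per class")
  if (length(grid$C) == 0 || length(grid$gamma) == 0) stop("empty grid")
  pos_level <- if ("patient" %in% levels(y)) "patient" else levels(y)[2]
  n <- nrow(X)
  combos <- expand.grid(C = grid$C, gamma = grid$gamma)

  grid_search <- function(Xtr, ytr, fold_seed) {
    set.seed(fold_seed)
    folds <- .stratified_folds(as.character(ytr), inner_folds)
    acc <- vapply(seq_len(nrow(combos)), function(i) {
      .cv_accuracy(Xtr, as.character(ytr), combos$C[i], combos$gamma[i], folds)
    }, numeric(1))
    combos[which.max(acc), ]
  }

  outer_folds <- switch(scheme,
    loo = seq_len(n),
    kfold = { set.seed(seed); .stratified_folds(as.character(y), k_outer) },
    resubstitution = rep(1L, n))

  decision <- numeric(n)
  pred_class <- character(n)
  chosen_list <- list()
  if (scheme == "resubstitution") {
    best <- grid_search(X, y, seed)
    sc <- .scale_fit(X)
    m <- svm_train(.scale_apply(X, sc), as.character(y),
                   C = best$C, gamma = best$gamma)
    pr <- predict(m, .scale_apply(X, sc))
    decision <- pr$decision
    pred_class <- pr$class
    chosen_list[[1]] <- best
  } else {
    for (f in sort(unique(outer_folds))) {
      te <- outer_folds == f
      tr <- !te
      best <- grid_search(X[tr, , drop = FALSE], y[tr], seed + f)
      sc <- .scale_fit(X[tr, , drop = FALSE])
      m <- svm_train(.scale_apply(X[tr, , drop = FALSE], sc),
                     as.character(y[tr]), C = best$C, gamma = best$gamma)
      pr <- predict(m, .scale_apply(X[te, , drop = FALSE], sc))
      decision[te] <- pr$decision
      pred_class[te] <- pr$class
      chosen_list[[length(chosen_list) + 1L]] <- best
    }
  }
  # decision sign convention: positive margin = second training level; make
  # "larger = more patient-like" for the ROC
  lv <- levels(y)
  dec_pos <- if (pos_level == lv[2]) decision else -decision
  is_pos <- y == pos_level
  accuracy <- 100 * mean(pred_class == as.character(y))
  sensitivity <- mean(pred_class[is_pos] == pos_level)
  specificity <- mean(pred_class[!is_pos] != pos_level)
  rc <- roc_curve(dec_pos, is_pos)
  chosen_df <- do.call(rbind, chosen_list)
  chosen <- chosen_df[which.max(tabulate(match(
    paste(chosen_df$C, chosen_df$gamma),
    unique(paste(chosen_df$C, chosen_df$gamma))))), ]
  structure(list(accuracy = accuracy, sensitivity = sensitivity,
                 specificity = specificity, auc = rc$auc, roc = rc$roc,
                 chosen = as.list(chosen), scheme = scheme, seed = seed,
                 predictions = data.frame(label = as.character(y),
                                          decision = dec_pos,
                                          predicted = pred_class)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s: accuracy %.2f%%, AUC %.3f (sens %.2f, spec %.2f)\n",
              x$scheme, x$accuracy, x$auc, x$sensitivity, x$specificity))
  invisible(x)
}

#' Permutation test of classifier accuracy
#'
#' Re-runs the full evaluation with permuted labels `n_perm` times;
#' `p = (1 + #\{permuted accuracy >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams train_evaluate_svm
#' @param n_perm number of permutations (>= 100).
#' @return list with `p_value`, `observed_accuracy`, `null_accuracies`.
#' @export
permutation_test_classifier <- function(features, labels = NULL,
                                        grid = svm_grid(), n_perm = 100L,
                                        scheme = "loo", seed = 1L, ...) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (inherits(features, "feature_table") && is.null(labels))
    labels <- features$labels
  obs <- train_evaluate_svm(features, labels, grid = grid, scheme = scheme,
                            seed = seed, ...)
  set.seed(seed)
  null_acc <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    perm <- sample(labels)
    null_acc[p] <- train_evaluate_svm(features, perm, grid = grid,
                                      scheme = scheme, seed = seed + p,
                                      ...)$accuracy
  }
  list(p_value = (1 + sum(null_acc >= obs$accuracy)) / (n_perm + 1),
       observed_accuracy = obs$accuracy, null_accuracies = null_acc)
}
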