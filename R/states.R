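#' L1 (Manhattan) distances from rows of X to a centroid
#' @noRd
.l1_dist <- function(X, centroid) {
  rowSums(abs(sweep(X, 2, centroid)))
}

# Distance matrix rows(X) x rows(C).
.l1_dist_matrix <- function(X, C) {
  vapply(seq_len(nrow(C)), function(j) .l1_dist(X, C[j, ]),
         numeric(nrow(X)))
}

# Careful seeding under L1: first centroid uniform, then windows drawn with
# probability proportional to their distance to the nearest chosen centroid.
.l1_seed <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  if (k == 1) return(centers)
  dmin <- .l1_dist(X, centers[1, ])
  for (j in 2:k) {
    prob <- if (sum(dmin) > 0) dmin / sum(dmin) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = prob)
    centers[j, ] <- X[idx, ]
    dmin <- pmin(dmin, .l1_dist(X, centers[j, ]))
  }
  centers
}

.colMedians <- function(X) apply(X, 2, stats::median)

# One Lloyd run under L1: assign to nearest centroid by Manhattan distance,
# update centroids as component-wise medians (the L1 minimizer), repeat to
# an assignment fixed point. Empty clusters are re-seeded from the window
# farthest from its centroid. Returns assignment, centroids, cost trace.
.l1_kmeans_once <- function(X, k, max_iter) {
  centers <- .l1_seed(X, k)
  assign_prev <- rep(0L, nrow(X))
  cost_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- .l1_dist_matrix(X, centers)
    assign_new <- max.col(-D, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(assign_new == j)) {
        far <- which.max(D[cbind(seq_len(nrow(X)), assign_new)])
        assign_new[far] <- j
      }
    }
    for (j in seq_len(k)) {
      centers[j, ] <- .colMedians(X[assign_new == j, , drop = FALSE])
    }
    D <- .l1_dist_matrix(X, centers)
    cost_trace <- c(cost_trace, sum(D[cbind(seq_len(nrow(X)), assign_new)]))
    if (identical(assign_new, assign_prev)) break
    assign_prev <- assign_new
  }
  list(assignment = assign_new, centers = centers,
       cost = cost_trace[length(cost_trace)], cost_trace = cost_trace)
}

#' Cluster windowed ALFF maps into recurring states (L1 k-means)
#'
#' Pools the window-wise ALFF maps of all subjects and clusters them with
#' Lloyd-style k-means under the Manhattan (L1) distance: assignment to the
#' nearest centroid by L1 distance, centroid update by the component-wise
#' median. Best of `n_init` careful random initializations by total L1
#' cost; deterministic given `seed`. States are relabeled by descending
#' overall occupancy, so state 1 is the modal state.
#'
#' @param stacks list of [compute_windowed_alff] results (one per subject),
#'   all sharing voxel set, window and step.
#' @param k number of states (>= 2 for dynamics; 1 allowed and returns the
#'   overall component-wise median).
#' @param n_init random restarts (default 10).
#' @param max_iter Lloyd iterations per restart (default 100).
#' @param seed RNG seed (default 1).
#' @return object of class `state_model`: `k`, `centroids` (k x V),
#'   `assignment` (list per subject of window labels), `inertia` (total L1
#'   cost), `cost_trace`, `distance = "manhattan"`, `window`, `step`, `tr`,
#'   `subject_ids`.
#' @export
cluster_states <- function(stacks, k, n_init = 10L, max_iter = 100L, seed = 1L) {
  if (length(stacks) == 0) stop("no stacks given")
  Vs <- vapply(stacks, function(s) ncol(s$values), 1L)
  ws <- vapply(stacks, function(s) s$window, 1L)
  if (length(unique(Vs)) != 1 || length(unique(ws)) != 1)
    stop("all stacks must share the same voxel set and window length")
  X <- do.call(rbind, lapply(stacks, function(s) s$values))
  n_win <- vapply(stacks, function(s) nrow(s$values), 1L)
  if (nrow(X) < k) stop("total windows (", nrow(X), ") must be >= k")
  set.seed(seed)
  best <- NULL
  for (init in seq_len(n_init)) {
    run <- .l1_kmeans_once(X, k, max_iter)
    if (any(diff(run$cost_trace) > 1e-8))
      stop("internal error: L1 cost increased across iterations")
    if (is.null(best) || run$cost < best$cost) best <- run
  }
  # relabel by descending occupancy (modal state first)
  occ <- tabulate(best$assignment, k)
  ord <- order(occ, decreasing = TRUE)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  assignment <- relabel[best$assignment]
  centers <- best$centers[ord, , drop = FALSE]
  split_idx <- rep(seq_along(stacks), n_win)
  structure(list(k = k, centroids = centers,
                 assignment = split(assignment, split_idx),
                 inertia = best$cost, cost_trace = best$cost_trace,
                 distance = "manhattan",
                 window = stacks[[1]]$window, step = stacks[[1]]$step,
                 tr = stacks[[1]]$tr,
                 subject_ids = names(stacks)),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k=%d, %d subjects, inertia %.4g (L1)\n",
              x$k, length(x$assignment), x$inertia))
  invisible(x)
}

# Mean L1 silhouette over a subsample of windows.
.l1_silhouette <- function(X, assignment, k, max_points = 400L) {
  n <- nrow(X)
  use <- if (n > max_points) sort(sample.int(n, max_points)) else seq_len(n)
  sil <- numeric(length(use))
  for (ii in seq_along(use)) {
    i <- use[ii]
    d <- .l1_dist(X, X[i, ])
    own <- assignment == assignment[i]
    a <- if (sum(own) > 1) sum(d[own]) / (sum(own) - 1) else 0
    b <- Inf
    for (j in seq_len(k)) {
      if (j == assignment[i]) next
      others <- assignment == j
      if (any(others)) b <- min(b, mean(d[others]))
    }
    sil[ii] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(sil)
}

#' Choose the number of states from cost diagnostics
#'
#' Runs [cluster_states] for each k in `k_range`, reports total L1 cost and
#' mean L1 silhouette, and picks the elbow as the k with the maximum second
#' difference of the cost curve. The full curve is returned so the choice
#' can be overridden.
#'
#' @inheritParams cluster_states
#' @param k_range candidate k values, inside 2..10.
#' @return list with `k` (chosen), `diagnostics` (data.frame k, cost,
#'   silhouette), `flat` (TRUE when the curve gave no usable elbow and the
#'   smallest k was returned with a warning).
#' @export
select_k <- function(stacks, k_range = 2:6, n_init = 5L, max_iter = 100L,
                     seed = 1L) {
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > 10))
    stop("k_range must lie in 2..10")
  costs <- numeric(length(k_range))
  sils <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    sm <- cluster_states(stacks, k_range[i], n_init = n_init,
                         max_iter = max_iter, seed = seed + i)
    costs[i] <- sm$inertia
    X <- do.call(rbind, lapply(stacks, function(s) s$values))
    set.seed(seed + 1000 + i)
    sils[i] <- .l1_silhouette(X, unlist(sm$assignment), k_range[i])
  }
  diag_df <- data.frame(k = k_range, cost = costs, silhouette = sils)
  flat <- FALSE
  if (length(k_range) >= 3) {
    d2 <- diff(diff(costs))   # positive at an elbow (convex drop then flat)
    if (max(d2) <= 1e-10 * max(abs(costs))) {
      flat <- TRUE
      chosen <- k_range[1]
      warning("flat cost curve: no clear elbow, returning smallest k")
    } else {
      chosen <- k_range[which.max(d2) + 1L]
    }
  } else {
    chosen <- k_range[1]
    if (length(k_range) == 1) flat <- FALSE else {
      flat <- TRUE
      warning("k_range too short for an elbow; returning smallest k")
    }
  }
  list(k = chosen, diagnostics = diag_df, flat = flat)
}

#' Temporal state metrics for one subject
#'
#' Fractional occupancy (share of windows per state), mean dwell time
#' (average maximal-run length per state, in windows and in seconds via
#' `tr * step`), visits per minute, number of transitions, and the bigram
#' transition-probability matrix (rows over visited states sum to 1;
#' unvisited states are flagged with NA rows).
#'
#' @param assignment integer window labels in 1..k for one subject.
#' @param k number of states (default: max label).
#' @param tr repetition time, seconds.
#' @param step window step in TR units.
#' @return list of class `state_metrics`: `occupancy` (length k),
#'   `mean_dwell_windows`, `mean_dwell_seconds`, `visits_per_minute`,
#'   `n_transitions`, `transition_matrix` (k x k), `unvisited` (logical k).
#' @export
compute_state_metrics <- function(assignment, k = max(assignment), tr = 2,
                                  step = 1L) {
  W <- length(assignment)
  if (W == 0) stop("empty label sequence")
  occupancy <- tabulate(assignment, k) / W
  r <- rle(assignment)
  dwell <- rep(NA_real_, k)
  visits <- tabulate(r$values, k)
  for (j in seq_len(k)) {
    if (visits[j] > 0) dwell[j] <- mean(r$lengths[r$values == j])
  }
  n_trans <- sum(assignment[-1] != assignment[-W])
  P <- matrix(NA_real_, k, k)
  if (W > 1) {
    from <- assignment[-W]; to <- assignment[-1]
    for (j in seq_len(k)) {
      sel <- from == j
      if (any(sel)) P[j, ] <- tabulate(to[sel], k) / sum(sel)
    }
  }
  window_seconds <- tr * step
  scan_minutes <- W * window_seconds / 60
  structure(list(occupancy = occupancy,
                 mean_dwell_windows = dwell,
                 mean_dwell_seconds = dwell * window_seconds,
                 visits_per_minute = visits / scan_minutes,
                 n_transitions = n_trans,
                 transition_matrix = P,
                 unvisited = visits == 0, k = k, n_windows = W),
            class = "state_metrics")
}

#' Per-subject state-metric table for a cohort
#'
#' @param model a `state_model` from [cluster_states].
#' @param covariates covariate data.frame in subject order.
#' @return data.frame: one row per subject with occupancy_j, dwell_j
#'   (windows), n_transitions, plus id and group.
#' @export
state_metrics_table <- function(model, covariates = NULL) {
  k <- model$k
  rows <- lapply(seq_along(model$assignment), function(i) {
    m <- compute_state_metrics(model$assignment[[i]], k = k,
                               tr = model$tr, step = model$step)
    out <- c(m$occupancy, m$mean_dwell_windows, m$n_transitions)
    names(out) <- c(paste0("occupancy_", seq_len(k)),
                    paste0("dwell_", seq_len(k)), "n_transitions")
    out
  })
  df <- as.data.frame(do.call(rbind, rows))
  if (!is.null(covariates)) {
    df <- cbind(subject_id = covariates$subject_id, group = covariates$group,
                df, stringsAsFactors = FALSE)
  }
  df
}

# Normality-routed two-sample comparison shared with the clinical module:
# Shapiro-Wilk on each group; t-test when both look normal, Wilcoxon
# rank-sum otherwise.
.route_two_sample <- function(x, y, alpha_normality = 0.05) {
  if (stats::sd(c(x, y)) == 0) {
    return(list(method = "none", statistic = NA_real_, p = NA_real_,
                difference = mean(x) - mean(y), flagged = TRUE))
  }
  shap <- function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(0)  # route to rank-based
    stats::shapiro.test(v)$p.value
  }
  normal <- shap(x) >= alpha_normality && shap(y) >= alpha_normality
  if (normal) {
    ht <- stats::t.test(x, y)
    list(method = "t", statistic = unname(ht$statistic), p = ht$p.value,
         difference = mean(x) - mean(y), flagged = FALSE)
  } else {
    ht <- stats::wilcox.test(x, y, exact = FALSE)
    list(method = "wilcoxon", statistic = unname(ht$statistic), p = ht$p.value,
         difference = mean(x) - mean(y), flagged = FALSE)
  }
}

#' Group comparison of state metrics
#'
#' Compares occupancy, mean dwell time and transition count between the two
#' groups, metric by metric, using the shared normality-routed two-sample
#' test (t when both groups pass Shapiro-Wilk, Wilcoxon otherwise).
#' Zero-variance metrics are flagged and skipped.
#'
#' @param metrics data.frame from [state_metrics_table] with a `group`
#'   column.
#' @param alpha_normality Shapiro-Wilk routing threshold (default 0.05).
#' @return data.frame: metric, group means, difference, method, statistic, p,
#'   flagged.
#' @export
compare_group_metrics <- function(metrics, alpha_normality = 0.05) {
  if (!"group" %in% names(metrics)) stop("metrics must have a group column")
  groups <- unique(metrics$group)
  if (length(groups) != 2) stop("need exactly 2 groups")
  if (min(table(metrics$group)) < 2)
    stop("each group needs at least 2 subjects")
  metric_cols <- setdiff(names(metrics), c("subject_id", "group"))
  rows <- lapply(metric_cols, function(mc) {
    x <- metrics[[mc]][metrics$group == groups[1]]
    y <- metrics[[mc]][metrics$group == groups[2]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(metric = mc, mean_1 = mean(x), mean_2 = mean(y),
                        difference = NA_real_, method = "none",
                        statistic = NA_real_, p = NA_real_, flagged = TRUE))
    }
    r <- .route_two_sample(x, y, alpha_normality)
    data.frame(metric = mc, mean_1 = mean(x), mean_2 = mean(y),
               difference = r$difference, method = r$method,
               statistic = r$statistic, p = r$p, flagged = r$flagged)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("mean_", groups)
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones.
#'
#' @param a,b integer label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_i * sum_j / n2
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Greedy L1 matching of two centroid sets
#'
#' Matches each centroid of `A` to its nearest unmatched centroid of `B`
#' (greedy by increasing L1 distance); used to compare state models across
#' reorderings of the input.
#'
#' @param A,B k x V centroid matrices.
#' @return integer permutation `perm` with `B[perm[j], ]` matched to `A[j, ]`.
#' @export
match_centroids <- function(A, B) {
  k <- nrow(A)
  D <- .l1_dist_matrix(A, B)   # k x k
  perm <- integer(k)
  used <- rep(FALSE, k)
  ord <- order(D)
  for (o in ord) {
    i <- (o - 1) %% k + 1
    j <- (o - 1) %/% k + 1
    if (perm[i] == 0 && !used[j]) {
      perm[i] <- j
      used[j] <- TRUE
    }
  }
  perm
}
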