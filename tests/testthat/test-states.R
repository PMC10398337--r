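# Minimal stack constructor for clustering tests: windows x voxels matrices
# wrapped with the metadata cluster_states expects.
fake_stack <- function(values, window = 30L, step = 30L, tr = 2) {
  structure(list(values = values, voxel_idx = seq_len(ncol(values)),
                 dims = c(ncol(values), 1L, 1L),
                 mask = array(TRUE, c(ncol(values), 1, 1)),
                 affine = diag(4), window = window, step = step,
                 tr = tr, band = c(0.01, 0.08)),
            class = "windowed_alff_stack")
}

test_that("k = 1 returns the component-wise median; duplication is inert", {
  set.seed(41)
  X <- matrix(rnorm(20 * 6), 20, 6)
  sm <- cluster_states(list(fake_stack(X)), k = 1, n_init = 2, seed = 1)
  expect_equal(as.numeric(sm$centroids), apply(X, 2, median))
  # duplicating every window leaves centroids and assignments unchanged
  sm2 <- cluster_states(list(fake_stack(X), fake_stack(X)), k = 1,
                        n_init = 2, seed = 1)
  expect_equal(sm2$centroids, sm$centroids)
})

test_that("well-separated prototypes are recovered perfectly", {
  set.seed(42)
  protos <- rbind(rep(0, 8), rep(5, 8), c(rep(0, 4), rep(5, 4)))
  truth <- sample(1:3, 60, replace = TRUE)
  X <- protos[truth, ] + matrix(rnorm(60 * 8, sd = 0.05), 60, 8)
  sm <- cluster_states(list(fake_stack(X)), k = 3, n_init = 5, seed = 2)
  est <- sm$assignment[[1]]
  expect_equal(adjusted_rand_index(truth, est), 1)
  # subject order permutation: centroids match up to greedy L1 matching
  idx1 <- 1:30; idx2 <- 31:60
  smA <- cluster_states(list(fake_stack(X[idx1, ]), fake_stack(X[idx2, ])),
                        k = 3, n_init = 5, seed = 3)
  smB <- cluster_states(list(fake_stack(X[idx2, ]), fake_stack(X[idx1, ])),
                        k = 3, n_init = 5, seed = 3)
  perm <- match_centroids(smA$centroids, smB$centroids)
  expect_equal(smA$centroids, smB$centroids[perm, ], tolerance = 1e-8)
})

test_that("select_k finds planted structure and handles edge ranges", {
  set.seed(43)
  protos <- rbind(rep(0, 6), rep(4, 6), c(rep(4, 3), rep(0, 3)))
  truth <- sample(1:3, 90, replace = TRUE)
  X <- protos[truth, ] + matrix(rnorm(90 * 6, sd = 0.2), 90, 6)
  sel <- select_k(list(fake_stack(X)), k_range = 2:5, n_init = 3, seed = 4)
  expect_equal(sel$k, 3)
  expect_named(sel$diagnostics, c("k", "cost", "silhouette"))
  sel2 <- suppressWarnings(select_k(list(fake_stack(X)), k_range = 2))
  expect_equal(sel2$k, 2)
  expect_error(select_k(list(fake_stack(X)), k_range = 1:3), "2..10")
})

test_that("state metrics match hand computations", {
  m <- compute_state_metrics(c(1, 1, 2, 2, 2, 1), tr = 2, step = 1)
  expect_equal(m$n_transitions, 2)
  expect_equal(m$occupancy, c(0.5, 0.5))
  expect_equal(m$mean_dwell_windows, c(1.5, 3))
  expect_equal(m$mean_dwell_seconds, c(3, 6))
  # transition matrix from bigrams: 1->1 once, 1->2 once; 2->2 twice, 2->1 once
  expect_equal(m$transition_matrix,
               rbind(c(0.5, 0.5), c(1 / 3, 2 / 3)))
  cst <- compute_state_metrics(rep(2L, 10), k = 2, tr = 2, step = 1)
  expect_equal(cst$n_transitions, 0)
  expect_equal(cst$mean_dwell_windows[2], 10)
  expect_true(cst$unvisited[1])
  alt <- compute_state_metrics(rep(c(1L, 2L), 5), tr = 2, step = 1)
  expect_equal(alt$n_transitions, 9)
  expect_equal(alt$mean_dwell_windows, c(1, 1))
  expect_error(compute_state_metrics(integer(0)), "empty")
})

test_that("L1 cost trace is non-increasing on noisy data", {
  set.seed(44)
  X <- matrix(rnorm(100 * 5), 100, 5)
  sm <- cluster_states(list(fake_stack(X)), k = 4, n_init = 5, seed = 5)
  expect_true(all(diff(sm$cost_trace) <= 1e-8))
  # occupancy-ordered labels: state 1 is the modal state
  occ <- tabulate(sm$assignment[[1]], 4)
  expect_equal(which.max(occ), 1L)
})

test_that("group comparison routes and guards degenerate input", {
  set.seed(45)
  mt <- data.frame(subject_id = sprintf("s%02d", 1:20),
                   group = rep(c("patient", "control"), each = 10),
                   occupancy_1 = runif(20, 0.4, 0.6),
                   n_transitions = rpois(20, 5))
  cmp <- compare_group_metrics(mt)
  expect_setequal(cmp$metric, c("occupancy_1", "n_transitions"))
  expect_true(all(cmp$p > 0 & cmp$p <= 1))
  zero_var <- mt; zero_var$n_transitions <- 3
  cmpz <- compare_group_metrics(zero_var)
  expect_true(cmpz$flagged[cmpz$metric == "n_transitions"])
  single <- mt[c(1, 11), ]
  expect_error(compare_group_metrics(single), "at least 2")
})

test_that("planted faster switching shows up in transition counts", {
  # patients switch faster than controls in the generating chain; the
  # recovered per-subject transition counts separate the groups
  set.seed(46)
  n_epochs <- 40
  Pfast <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2, byrow = TRUE)
  Pslow <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  trans <- function(P, n) {
    vapply(seq_len(n), function(i) {
      s <- simulate_markov_chain(P, n_epochs)
      compute_state_metrics(s, k = 2, tr = 2, step = 30)$n_transitions
    }, numeric(1))
  }
  tp <- trans(Pfast, 12); tc <- trans(Pslow, 12)
  expect_gt(mean(tp), mean(tc))
  expect_lt(t.test(tp, tc)$p.value, 0.01)
})
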