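small_grid <- svm_grid(8)

test_that("extract_roi_features averages CV within labeled clusters", {
  dims <- c(6, 6, 4)
  lab <- array(0L, dims)
  lab[2:3, 2:3, 2] <- 1L          # 4 voxels
  lab[5, 5, 3:4] <- 2L            # 2 voxels
  m1 <- array(0.5, dims)
  set.seed(51)
  m2 <- array(runif(prod(dims)), dims)
  ft <- extract_roi_features(list(m1, m2), lab,
                             labels = c("patient", "control"))
  expect_equal(dim(ft$features), c(2, 2))
  expect_equal(ft$features[1, ], c(cluster_1 = 0.5, cluster_2 = 0.5))
  expect_equal(unname(ft$features[2, 1]), mean(m2[lab == 1L]))
  expect_error(extract_roi_features(list(m1), array(0L, dims)),
               "no clusters")
})

test_that("separable features give perfect LOO accuracy and AUC", {
  set.seed(52)
  X <- matrix(c(rnorm(10, 0, 0.01), rnorm(10, 10, 0.01)), ncol = 1)
  y <- rep(c("control", "patient"), each = 10)
  rep1 <- train_evaluate_svm(X, y, grid = small_grid, seed = 1)
  expect_equal(rep1$accuracy, 100)
  expect_equal(rep1$auc, 1)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)
})

test_that("an uninformative constant feature is chance level", {
  X <- matrix(1, 20, 1)
  y <- rep(c("control", "patient"), each = 10)
  r <- train_evaluate_svm(X, y, grid = small_grid, scheme = "kfold", seed = 2)
  expect_equal(r$accuracy, 50)
  expect_equal(r$auc, 0.5, tolerance = 0.05)
})

test_that("ROC is monotone and AUC is rank-invariant", {
  set.seed(53)
  dec <- rnorm(30)
  lab <- dec + rnorm(30) > 0
  rc <- roc_curve(dec, lab)
  expect_equal(rc$roc$fpr[1], 0); expect_equal(rc$roc$tpr[1], 0)
  expect_equal(rc$roc$fpr[nrow(rc$roc)], 1)
  expect_equal(rc$roc$tpr[nrow(rc$roc)], 1)
  expect_true(all(diff(rc$roc$fpr) >= 0))
  expect_true(all(diff(rc$roc$tpr) >= 0))
  rc2 <- roc_curve(exp(3 * dec) + 5, lab)   # strictly increasing transform
  expect_equal(rc2$auc, rc$auc, tolerance = 1e-12)
})

test_that("standardization uses training-fold statistics only (canary)", {
  set.seed(54)
  X <- matrix(c(rnorm(8, 0, 1), rnorm(8, 3, 1)), ncol = 1)
  y <- rep(c("control", "patient"), each = 8)
  tr_idx <- c(1:7, 9:15)
  te <- X[c(8, 16), , drop = FALSE]
  sc <- dalff:::.scale_fit(X[tr_idx, , drop = FALSE])
  m <- svm_train(dalff:::.scale_apply(X[tr_idx, , drop = FALSE], sc),
                 y[tr_idx], C = 1, gamma = 0.5)
  p1 <- predict(m, dalff:::.scale_apply(te, sc))
  # adding out-of-fold copies of the test subjects must not change their
  # predictions (no test-set statistic is ever used)
  te_aug <- rbind(te, te, te)
  p2 <- predict(m, dalff:::.scale_apply(te_aug, sc))
  expect_equal(p2$decision[1:2], p1$decision)
  expect_equal(p2$class[1:2], p1$class)
})

test_that("SMO agrees with a hard-margin closed form on 1D points", {
  # two points at -1 and +1: symmetric solution, decision boundary at 0
  X <- matrix(c(-1, 1), ncol = 1)
  m <- svm_train(X, c(-1, 1), C = 100, gamma = 0.5)
  expect_equal(m$alpha[1], m$alpha[2], tolerance = 1e-6)
  d <- predict(m, matrix(c(-2, 0, 2), ncol = 1))$decision
  expect_equal(d[2], 0, tolerance = 1e-6)
  expect_lt(d[1], 0); expect_gt(d[3], 0)
})

test_that("permutation test rejects invalid inputs", {
  X <- matrix(rnorm(12), ncol = 1)
  y <- rep(c("control", "patient"), each = 6)
  expect_error(permutation_test_classifier(X, y, n_perm = 0), ">= 100")
  expect_error(train_evaluate_svm(X, y, grid = list(C = numeric(0),
                                                    gamma = numeric(0))),
               "empty grid")
  expect_error(train_evaluate_svm(X[1:8, , drop = FALSE],
                                  c(rep("a", 2), rep("b", 6))),
               "3 subjects")
})
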