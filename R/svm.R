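#' RBF kernel matrix
#'
#' `K(x, y) = exp(-gamma * ||x - y||^2)` for all row pairs.
#'
#' @param A n x p matrix.
#' @param B m x p matrix (default A).
#' @param gamma kernel width parameter (> 0).
#' @return n x m kernel matrix.
#' @export
rbf_kernel <- function(A, B = A, gamma) {
  A <- as.matrix(A); B <- as.matrix(B)
  an <- rowSums(A^2); bn <- rowSums(B^2)
  sq <- outer(an, bn, "+") - 2 * A %*% t(B)
  sq[sq < 0] <- 0
  exp(-gamma * sq)
}

#' Train a binary C-SVC with RBF kernel (SMO)
#'
#' Sequential-minimal-optimization solver for the soft-margin SVM dual,
#' LIBSVM-style formulation. Deterministic (the second working-set index is
#' chosen by the maximum-|E_i - E_j| heuristic, not at random).
#'
#' @param X n x p feature matrix.
#' @param y labels in `{-1, +1}` (or a 2-level factor, first level = -1).
#' @param C soft-margin cost (> 0).
#' @param gamma RBF width (> 0).
#' @param tol KKT violation tolerance (default 1e-3).
#' @param max_passes passes without change before declaring convergence.
#' @param max_iter hard iteration cap.
#' @return object of class `svm_model`: support coefficients `alpha`,
#'   intercept `b`, training data reference, `C`, `gamma`, `levels`.
#' @export
svm_train <- function(X, y, C = 1, gamma = 1 / ncol(X), tol = 1e-3,
                      max_passes = 10L, max_iter = 5000L) {
  X <- as.matrix(X)
  lv <- NULL
  if (!is.numeric(y)) {
    f <- factor(y)
    if (nlevels(f) != 2) stop("need exactly 2 classes")
    lv <- levels(f)
    y <- ifelse(as.integer(f) == 1, -1, 1)
  }
  if (!all(y %in% c(-1, 1))) stop("numeric y must be -1/+1")
  if (length(unique(y)) != 2) stop("need both classes present")
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  alpha <- numeric(n)
  b <- 0
  fvals <- numeric(n)      # K %*% (alpha * y), maintained incrementally
  passes <- 0L; iter <- 0L
  while (passes < max_passes && iter < max_iter) {
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- fvals[i] + b - y[i]
      if (!((y[i] * Ei < -tol && alpha[i] < C) ||
            (y[i] * Ei > tol && alpha[i] > 0))) next
      E_all <- fvals + b - y
      j <- which.max(abs(E_all - Ei))
      if (j == i) next
      Ej <- E_all[j]
      ai_old <- alpha[i]; aj_old <- alpha[j]
      if (y[i] != y[j]) {
        L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
      } else {
        L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
      }
      if (L >= H) next
      eta <- 2 * K[i, j] - K[i, i] - K[j, j]
      if (eta >= 0) next
      aj <- aj_old - y[j] * (Ei - Ej) / eta
      aj <- min(max(aj, L), H)
      if (abs(aj - aj_old) < 1e-7) next
      ai <- ai_old + y[i] * y[j] * (aj_old - aj)
      alpha[i] <- ai; alpha[j] <- aj
      fvals <- fvals + (ai - ai_old) * y[i] * K[, i] +
        (aj - aj_old) * y[j] * K[, j]
      b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
        y[j] * (aj - aj_old) * K[i, j]
      b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
        y[j] * (aj - aj_old) * K[j, j]
      b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
      changed <- changed + 1L
    }
    passes <- if (changed == 0L) passes + 1L else 0L
    iter <- iter + 1L
  }
  structure(list(alpha = alpha, b = b, X = X, y = y, C = C, gamma = gamma,
                 levels = lv),
            class = "svm_model")
}

#' Decision values and class predictions from an SVM model
#'
#' @param object an `svm_model`.
#' @param newdata m x p matrix.
#' @param ... unused.
#' @return list with `decision` (signed margin values) and `class`
#'   (predicted labels; original levels when the model was fit on a factor).
#' @export
predict.svm_model <- function(object, newdata, ...) {
  K <- rbf_kernel(as.matrix(newdata), object$X, object$gamma)
  dec <- as.vector(K %*% (object$alpha * object$y)) + object$b
  cls <- ifelse(dec >= 0, 1, -1)
  if (!is.null(object$levels)) cls <- object$levels[ifelse(cls == 1, 2, 1)]
  list(decision = dec, class = cls)
}

# Stratified fold assignment: deterministic given the RNG state.
.stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  folds
}

.scale_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
.scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

# Inner cross-validated accuracy for one (C, gamma); folds precomputed.
.cv_accuracy <- function(X, y, C, gamma, folds) {
  correct <- 0L
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) next
    sc <- .scale_fit(X[tr, , drop = FALSE])
    m <- svm_train(.scale_apply(X[tr, , drop = FALSE], sc), y[tr],
                   C = C, gamma = gamma)
    pr <- predict(m, .scale_apply(X[!tr, , drop = FALSE], sc))
    correct <- correct + sum(pr$class == y[!tr])
  }
  correct / length(y)
}

#' ROC curve and AUC from decision values
#'
#' @param decision numeric decision values (larger = more positive-class).
#' @param labels logical or 0/1 vector, TRUE/1 = positive class.
#' @return list with `roc` (data.frame fpr, tpr, starting (0,0), ending
#'   (1,1), monotone) and `auc` (Mann-Whitney; ties get 1/2).
#' @export
roc_curve <- function(decision, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need both classes for a ROC curve")
  r <- rank(decision, ties.method = "average")
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(decision, decreasing = TRUE)
  tp <- cumsum(labels[ord]); fp <- cumsum(!labels[ord])
  roc <- data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  roc <- roc[!duplicated(roc[, c("fpr", "tpr")]), ]
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  list(roc = roc, auc = auc)
}
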