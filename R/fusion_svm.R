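# Fused-kernel SVM: convex combination of a spectral RBF Gram matrix and an
# image-feature RBF Gram matrix feeding one precomputed-kernel C-SVM
# (kernlab, one-vs-one multiclass).

#' RBF Gram matrix
#'
#' `K[i, j] = exp(-gamma * ||a_i - b_j||^2)`.
#'
#' @param A,B feature matrices with equal width; `B = NULL` uses `A`.
#' @param gamma positive kernel width parameter.
#' @return `nrow(A)` x `nrow(B)` Gram matrix.
#' @export
rbf_gram <- function(A, B = NULL, gamma) {
  A <- as.matrix(A)
  B <- if (is.null(B)) A else as.matrix(B)
  if (ncol(A) != ncol(B)) stopf("feature widths differ (%d vs %d)", ncol(A), ncol(B))
  if (gamma <= 0) stopf("gamma must be positive")
  check_finite(A, "features"); check_finite(B, "features")
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Convex fusion of two Gram matrices
#'
#' Elementwise `mu * K1 + (1 - mu) * K2`. Throughout the pipeline the
#' spectral kernel is passed first, so `mu` weights the spectral modality
#' and `mu = 1` reduces the model to the spectral-only SVM.
#'
#' @param Ks,Kw Gram matrices of equal shape.
#' @param mu fusion weight in [0, 1].
#' @return fused Gram matrix (positive semidefinite whenever both inputs
#'   are).
#' @export
fuse_kernels <- function(Ks, Kw, mu) {
  if (!identical(dim(Ks), dim(Kw))) stopf("Gram shapes differ")
  if (mu < 0 || mu > 1) stopf("mu must lie in [0, 1]")
  mu * Ks + (1 - mu) * Kw
}

#' Scale-heuristic RBF gamma
#'
#' `1 / (n_features * var(X))`, the common default width for standardized
#' feature blocks.
#'
#' @param X feature matrix.
#' @return positive scalar.
#' @export
gamma_scale <- function(X) {
  v <- stats::var(as.vector(as.matrix(X)))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

#' Fit a precomputed-kernel C-SVM
#'
#' One-vs-one binary C-SVMs on the supplied Gram matrix; prediction is by
#' majority vote with the standard decision-value tie-break. The Gram matrix
#' must be symmetric positive semidefinite within tolerance; small negative
#' eigenvalues can be clipped on request.
#'
#' @param K n x n training Gram matrix.
#' @param labels n class labels (>= 2 classes).
#' @param C regularization (error tolerance) parameter, > 0.
#' @param psd_tol negative-eigenvalue tolerance relative to the largest
#'   eigenvalue.
#' @param clip_eigenvalues clip negative eigenvalues to 0 instead of
#'   erroring.
#' @return a `fused_svm`: kernlab model plus label levels and `C`.
#' @export
fit_fused_svm <- function(K, labels, C = 1, psd_tol = 1e-8,
                          clip_eigenvalues = FALSE) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stopf("K must be square")
  if (nrow(K) != length(labels)) stopf("one label per training row required")
  if (C <= 0) stopf("C must be positive")
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stopf("K is not symmetric")
  K <- (K + t(K)) / 2
  lam <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) < -psd_tol * max(1, max(lam))) {
    if (!clip_eigenvalues)
      stopf("K is not positive semidefinite (min eigenvalue %.3g); set clip_eigenvalues = TRUE to clip",
            min(lam))
    ev <- eigen(K, symmetric = TRUE)
    K <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    K <- (K + t(K)) / 2
  }
  y <- factor(labels)
  if (nlevels(y) < 2) stopf("need at least 2 classes")
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc", C = C)
  structure(list(ksvm = m, levels = levels(y), C = C, n = nrow(K)),
            class = "fused_svm")
}

#' Predict from a precomputed-kernel SVM fit
#'
#' @param fit a `fused_svm`.
#' @param K_new m x n_train cross Gram matrix between new samples (rows) and
#'   the training samples (columns, in training order).
#' @return character vector of predicted labels (training level set).
#' @export
predict_fused_svm <- function(fit, K_new) {
  stopifnot(inherits(fit, "fused_svm"))
  K_new <- as.matrix(K_new)
  if (ncol(K_new) != fit$n) stopf("K_new must have %d columns", fit$n)
  sv <- kernlab::SVindex(fit$ksvm)
  p <- kernlab::predict(fit$ksvm,
                        kernlab::as.kernelMatrix(K_new[, sv, drop = FALSE]))
  as.character(p)
}

#' Dual feasibility diagnostics of a fit
#'
#' For every one-vs-one binary subproblem, reports `sum(alpha_i * y_i)`
#' (should be 0), and the range of `alpha` (should lie in `[0, C]`), within
#' solver tolerance.
#'
#' @param fit a `fused_svm`.
#' @return data.frame with one row per binary machine: `machine`,
#'   `sum_alpha_y`, `min_alpha`, `max_alpha`.
#' @export
svm_dual_check <- function(fit) {
  stopifnot(inherits(fit, "fused_svm"))
  co <- kernlab::coef(fit$ksvm)    # alpha_i * y_i per binary machine
  al <- kernlab::alpha(fit$ksvm)   # alpha_i >= 0 per binary machine
  if (!is.list(co)) co <- list(co)
  if (!is.list(al)) al <- list(al)
  data.frame(machine = seq_along(co),
             sum_alpha_y = vapply(co, sum, numeric(1)),
             min_alpha = vapply(al, min, numeric(1)),
             max_alpha = vapply(al, max, numeric(1)))
}

fit_scaler <- function(X) {
  s <- apply(X, 2, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(center = colMeans(X), scale = s)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(as.matrix(X), 2, scaler$center), 2, scaler$scale, `/`)
}

#' Kernel-fusion hyperparameter set
#'
#' @param mu spectral-kernel weight in [0, 1].
#' @param gamma_s,gamma_w RBF widths for the spectral and image blocks.
#' @param C SVM regularization parameter.
#' @return a `kernel_config` list.
#' @export
kernel_config <- function(mu, gamma_s, gamma_w, C) {
  if (mu < 0 || mu > 1) stopf("mu must lie in [0, 1]")
  if (gamma_s <= 0 || gamma_w <= 0) stopf("gammas must be positive")
  if (C <= 0) stopf("C must be positive")
  structure(list(mu = mu, gamma_s = gamma_s, gamma_w = gamma_w, C = C),
            class = "kernel_config")
}

#' Train the fused-kernel model
#'
#' Standardizes both feature blocks (training-fit z-scoring), builds the two
#' RBF Gram matrices, fuses them with weight `mu` on the spectral kernel,
#' and fits the precomputed-kernel SVM. Stores the scalers and training
#' feature blocks needed to kernelize new samples.
#'
#' @param spectral_features n x p training spectral block (e.g. SPA-selected
#'   pretreated spectra).
#' @param image_features n x q training image-feature block.
#' @param labels n class labels.
#' @param config a [kernel_config()].
#' @param standardize z-score both blocks before the RBF (default TRUE).
#' @param sample_ids optional training ids.
#' @return a `fused_kernel_model`.
#' @export
train_fused_model <- function(spectral_features, image_features, labels, config,
                              standardize = TRUE, sample_ids = NULL) {
  stopifnot(inherits(config, "kernel_config"))
  Xs <- as.matrix(spectral_features)
  Xw <- as.matrix(image_features)
  if (nrow(Xs) != nrow(Xw) || nrow(Xs) != length(labels))
    stopf("spectral and image blocks must align with labels")
  sc_s <- if (standardize) fit_scaler(Xs) else NULL
  sc_w <- if (standardize) fit_scaler(Xw) else NULL
  Zs <- if (standardize) apply_scaler(Xs, sc_s) else Xs
  Zw <- if (standardize) apply_scaler(Xw, sc_w) else Xw
  K <- fuse_kernels(rbf_gram(Zs, gamma = config$gamma_s),
                    rbf_gram(Zw, gamma = config$gamma_w), config$mu)
  fit <- fit_fused_svm(K, labels, C = config$C)
  structure(list(fit = fit, config = config,
                 scaler_s = sc_s, scaler_w = sc_w,
                 train_spectral = Zs, train_image = Zw,
                 training_sample_ids = sample_ids,
                 label_type = typeof(labels)),
            class = "fused_kernel_model")
}

#' Predict class labels for new samples
#'
#' Builds the cross Gram blocks between the new samples and the stored
#' training features, fuses them with the trained weight, and votes.
#'
#' @param object a `fused_kernel_model` from [train_fused_model()].
#' @param spectral_features,image_features new feature blocks with the
#'   training widths.
#' @param ... unused.
#' @return predicted labels (integer when training labels were numeric).
#' @method predict fused_kernel_model
#' @export
predict.fused_kernel_model <- function(object, spectral_features,
                                       image_features, ...) {
  Xs <- as.matrix(spectral_features)
  Xw <- as.matrix(image_features)
  if (ncol(Xs) != ncol(object$train_spectral))
    stopf("spectral feature width %d differs from training width %d",
          ncol(Xs), ncol(object$train_spectral))
  if (ncol(Xw) != ncol(object$train_image))
    stopf("image feature width %d differs from training width %d",
          ncol(Xw), ncol(object$train_image))
  Zs <- if (is.null(object$scaler_s)) Xs else apply_scaler(Xs, object$scaler_s)
  Zw <- if (is.null(object$scaler_w)) Xw else apply_scaler(Xw, object$scaler_w)
  K <- fuse_kernels(rbf_gram(Zs, object$train_spectral, object$config$gamma_s),
                    rbf_gram(Zw, object$train_image, object$config$gamma_w),
                    object$config$mu)
  p <- predict_fused_svm(object$fit, K)
  if (object$label_type %in% c("integer", "double")) as.integer(p) else p
}

#' Grid search over fusion weight and SVM hyperparameters
#'
#' Stratified k-fold cross-validated accuracy for every grid point
#' (mu x C x gamma_s x gamma_w), on the training partition only. Ties break
#' to the smaller C, then the larger mu, then the smaller gammas.
#'
#' @param spectral_features,image_features training feature blocks.
#' @param labels training class labels.
#' @param mu_grid fusion weights in [0, 1].
#' @param C_grid SVM regularization values.
#' @param gamma_s_grid,gamma_w_grid RBF widths; `NULL` uses
#'   `c(scale heuristic, 0.01, 0.1, 1)` for that block, and the string
#'   `"scale"` uses the scale heuristic alone.
#' @param cv_folds number of stratified folds (>= 2).
#' @param seed fold-assignment seed.
#' @param standardize z-score blocks before the RBF.
#' @return list: `best` ([kernel_config()]), `best_accuracy`, `cv_table`
#'   (full CV accuracy table).
#' @export
grid_search_fused <- function(spectral_features, image_features, labels,
                              mu_grid = seq(0, 1, 0.1),
                              C_grid = c(0.1, 1, 10, 100),
                              gamma_s_grid = NULL, gamma_w_grid = NULL,
                              cv_folds = 5, seed = 1, standardize = TRUE) {
  Xs <- as.matrix(spectral_features)
  Xw <- as.matrix(image_features)
  n <- nrow(Xs)
  if (nrow(Xw) != n || length(labels) != n) stopf("blocks and labels must align")
  if (length(mu_grid) == 0 || length(C_grid) == 0) stopf("grids must be non-empty")
  if (cv_folds < 2) stopf("cv_folds must be >= 2")
  if (standardize) {
    Xs <- apply_scaler(Xs, fit_scaler(Xs))
    Xw <- apply_scaler(Xw, fit_scaler(Xw))
  }
  gamma_s_grid <- if (identical(gamma_s_grid, "scale")) gamma_scale(Xs) else
    gamma_s_grid %||% unique(c(gamma_scale(Xs), 0.01, 0.1, 1))
  gamma_w_grid <- if (identical(gamma_w_grid, "scale")) gamma_scale(Xw) else
    gamma_w_grid %||% unique(c(gamma_scale(Xw), 0.01, 0.1, 1))
  folds <- stratified_folds(labels, cv_folds, seed)
  for (f in folds) {
    if (!setequal(unique(labels[-f]), unique(labels)))
      stopf("a CV fold is missing a class in its training part; use fewer folds")
  }
  grid <- expand.grid(gamma_s = gamma_s_grid, gamma_w = gamma_w_grid,
                      mu = mu_grid, C = C_grid, KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- NA_real_
  gram_s <- lapply(gamma_s_grid, function(g) rbf_gram(Xs, gamma = g))
  gram_w <- lapply(gamma_w_grid, function(g) rbf_gram(Xw, gamma = g))
  for (gi in seq_along(gamma_s_grid)) {
    for (gj in seq_along(gamma_w_grid)) {
      for (mu in mu_grid) {
        K <- fuse_kernels(gram_s[[gi]], gram_w[[gj]], mu)
        for (C in C_grid) {
          correct <- 0L
          for (f in folds) {
            tr <- setdiff(seq_len(n), f)
            fit <- fit_fused_svm(K[tr, tr], labels[tr], C = C,
                                 clip_eigenvalues = TRUE)
            pred <- predict_fused_svm(fit, K[f, tr, drop = FALSE])
            correct <- correct + sum(pred == as.character(labels[f]))
          }
          row <- which(grid$gamma_s == gamma_s_grid[gi] &
                         grid$gamma_w == gamma_w_grid[gj] &
                         grid$mu == mu & grid$C == C)
          grid$accuracy[row] <- correct / n
        }
      }
    }
  }
  o <- order(-grid$accuracy, grid$C, -grid$mu, grid$gamma_s, grid$gamma_w)
  best <- grid[o[1], ]
  list(best = kernel_config(best$mu, best$gamma_s, best$gamma_w, best$C),
       best_accuracy = best$accuracy,
       cv_table = grid)
}

#' Single-modality grid search
#'
#' Convenience wrapper: the fused grid search with `mu` pinned to 1 and the
#' supplied block in the spectral slot, i.e. plain RBF-SVM model selection.
#'
#' @inheritParams grid_search_fused
#' @param features the single feature block.
#' @param gamma_grid RBF widths (`NULL`: scale heuristic, 0.01, 0.1, 1).
#' @export
grid_search_single <- function(features, labels, C_grid = c(0.1, 1, 10, 100),
                               gamma_grid = NULL, cv_folds = 5, seed = 1,
                               standardize = TRUE) {
  grid_search_fused(features, features, labels,
                    mu_grid = 1, C_grid = C_grid,
                    gamma_s_grid = gamma_grid, gamma_w_grid = 1,
                    cv_folds = cv_folds, seed = seed,
                    standardize = standardize)
}
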