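test_that("RBF Gram entries equal their closed form", {
  A <- matrix(c(0, 1, 2, -1, 0.5, 3), 3, 2)
  B <- matrix(c(1, 0, -2, 1), 2, 2)
  K <- rbf_gram(A, B, gamma = 0.5)
  for (i in 1:3) for (j in 1:2) {
    expect_equal(K[i, j], exp(-0.5 * sum((A[i, ] - B[j, ])^2)), tolerance = 1e-12)
  }
  expect_equal(diag(rbf_gram(A, gamma = 2)), rep(1, 3))
  expect_true(all(abs(rbf_gram(A, B, gamma = 1e-12) - 1) < 1e-9))
  expect_error(rbf_gram(A, B, gamma = 0), "gamma")
  expect_error(rbf_gram(A, matrix(1, 2, 3), gamma = 1), "widths")
})

test_that("kernel fusion is exact at its endpoints and convex in between", {
  set.seed(6)
  X1 <- matrix(rnorm(30), 10, 3); X2 <- matrix(rnorm(40), 10, 4)
  Ks <- rbf_gram(X1, gamma = 0.3); Kw <- rbf_gram(X2, gamma = 0.1)
  expect_identical(fuse_kernels(Ks, Kw, 1), Ks)
  expect_identical(fuse_kernels(Ks, Kw, 0), Kw)
  expect_equal(fuse_kernels(Ks, Kw, 0.5), (Ks + Kw) / 2)
  toy1 <- matrix(c(1, 0.2, 0.2, 1), 2); toy2 <- matrix(c(1, 0.8, 0.8, 1), 2)
  expect_equal(fuse_kernels(toy1, toy2, 0.5), matrix(c(1, 0.5, 0.5, 1), 2))
  expect_error(fuse_kernels(Ks, Kw[1:5, 1:5], 0.5), "shapes")
  expect_error(fuse_kernels(Ks, Kw, 1.2), "mu")

  # PSD is preserved for every mu in [0, 1]
  for (r in 1:10) {
    set.seed(r)
    K1 <- rbf_gram(matrix(rnorm(24), 8, 3), gamma = runif(1, 0.05, 2))
    K2 <- rbf_gram(matrix(rnorm(24), 8, 3), gamma = runif(1, 0.05, 2))
    for (mu in c(0, 0.3, 0.7, 1)) {
      ev <- eigen(fuse_kernels(K1, K2, mu), symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8)
    }
  }
})

test_that("the dual solution matches analytic and QP oracles", {
  # 1-D toy with a hard-margin closed form: class -1 at {0, -1}, class +1 at
  # {2, 3}; supports are 0 and 2 with alpha = 1/2, w = 1, f(x) = x - 1.
  x <- c(0, -1, 2, 3); y <- c(-1, -1, 1, 1)
  fit <- fit_fused_svm(outer(x, x), y, C = 1000)
  expect_identical(sort(kernlab::alphaindex(fit$ksvm)[[1]]), c(1L, 3L))
  expect_equal(sort(kernlab::alpha(fit$ksvm)[[1]]), c(0.5, 0.5), tolerance = 1e-6)
  co <- kernlab::coef(fit$ksvm)[[1]]
  sv <- kernlab::alphaindex(fit$ksvm)[[1]]
  expect_equal(sum(co * x[sv]), 1, tolerance = 1e-6)            # w
  expect_equal(kernlab::b(fit$ksvm), 1, tolerance = 1e-6)       # f(x) = w x - b

  # interior-point QP oracle on a separable 2-D toy
  set.seed(4)
  X <- rbind(matrix(rnorm(6, -2, 0.5), 3, 2), matrix(rnorm(6, 2, 0.5), 3, 2))
  y2 <- c(-1, -1, -1, 1, 1, 1); C <- 10
  K <- tcrossprod(X)
  qp <- kernlab::ipop(c = rep(-1, 6), H = (y2 %o% y2) * K + diag(6) * 1e-8,
                      A = matrix(y2, 1), b = 0, l = rep(0, 6), u = rep(C, 6),
                      r = 0, sigf = 9)
  a_oracle <- kernlab::primal(qp)
  fit2 <- fit_fused_svm(K, y2, C = C)
  a_fit <- rep(0, 6)
  a_fit[kernlab::alphaindex(fit2$ksvm)[[1]]] <- kernlab::alpha(fit2$ksvm)[[1]]
  expect_equal(a_fit, a_oracle, tolerance = 1e-5)
  expect_equal(colSums(a_fit * y2 * X), colSums(a_oracle * y2 * X),
               tolerance = 1e-6)
})

test_that("every fit satisfies dual feasibility and separable recovery", {
  set.seed(12)
  X <- rbind(matrix(rnorm(20, -3), 10, 2), matrix(rnorm(20, 3), 10, 2))
  y <- rep(c(0, 1), each = 10)
  K <- rbf_gram(X, gamma = 0.5)
  fit <- fit_fused_svm(K, y, C = 100)
  expect_identical(predict_fused_svm(fit, K), as.character(y))
  d <- svm_dual_check(fit)
  expect_true(all(abs(d$sum_alpha_y) < 1e-6))
  expect_true(all(d$min_alpha >= -1e-6 & d$max_alpha <= 100 + 1e-6))

  # 4-class one-vs-one: 6 binary machines, all feasible
  set.seed(13)
  X4 <- matrix(rnorm(80), 40, 2) + 2.5 * cbind(rep(0:3, each = 10) %% 2,
                                               rep(0:3, each = 10) %/% 2)
  K4 <- rbf_gram(X4, gamma = 0.7)
  fit4 <- fit_fused_svm(K4, rep(0:3, each = 10), C = 10)
  d4 <- svm_dual_check(fit4)
  expect_identical(nrow(d4), 6L)
  expect_true(all(abs(d4$sum_alpha_y) < 1e-6))
  expect_true(all(d4$min_alpha >= -1e-6 & d4$max_alpha <= 10 + 1e-6))
})

test_that("non-PSD kernels are rejected unless eigenvalue clipping is requested", {
  K <- diag(4); K[1, 2] <- K[2, 1] <- 2  # indefinite
  expect_error(fit_fused_svm(K, c(0, 0, 1, 1), C = 1), "clip_eigenvalues")
  expect_error(fit_fused_svm(matrix(rnorm(16), 4), c(0, 0, 1, 1)), "symmetric")
  fit <- fit_fused_svm(K, c(0, 0, 1, 1), C = 1, clip_eigenvalues = TRUE)
  expect_s3_class(fit, "fused_svm")
})

test_that("the fused model predicts row-wise with training-width checks", {
  set.seed(14)
  n <- 24
  y <- rep(0:1, each = n / 2)
  Xs <- matrix(rnorm(n * 3), n, 3) + 3 * y
  Xw <- matrix(rnorm(n * 5), n, 5) - 2 * y
  model <- train_fused_model(Xs, Xw, y, kernel_config(0.6, 0.2, 0.1, 50))
  expect_identical(predict(model, Xs, Xw), y)       # separable training set
  expect_length(predict(model, Xs[1, , drop = FALSE], Xw[1, , drop = FALSE]), 1)
  # duplicating a test row cannot change any prediction
  p1 <- predict(model, Xs[1:4, ], Xw[1:4, ])
  p2 <- predict(model, Xs[c(1:4, 2), ], Xw[c(1:4, 2), ])
  expect_identical(p2[1:4], p1)
  expect_identical(p2[5], p1[2])
  expect_error(predict(model, Xs[, 1:2], Xw), "width")
  expect_error(predict(model, Xs, Xw[, 1:3]), "width")
})

test_that("with mu = 1 the fused pipeline is the spectral-only SVM bit-for-bit", {
  set.seed(15)
  n <- 32
  y <- rep(0:3, each = n / 4)
  Xs <- matrix(rnorm(n * 4), n, 4) + y
  Xw <- matrix(rnorm(n * 6), n, 6)
  cfgk <- kernel_config(1, 0.3, 0.2, 10)
  fused <- train_fused_model(Xs, Xw, y, cfgk)
  Zs <- mycohsi:::apply_scaler(Xs, mycohsi:::fit_scaler(Xs))
  direct <- fit_fused_svm(rbf_gram(Zs, gamma = 0.3), y, C = 10)
  expect_identical(kernlab::alpha(fused$fit$ksvm), kernlab::alpha(direct$ksvm))
  expect_identical(kernlab::b(fused$fit$ksvm), kernlab::b(direct$ksvm))
  expect_identical(predict(fused, Xs, Xw),
                   as.integer(predict_fused_svm(direct, rbf_gram(Zs, Zs, 0.3))))
})

test_that("grid search selects the informative modality and honors its contract", {
  # planted modality: spectra carry the classes, image features are noise
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 60
    y <- rep(0:3, each = n / 4)
    Xs <- matrix(rnorm(n * 3, sd = 0.4), n, 3) + y
    Xw <- matrix(rnorm(n * 8), n, 8)
    gs <- grid_search_fused(Xs, Xw, y, mu_grid = seq(0, 1, 0.2),
                            C_grid = c(1, 10),
                            gamma_s_grid = "scale", gamma_w_grid = "scale",
                            cv_folds = 5, seed = s)
    hits <- hits + (gs$best$mu >= 0.8)
  }
  expect_gte(hits, 8)

  # the CV table covers the full grid; fused CV >= single-modality CV at
  # matched grids because the endpoints are in the grid
  set.seed(30)
  n <- 40
  y <- rep(0:3, each = 10)
  Xs <- matrix(rnorm(n * 3, sd = 0.8), n, 3) + (y %% 2) * 2
  Xw <- matrix(rnorm(n * 3, sd = 0.8), n, 3) + (y %/% 2) * 2
  gs <- grid_search_fused(Xs, Xw, y, mu_grid = seq(0, 1, 0.25),
                          C_grid = c(1, 10), gamma_s_grid = c(0.05, 0.2),
                          gamma_w_grid = c(0.05, 0.2), cv_folds = 4, seed = 2)
  expect_identical(nrow(gs$cv_table), 5L * 2L * 2L * 2L)
  spec_only <- max(gs$cv_table$accuracy[gs$cv_table$mu == 1])
  img_only <- max(gs$cv_table$accuracy[gs$cv_table$mu == 0])
  expect_gte(gs$best_accuracy, max(spec_only, img_only))

  # mu pinned to 1 reduces to single-modality model selection
  g1 <- grid_search_single(Xs, y, C_grid = c(1, 10), gamma_grid = c(0.05, 0.2),
                           cv_folds = 4, seed = 2)
  expect_equal(g1$best_accuracy, spec_only)

  expect_error(grid_search_fused(Xs, Xw, y, mu_grid = 0.5, C_grid = 1,
                                 cv_folds = 15, seed = 1), "fewer folds")
})
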