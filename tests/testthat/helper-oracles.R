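# Shared fixtures and independent brute-force oracles.

# Small flat-reference scene: raw counts equal the transmittance field.
flat_scene <- function(..., noise_sd = 0) {
  scene_config(image_height = 48, image_width = 48, n_bands = 24,
               filaments_per_image = c(1, 3),
               noise_sd = noise_sd, baseline_drift_sd = 0, scatter_slope_sd = 0,
               white_level = 1, dark_level = 0, reference_shading = FALSE, ...)
}

# Realistic small scene (shading, noise, distortions on).
small_scene <- function(...) {
  scene_config(image_height = 48, image_width = 48, n_bands = 24,
               filaments_per_image = c(1, 3), ...)
}

# Reduced-scale analogue of the imaging study used for multi-seed
# experiments (smaller frames/axis, fewer filaments; same physics).
desk_scene <- function(...) {
  scene_config(image_height = 64, image_width = 64, n_bands = 120,
               filaments_per_image = c(2, 4), ...)
}

# SPA oracle: rebuilds the orthogonal complement of the selected original
# columns explicitly at every step (QR), then maximizes the projected norm.
spa_oracle <- function(X, start, n_select) {
  sel <- as.integer(start)
  for (n in seq_len(n_select - 1)) {
    Q <- qr.Q(qr(X[, sel, drop = FALSE]))
    P <- diag(nrow(X)) - tcrossprod(Q)
    norms <- apply(X, 2, function(col) sum((P %*% col)^2))
    norms[sel] <- -Inf
    sel <- c(sel, which.max(norms))
  }
  sel
}

# Kennard-Stone oracle: recomputes all pairwise distances at every step.
ks_oracle <- function(X, n_select) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  pair <- which(D == max(D), arr.ind = TRUE)
  pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE]
  pair <- pair[order(pair[, 1], pair[, 2])[1], ]
  sel <- c(pair[[1]], pair[[2]])
  while (length(sel) < n_select) {
    cand <- setdiff(seq_len(n), sel)
    score <- vapply(cand, function(i) min(sqrt(colSums((t(X[sel, , drop = FALSE]) - X[i, ])^2))),
                    numeric(1))
    sel <- c(sel, cand[which.max(score)])
  }
  sel
}

# Savitzky-Golay oracle: explicit per-window polynomial least-squares refit.
sg_oracle <- function(x, window, polyorder) {
  n <- length(x)
  h <- (window - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- min(max(1, i - h), n - window + 1)
    idx <- lo:(lo + window - 1)
    df <- data.frame(t = idx - i, y = x[idx])
    fit <- if (polyorder == 0) lm(y ~ 1, data = df) else
      lm(y ~ poly(t, degree = polyorder, raw = TRUE), data = df)
    out[i] <- unname(predict(fit, data.frame(t = 0)))
  }
  out
}

# Naive double-loop bilinear resize under the align-corners convention.
naive_bilinear <- function(img, oh, ow) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) {
    for (j in seq_len(ow)) {
      sr <- if (oh == 1) (h + 1) / 2 else 1 + (i - 1) * (h - 1) / (oh - 1)
      sc <- if (ow == 1) (w + 1) / 2 else 1 + (j - 1) * (w - 1) / (ow - 1)
      r0 <- min(floor(sr), h - 1); c0 <- min(floor(sc), w - 1)
      fr <- sr - r0; fc <- sc - c0
      out[i, j] <- img[r0, c0] * (1 - fr) * (1 - fc) +
        img[r0 + 1, c0] * fr * (1 - fc) +
        img[r0, c0 + 1] * (1 - fr) * fc +
        img[r0 + 1, c0 + 1] * fr * fc
    }
  }
  out
}

# Naive direct convolution + ReLU (valid padding) for backend verification.
naive_conv_relu <- function(x, W, k, stride) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  oh <- (h - k) %/% stride + 1; ow <- (w - k) %/% stride + 1
  cout <- ncol(W)
  out <- array(0, c(oh, ow, cout))
  for (i in seq_len(oh)) {
    for (j in seq_len(ow)) {
      patch <- x[((i - 1) * stride + 1):((i - 1) * stride + k),
                 ((j - 1) * stride + 1):((j - 1) * stride + k), , drop = FALSE]
      out[i, j, ] <- pmax(as.vector(patch) %*% W, 0)
    }
  }
  out
}
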