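# Fixtures and independent brute-force oracles used across the suite.
# Everything is generated in code; nothing is read from disk.

# -- geometric fixtures ------------------------------------------------------

disc_image <- function(n = 64L, center = c(n / 2, n / 2), R = 12,
                       lo = -900, hi = 400) {
  co <- expand.grid(x = seq_len(n) - 0.5, y = seq_len(n) - 0.5)
  inside <- (co$x - center[1])^2 + (co$y - center[2])^2 <= R^2
  img <- array(lo, c(n, n, 1L))
  img[cbind(ceiling(co$x[inside]), ceiling(co$y[inside]), 1L)] <- hi
  list(img = img, disc = array(inside, c(n, n, 1L)))
}

disc_mask2d <- function(n, R, center = c(n / 2 + 0.5, n / 2 + 0.5)) {
  co <- expand.grid(i = 1:n, j = 1:n)
  m <- matrix(FALSE, n, n)
  sel <- (co$i - center[1])^2 + (co$j - center[2])^2 <= R^2
  m[as.matrix(co[sel, ])] <- TRUE
  m
}

sphere_volume <- function(r = 5, pad = 4L, spacing = 1, soft = 0) {
  n <- as.integer(ceiling(2 * (r + pad) / spacing))
  ctr <- rep(n * spacing / 2, 3)
  spec <- phantom_spec(rep(n, 3L), rep(spacing, 3L),
                       nodules = list(nodule_spec(ctr, r, edge_softness = soft)),
                       seed = 1L)
  render_phantom(spec)
}

tube_volume <- function(r = 2, len = 40L, soft = 0) {
  spec <- phantom_spec(c(16L, 16L, len), c(1, 1, 1),
                       vessels = list(vessel_spec(rbind(c(8, 8, 1), c(8, 8, len - 1)),
                                                  r, edge_softness = soft)),
                       seed = 1L)
  render_phantom(spec)
}

juxta_volume <- function(seed = 1L, noise = 15, bias = 0.03) {
  nod <- nodule_spec(c(16, 16, 14), 6, "solid")
  ves <- vessel_spec(rbind(c(1, 23, 14), c(43, 23, 14)), 2)
  spec <- phantom_spec(c(44L, 44L, 28L), noise_sigma = noise,
                       bias_amplitude = bias, seed = seed)
  juxtavascular_phantom(nod, ves, spec)
}

# -- independent oracles -----------------------------------------------------

# Textbook fuzzy c-means, written directly from the alternating updates.
fcm_oracle <- function(x, k, m = 2, iters = 100L, centers) {
  x <- as.matrix(x)
  for (it in seq_len(iters)) {
    d2 <- sapply(seq_len(k), function(j) rowSums(sweep(x, 2L, centers[j, ], `-`)^2))
    d2 <- pmax(d2, 1e-12)
    u <- (1 / d2)^(1 / (m - 1))
    u <- u / rowSums(u)
    centers <- t(sapply(seq_len(k), function(j)
      colSums(u[, j]^m * x) / sum(u[, j]^m)))
  }
  list(membership = u, centers = centers)
}

# Brute-force Gaussian-windowed interior/exterior means (double loop).
region_fitting_oracle <- function(I, phi, sigma_vox, epsilon, truncate = 3) {
  d <- dim(I)
  H <- 0.5 * (1 + (2 / pi) * atan(phi / epsilon))
  r <- max(1L, as.integer(ceiling(truncate * sigma_vox)))
  f1 <- array(0, d); f2 <- array(0, d)
  k1d <- exp(-((-r:r)^2) / (2 * sigma_vox^2)); k1d <- k1d / sum(k1d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    n1 <- 0; d1 <- 0; n2 <- 0; d2 <- 0; nI <- 0; dI <- 0
    for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      w <- k1d[di + r + 1] * k1d[dj + r + 1] * k1d[dk + r + 1]
      h <- H[ii, jj, kk]; v <- I[ii, jj, kk]
      n1 <- n1 + w * h * v; d1 <- d1 + w * h
      n2 <- n2 + w * (1 - h) * v; d2 <- d2 + w * (1 - h)
      nI <- nI + w * v; dI <- dI + w
    }
    f1[i, j, k] <- if (d1 < 1e-8) nI / dI else n1 / d1
    f2[i, j, k] <- if (d2 < 1e-8) nI / dI else n2 / d2
  }
  list(f1 = f1, f2 = f2)
}

# Direct pair-counting GLCM features.
glcm_oracle <- function(img, mask, levels,
                        offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
  vals <- img[mask]
  rng <- range(vals)
  qz <- function(v) if (diff(rng) == 0) 1L else
    min(levels, 1L + floor((v - rng[1]) / diff(rng) * levels))
  P <- matrix(0, levels, levels)
  used <- 0L
  for (off in offsets) {
    Po <- matrix(0, levels, levels)
    for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
      i2 <- i + off[1]; j2 <- j + off[2]
      if (i2 < 1 || i2 > nrow(img) || j2 < 1 || j2 > ncol(img)) next
      if (!mask[i, j] || !mask[i2, j2]) next
      a <- qz(img[i, j]); b <- qz(img[i2, j2])
      Po[a, b] <- Po[a, b] + 1
      Po[b, a] <- Po[b, a] + 1
    }
    if (sum(Po) > 0) {
      P <- P + Po / sum(Po)
      used <- used + 1L
    }
  }
  P <- P / used
  ij <- outer(seq_len(levels), seq_len(levels), `-`)
  list(energy = sum(P^2), contrast = sum(ij^2 * P),
       entropy = sum(ifelse(P > 0, -P * log(P), 0)),
       idm = sum(P / (1 + ij^2)))
}

# Grayscale erosion/dilation by direct min/max loops.
opening_oracle <- function(a, radius) {
  d <- dim(a)
  pass <- function(x, fun, pad) {
    out <- array(pad, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      lo <- pmax(c(i, j, k) - radius, 1L)
      hi <- pmin(c(i, j, k) + radius, d)
      out[i, j, k] <- fun(x[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
    }
    out
  }
  pass(pass(a, min, Inf), max, -Inf)
}

# Dense multivariate normal density, written independently (solve + det).
mvn_dens <- function(x, mu, Sigma) {
  d <- length(mu)
  xc <- sweep(as.matrix(x), 2L, mu, `-`)
  quad <- rowSums((xc %*% solve(Sigma)) * xc)
  exp(-0.5 * quad) / sqrt((2 * pi)^d * det(Sigma))
}

# Small cached classifier so pipeline plumbing tests do not retrain.
.model_cache <- new.env(parent = emptyenv())
small_model <- function() {
  if (is.null(.model_cache$m)) {
    tr <- make_training_set(12L, 36L, seed = 7L)
    .model_cache$m <- train_default_model(tr, seed = 7L, k = 3L,
                                          C_grid = c(0.5, 2), gamma_grid = c(0.125, 0.5))
  }
  .model_cache$m
}
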