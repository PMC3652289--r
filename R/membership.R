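# Per-voxel fuzzy nodule membership: principal curvatures of the
# iso-intensity surfaces, the volumetric shape index, fuzzy c-means
# clustering of (position, shape index, intensity) samples, and grayscale
# (fuzzy) morphological opening for denoising.
#
# Sign convention: iso-surface curvatures are signed so that bright convex
# structures have negative curvatures, with ordering k1 >= k2. Under this
# convention the shape index maps bright spheres to 1 and bright tubes to
# 0.75 (the unique convention consistent with those anchor values).

#' Principal curvatures of the iso-intensity surfaces
#'
#' Curvatures are computed from the gradient and Hessian of the
#' Gaussian-smoothed volume: twice the mean curvature is the divergence of
#' the unit gradient, and the Gaussian curvature uses the Hessian adjugate.
#' Voxels with (near-)zero gradient carry no iso-surface and are flagged
#' undefined rather than propagating NaNs.
#'
#' @param volume a `volume_handle`, `labeled_volume` or array.
#' @param scale Gaussian smoothing scale (mm), > 0.
#' @return a `curvature_field`: arrays `k1 >= k2`, logical `undefined`, and
#'   the scale.
#' @export
principal_curvatures <- function(volume, scale = 1.5) {
  stopifnot(scale > 0)
  if (!inherits(volume, "volume_handle")) volume <- as_volume(volume)
  sp <- volume$spacing
  s <- gauss_smooth(volume$intensity, scale, sp)
  g <- lapply(1:3, function(ax) grad_axis(s, ax, sp[ax]))
  H <- list()
  for (i in 1:3) for (j in i:3)
    H[[paste0(i, j)]] <- grad_axis(g[[i]], j, sp[j])
  gmag2 <- g[[1]]^2 + g[[2]]^2 + g[[3]]^2
  gmag <- sqrt(gmag2)
  undef <- gmag < max(1e-8, 1e-6 * max(gmag))
  gm <- pmax(gmag, 1e-12)
  trH <- H[["11"]] + H[["22"]] + H[["33"]]
  gHg <- g[[1]]^2 * H[["11"]] + g[[2]]^2 * H[["22"]] + g[[3]]^2 * H[["33"]] +
    2 * (g[[1]] * g[[2]] * H[["12"]] + g[[1]] * g[[3]] * H[["13"]] +
           g[[2]] * g[[3]] * H[["23"]])
  # adjugate (cofactor matrix) of the symmetric Hessian
  A11 <- H[["22"]] * H[["33"]] - H[["23"]]^2
  A22 <- H[["11"]] * H[["33"]] - H[["13"]]^2
  A33 <- H[["11"]] * H[["22"]] - H[["12"]]^2
  A12 <- H[["13"]] * H[["23"]] - H[["12"]] * H[["33"]]
  A13 <- H[["12"]] * H[["23"]] - H[["13"]] * H[["22"]]
  A23 <- H[["12"]] * H[["13"]] - H[["11"]] * H[["23"]]
  gAg <- g[[1]]^2 * A11 + g[[2]]^2 * A22 + g[[3]]^2 * A33 +
    2 * (g[[1]] * g[[2]] * A12 + g[[1]] * g[[3]] * A13 + g[[2]] * g[[3]] * A23)
  km <- 0.5 * (trH / gm - gHg / gm^3) # mean curvature of the iso-surface
  K <- gAg / gm^4                     # Gaussian curvature
  disc <- sqrt(pmax(km^2 - K, 0))
  k1 <- km + disc
  k2 <- km - disc
  k1[undef] <- 0
  k2[undef] <- 0
  structure(list(k1 = k1, k2 = k2, undefined = undef, scale = scale),
            class = "curvature_field")
}

#' Volumetric shape index
#'
#' `SI = 1/2 - (1/pi) * arctan((k1 + k2) / (k1 - k2))` with `k1 >= k2`.
#' Bright spheres (equal negative curvatures, taken as the limit) map to 1,
#' bright tubes (one zero, one negative curvature) to 0.75, saddles to 0.5.
#' Voxels with `k1 = k2 = 0` (and those undefined upstream) are flagged.
#'
#' @param curv a `curvature_field`, or a numeric of the two curvatures
#'   `c(k1, k2)` for scalar evaluation.
#' @return a `shape_index_field` (arrays `SI` in \[0, 1\] and `undefined`),
#'   or a scalar when given two curvatures.
#' @export
shape_index <- function(curv) {
  if (is.numeric(curv) && length(curv) == 2L) {
    curv <- structure(list(k1 = array(max(curv), c(1, 1, 1)),
                           k2 = array(min(curv), c(1, 1, 1)),
                           undefined = array(FALSE, c(1, 1, 1))),
                      class = "curvature_field")
    return(as.vector(shape_index(curv)$SI))
  }
  stopifnot(inherits(curv, "curvature_field"))
  k1 <- curv$k1; k2 <- curv$k2
  if (any(k1 < k2)) stop("curvature ordering k1 >= k2 violated", call. = FALSE)
  num <- k1 + k2
  den <- k1 - k2
  SI <- 0.5 - atan2(num, den) / pi # den >= 0, so atan2 == arctan(num/den) incl. limits
  undef <- curv$undefined | (den == 0 & num == 0)
  SI[undef] <- NA_real_
  SI <- pmin(pmax(SI, 0), 1)
  structure(list(SI = SI, undefined = undef), class = "shape_index_field")
}

## --- Fuzzy c-means ---------------------------------------------------------

# Seeded k-means++-style draw of initial centres from the sample rows.
seed_centers <- function(x, k, seed) {
  with_seed(seed, {
    n <- nrow(x)
    idx <- sample.int(n, 1L)
    for (j in seq_len(k - 1L)) {
      d2 <- rep(Inf, n)
      for (i in idx) d2 <- pmin(d2, rowSums(sweep(x, 2L, x[i, ], `-`)^2))
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
      idx <- c(idx, sample.int(n, 1L, prob = p))
    }
    x[idx, , drop = FALSE]
  })
}

#' Fuzzy c-means clustering of membership samples
#'
#' Samples are standardized feature-wise (zero mean, unit variance) and
#' clustered by fuzzy c-means with fuzzifier `m`; the nodule cluster is the
#' one whose centre has the highest combined (standardized) shape index and
#' intensity. Initial centres come from a seeded k-means++-style draw.
#'
#' @param samples data frame or matrix; columns named `SI` and `I` identify
#'   the shape-index and intensity features (the last two columns otherwise).
#' @param clusters number of clusters, >= 2.
#' @param m fuzzifier, > 1.
#' @param tol convergence tolerance on centre movement.
#' @param max_iter iteration cap.
#' @param seed RNG seed for the initial centres.
#' @return a `fuzzy_fit`: per-sample membership matrix (rows sum to 1),
#'   centres (standardized space), the nodule cluster index and the scaling.
#' @export
fuzzy_cluster <- function(samples, clusters = 2L, m = 2, tol = 1e-6,
                          max_iter = 200L, seed = 1L) {
  stopifnot(clusters >= 2L, m > 1)
  x <- as.matrix(samples)
  if (nrow(x) < clusters)
    stop("fewer samples than clusters", call. = FALSE)
  mu <- colMeans(x)
  sd_ <- apply(x, 2L, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  xs <- sweep(sweep(x, 2L, mu, `-`), 2L, sd_, `/`)
  init <- seed_centers(xs, clusters, seed)
  # tiny seeded jitter so coincident initial centres cannot collapse
  init <- init + with_seed(seed + 1L, matrix(stats::rnorm(length(init), 0, 1e-6),
                                             nrow(init)))
  fit <- e1071::cmeans(xs, centers = init, m = m, iter.max = max_iter,
                       method = "cmeans")
  cn <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  si_col <- if ("SI" %in% cn) which(cn == "SI") else ncol(x) - 1L
  i_col <- if ("I" %in% cn) which(cn == "I") else ncol(x)
  score <- fit$centers[, si_col] + fit$centers[, i_col]
  structure(list(membership = fit$membership, centers = fit$centers,
                 nodule_cluster = which.max(score),
                 scaling = list(mean = mu, sd = sd_)),
            class = "fuzzy_fit")
}

#' Build the per-voxel fuzzy nodule membership map
#'
#' Samples voxels (by default those above a contrast threshold between the
#' volume minimum and maximum), forms (x, y\[, z\], SI, I) feature vectors,
#' clusters them with [fuzzy_cluster()] and rasterizes the nodule cluster's
#' membership over the grid (unsampled voxels get 0). Undefined shape-index
#' voxels enter with the neutral value 0.5.
#'
#' @param volume `volume_handle`, `labeled_volume` or array.
#' @param mask optional logical array choosing the samples directly.
#' @param sample_quantile fraction of the intensity range above the minimum
#'   used as sampling threshold when `mask` is absent.
#' @param clusters,m,seed passed to [fuzzy_cluster()].
#' @param curvature_scale smoothing scale (mm) for [principal_curvatures()].
#' @param opening_radius grayscale opening radius (voxels; 0 = none).
#' @return a `membership_map`: array `u` in \[0, 1\], fuzzifier, cluster
#'   count, nodule cluster id and the underlying fit.
#' @export
membership_map <- function(volume, mask = NULL, sample_quantile = 0.25,
                           clusters = 2L, m = 2, seed = 1L,
                           curvature_scale = 1.5, opening_radius = 0L) {
  if (!inherits(volume, "volume_handle")) volume <- as_volume(volume)
  I <- volume$intensity
  dm <- dim(I)
  si <- shape_index(principal_curvatures(volume, curvature_scale))
  SI <- si$SI
  SI[si$undefined] <- 0.5
  if (is.null(mask)) {
    rng <- range(I)
    mask <- I > rng[1] + sample_quantile * diff(rng)
  } else mask <- as_vol3d(mask) != 0
  idx <- which(mask)
  if (length(idx) < clusters)
    stop("sampling mask selects fewer voxels than clusters", call. = FALSE)
  pos <- arrayInd(idx, dm)
  feats <- cbind(x = pos[, 1], y = pos[, 2], SI = SI[idx], I = I[idx])
  if (dm[3] > 1L) feats <- cbind(feats[, 1:2], z = pos[, 3], feats[, 3:4])
  fit <- fuzzy_cluster(feats, clusters = clusters, m = m, seed = seed)
  u <- array(0, dm)
  u[idx] <- fit$membership[, fit$nodule_cluster]
  out <- structure(list(u = u, m = m, clusters = clusters,
                        nodule_cluster = fit$nodule_cluster, fit = fit),
                   class = "membership_map")
  if (opening_radius >= 1L) out <- fuzzy_open(out, opening_radius)
  out
}

#' Grayscale (fuzzy) morphological opening of a membership map
#'
#' Erosion (minimum) followed by dilation (maximum) over a cubic structuring
#' element of half-width `radius`; anti-extensive, removes speckle smaller
#' than the element while leaving the membership range intact.
#'
#' @param u a `membership_map` or numeric array.
#' @param radius structuring-element half-width in voxels, >= 1.
#' @return same type as the input.
#' @export
fuzzy_open <- function(u, radius = 1L) {
  stopifnot(radius >= 1L)
  arr <- if (inherits(u, "membership_map")) u$u else as_vol3d(u)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius, dz = -radius:radius)
  dm <- dim(arr)
  if (dm[3] == 1L) offs <- offs[offs$dz == 0L, ]
  er <- array(Inf, dm)
  for (r in seq_len(nrow(offs)))
    er <- pmin(er, shift_arr(arr, as.integer(offs[r, ]), pad = Inf))
  op <- array(-Inf, dm)
  for (r in seq_len(nrow(offs)))
    op <- pmax(op, shift_arr(er, as.integer(offs[r, ]), pad = -Inf))
  if (inherits(u, "membership_map")) {
    u$u <- op
    u
  } else op
}
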