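# The fuzzy integrated active contour model (FIACM): an energy combining an
# edge term (smoothed Dirac * posterior-probability stop function * |grad
# phi|) with membership-weighted region-scalable fitting terms
#   lambda1 * u^m (I - f1)^2 inside  +  lambda2 * (1-u)^m (I - f2)^2 outside,
# where f1/f2 are kernel-weighted local intensity means. The gradient flow is
# advanced with an explicit step for the region force and a semi-implicit
# additive-operator-splitting (AOS) step, via vectorized Thomas solves per
# axis, for the edge/curvature regularization.
#
# Convention: interior = {phi > 0}, exterior = {phi < 0}.

#' Smoothed Heaviside and Dirac pair
#'
#' `H_eps(z) = 1/2 (1 + (2/pi) arctan(z/eps))` with derivative
#' `delta_eps(z) = eps / (pi (eps^2 + z^2))` — the global-support pair
#' standard for region-scalable fitting models.
#'
#' @param z numeric (any shape).
#' @param epsilon smoothing width, > 0.
#' @export
smoothed_heaviside <- function(z, epsilon = 1.5) {
  stopifnot(epsilon > 0)
  0.5 * (1 + (2 / pi) * atan(z / epsilon))
}

#' @rdname smoothed_heaviside
#' @export
smoothed_dirac <- function(z, epsilon = 1.5) {
  stopifnot(epsilon > 0)
  epsilon / (pi * (epsilon^2 + z^2))
}

#' FIACM parameter bundle
#'
#' @param mu edge-term weight (>= 0).
#' @param lambda1,lambda2 interior/exterior region-term weights (>= 0).
#' @param m membership exponent.
#' @param epsilon Heaviside/Dirac smoothing width (grid units).
#' @param tau time step; the region force is normalized to unit scale, so
#'   tau is the interface speed in grid units per iteration.
#' @param max_iter iteration cap.
#' @param conv_tol convergence threshold on the fraction of sign-changed
#'   voxels between iterations.
#' @export
fiacm_params <- function(mu = 0.2, lambda1 = 1, lambda2 = 1, m = 2,
                         epsilon = 1.5, tau = 1, max_iter = 300L,
                         conv_tol = 1e-4) {
  stopifnot(mu >= 0, lambda1 >= 0, lambda2 >= 0, epsilon > 0, tau > 0,
            max_iter >= 1L, conv_tol >= 0)
  structure(list(mu = mu, lambda1 = lambda1, lambda2 = lambda2, m = m,
                 epsilon = epsilon, tau = tau, max_iter = as.integer(max_iter),
                 conv_tol = conv_tol), class = "fiacm_params")
}

#' Local-fitting kernel specification
#'
#' Gaussian kernel `B` with scale `sigma` (mm), discretely normalized over
#' its truncated support.
#' @param sigma scale (mm), > 0.
#' @param n dimensionality (3, or 2 for single-slice volumes).
#' @param truncate support radius in sigmas.
#' @export
kernel_spec <- function(sigma, n = 3L, truncate = 3) {
  stopifnot(sigma > 0, truncate > 0)
  structure(list(sigma = sigma, n = as.integer(n), truncate = truncate),
            class = "kernel_spec")
}

#' Edge-stop parameter bundle (gradient-magnitude thresholds)
#' @param a lower threshold (g = 1 at or below).
#' @param b upper threshold (g = 0 above), > a.
#' @param smoothing Gaussian scale (mm) for the gradient of the intensity.
#' @export
edge_stop_params <- function(a, b, smoothing = 1) {
  if (!(a >= 0 && a < b)) stop("need 0 <= a < b", call. = FALSE)
  structure(list(a = a, b = b, smoothing = smoothing), class = "edge_stop_params")
}

#' Posterior-probability estimation of the edge-stop thresholds
#'
#' Gaussian-gradient magnitudes of the volume are modelled as a two-component
#' Gaussian mixture (homogeneous = lower mean, edge = higher mean) fitted by
#' EM; `a` is the smallest magnitude whose posterior edge probability reaches
#' `p_lo` and `b` the smallest reaching `p_hi`, located on a dense grid
#' between the two component means.
#'
#' @param volume `volume_handle`, `labeled_volume` or array.
#' @param smoothing Gaussian scale (mm) for the gradient.
#' @param p_lo,p_hi posterior probabilities, `0 < p_lo < p_hi < 1`.
#' @param seed RNG seed for subsampling the magnitudes.
#' @param max_sample subsample size for the EM fit.
#' @return an `edge_stop_params`.
#' @export
estimate_edge_thresholds <- function(volume, smoothing = 1, p_lo = 0.6,
                                     p_hi = 0.95, seed = 1L, max_sample = 5000L) {
  if (!(p_lo > 0 && p_lo < p_hi && p_hi < 1))
    stop("need 0 < p_lo < p_hi < 1", call. = FALSE)
  if (!inherits(volume, "volume_handle")) volume <- as_volume(volume)
  gm <- gradient_magnitude(volume, smoothing)
  if (diff(range(volume$intensity)) == 0 || max(gm) == 0)
    stop("degenerate (constant) volume: edge thresholds undefined", call. = FALSE)
  t_all <- as.vector(gm)
  if (length(t_all) > max_sample)
    t_all <- with_seed(seed, sample(t_all, max_sample))
  fit_edge_gmm(t_all, p_lo, p_hi, smoothing)
}

# Shared with tests: 2-component 1-D EM (via mclust) + posterior crossings.
fit_edge_gmm <- function(t_sample, p_lo, p_hi, smoothing = 1) {
  fit <- Mclust(t_sample, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) fit <- Mclust(t_sample, G = 2, modelNames = "E", verbose = FALSE)
  if (!is.null(fit)) {
    mu <- fit$parameters$mean
    sd_ <- sqrt(fit$parameters$variance$sigmasq)
    pro <- fit$parameters$pro
  } else {
    # piecewise-degenerate magnitudes (e.g. exactly-constant regions): fall
    # back to a 2-class moment split so thresholds remain defined
    cl <- stats::kmeans(t_sample, centers = range(t_sample))$cluster
    mu <- tapply(t_sample, cl, mean)
    sd_ <- tapply(t_sample, cl, stats::sd)
    pro <- as.numeric(table(cl)) / length(t_sample)
  }
  sd_[!is.finite(sd_) | sd_ == 0] <- 1e-3 * max(diff(range(t_sample)), 1e-6)
  if (length(sd_) == 1L) sd_ <- rep(sd_, 2L)
  edge <- which.max(mu) # label symmetry: defined by the larger mean
  hom <- 3L - edge
  post_edge <- function(t) {
    de <- pro[edge] * stats::dnorm(t, mu[edge], sd_[edge])
    dh <- pro[hom] * stats::dnorm(t, mu[hom], sd_[hom])
    de / (de + dh)
  }
  grid <- seq(min(mu), max(mu), length.out = 4096L)
  p <- post_edge(grid)
  first_at <- function(level, fallback) {
    i <- which(p >= level)
    if (length(i)) grid[min(i)] else fallback
  }
  a <- first_at(p_lo, min(mu))
  b <- first_at(p_hi, max(mu))
  if (a >= b) a <- b - 1e-6 * max(1, b) # guarantee a < b
  edge_stop_params(max(a, 0), b, smoothing)
}

# Gaussian-gradient magnitude of a volume (mm-aware).
gradient_magnitude <- function(volume, smoothing) {
  sp <- volume$spacing
  s <- gauss_smooth(volume$intensity, smoothing, sp)
  sqrt(grad_axis(s, 1, sp[1])^2 + grad_axis(s, 2, sp[2])^2 +
         grad_axis(s, 3, sp[3])^2)
}

#' Piecewise-quadratic edge-stopping function
#'
#' `g(t) = 1` for `t <= a`; `1 - 2((t-a)/(b-a))^2` on `(a, (a+b)/2]`;
#' `2((b-t)/(b-a))^2` on `((a+b)/2, b]`; `0` for `t > b`. Continuous and
#' monotone non-increasing.
#'
#' @param t gradient magnitudes (vectorized).
#' @param params an `edge_stop_params`.
#' @export
edge_stop <- function(t, params) {
  stopifnot(inherits(params, "edge_stop_params"))
  a <- params$a; b <- params$b
  w <- (t - a) / (b - a)
  g <- ifelse(t <= a, 1,
              ifelse(t <= (a + b) / 2, 1 - 2 * w^2,
                     ifelse(t <= b, 2 * ((b - t) / (b - a))^2, 0)))
  g
}

#' Membership-controlled kernel scale
#'
#' `sigma = sigma_base * (0.5 + mean(u))` over the window, clamped to
#' `[0.5, 1.5] * sigma_base`: higher average membership widens the local
#' fitting window.
#'
#' @param u `membership_map` or array.
#' @param window optional logical array selecting the region (whole grid by
#'   default).
#' @param sigma_base base scale (mm), > 0.
#' @return a `kernel_spec`.
#' @export
kernel_sigma_from_membership <- function(u, window = NULL, sigma_base = 3) {
  stopifnot(sigma_base > 0)
  arr <- if (inherits(u, "membership_map")) u$u else as_vol3d(u)
  vals <- if (is.null(window)) arr else arr[as_vol3d(window) != 0]
  if (length(vals) == 0L) stop("empty window", call. = FALSE)
  sigma <- sigma_base * (0.5 + mean(vals))
  sigma <- min(max(sigma, 0.5 * sigma_base), 1.5 * sigma_base)
  kernel_spec(sigma, n = if (length(dim(arr)) == 3L && dim(arr)[3] > 1L) 3L else 2L)
}

#' Level-set state constructor
#' @param phi signed function array (zero level = contour).
#' @export
level_set_state <- function(phi, iterations = 0L, converged = FALSE) {
  phi <- as_vol3d(phi)
  if (!all(is.finite(phi))) stop("phi must be finite", call. = FALSE)
  structure(list(phi = phi, iterations = as.integer(iterations),
                 converged = converged), class = "level_set_state")
}

#' Adaptive local-threshold initialization of the contour
#'
#' Voxels brighter than their windowed local mean plus `offset` form the
#' initial interior; the level set starts as +c inside / -c outside (c = 2
#' grid units).
#'
#' @param volume `volume_handle`, `labeled_volume` or array.
#' @param window box window edge length (voxels, >= 3).
#' @param offset additive threshold above the local mean.
#' @param fill fill enclosed cavities of the thresholded mask (the cores of
#'   wide blobs sit below their local mean and would start as holes).
#' @return a `level_set_state`.
#' @export
initialize_contour <- function(volume, window = 9L, offset = 40, fill = TRUE) {
  stopifnot(window >= 3L)
  if (!inherits(volume, "volume_handle")) volume <- as_volume(volume)
  I <- volume$intensity
  k <- rep(1, window)
  num <- I
  den <- array(1, dim(I))
  for (ax in 1:3) {
    if (dim(I)[ax] == 1L) next
    num <- conv_axis(num, k, ax)
    den <- conv_axis(den, k, ax)
  }
  localmean <- num / den
  inside <- I > localmean + offset
  if (fill && any(inside)) inside <- fill_holes(inside)
  level_set_state(ifelse(inside, 2, -2))
}

#' Region-scalable fitting values f1/f2
#'
#' Kernel-weighted local interior/exterior intensity means:
#' `f1 = B * (H(phi) I) / B * H(phi)` and the complementary `f2`. Where a
#' window holds (almost) no interior or exterior mass (convolved mass below
#' 1e-8) the unmasked local mean is substituted.
#'
#' @param volume `volume_handle`, `labeled_volume` or array.
#' @param state `level_set_state`.
#' @param kernel `kernel_spec`.
#' @param epsilon Heaviside smoothing width.
#' @return a `region_fitting`: arrays `f1`, `f2`.
#' @export
region_fitting <- function(volume, state, kernel, epsilon = 1.5) {
  if (!inherits(volume, "volume_handle")) volume <- as_volume(volume)
  I <- volume$intensity
  sig <- kernel$sigma / volume$spacing
  H <- smoothed_heaviside(state$phi, epsilon)
  conv <- function(a) gauss_conv_raw(a, sig, kernel$truncate)
  cI <- conv(I)
  c1 <- conv(array(1, dim(I)))
  localmean <- cI / c1
  nH <- conv(H * I); dH <- conv(H)
  nE <- cI - nH; dE <- c1 - dH
  f1 <- ifelse(dH < 1e-8, localmean, nH / pmax(dH, 1e-8))
  f2 <- ifelse(dE < 1e-8, localmean, nE / pmax(dE, 1e-8))
  structure(list(f1 = f1, f2 = f2), class = "region_fitting")
}

# One AOS half: solve (I - s * d/dx (D d/dx)) x = rhs along `axis`, Neumann
# ends, vectorized Thomas algorithm across all grid lines at once.
aos_solve_axis <- function(rhs, D, s, axis) {
  d <- dim(rhs)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  R <- aperm(rhs, perm); dim(R) <- c(n, prod(d[-axis]))
  Dv <- aperm(D, perm); dim(Dv) <- c(n, prod(d[-axis]))
  Dh <- 0.5 * (Dv[-n, , drop = FALSE] + Dv[-1L, , drop = FALSE]) # half points
  m <- ncol(R)
  lo <- rbind(0, -s * Dh)                 # sub-diagonal, rows 2..n
  up <- rbind(-s * Dh, 0)                 # super-diagonal, rows 1..n-1
  dg <- 1 - lo - up                        # diagonal (row sums keep constants)
  cp <- matrix(0, n, m); dp <- matrix(0, n, m)
  cp[1L, ] <- up[1L, ] / dg[1L, ]
  dp[1L, ] <- R[1L, ] / dg[1L, ]
  if (n > 1L) for (i in 2:n) {
    den <- dg[i, ] - lo[i, ] * cp[i - 1L, ]
    cp[i, ] <- up[i, ] / den
    dp[i, ] <- (R[i, ] - lo[i, ] * dp[i - 1L, ]) / den
  }
  X <- dp
  if (n > 1L) for (i in (n - 1L):1L) X[i, ] <- dp[i, ] - cp[i, ] * X[i + 1L, ]
  dim(X) <- d[perm]
  aperm(X, order(perm))
}

#' Evolve the FIACM level set
#'
#' Each iteration recomputes the region-scalable fitting pair, applies the
#' membership-weighted region force explicitly, and advances the
#' edge/curvature regularization semi-implicitly by AOS with lagged scalar
#' diffusivity `mu * g * delta_eps(phi) / |grad phi|`; `g` is the edge-stop
#' function evaluated once on the Gaussian-gradient magnitude of the
#' intensity. `phi` is clipped to \[-10, 10\] grid units to keep the Dirac
#' band active (no signed-distance reinitialization). Evolution stops when
#' the fraction of sign-changed voxels drops below `conv_tol` or at
#' `max_iter`.
#'
#' @param volume `volume_handle`, `labeled_volume` or array.
#' @param u `membership_map` or array in \[0, 1\].
#' @param init initial `level_set_state`.
#' @param params `fiacm_params`.
#' @param edge `edge_stop_params`.
#' @param kernel `kernel_spec`.
#' @param trace_energy record the discretized energy every 10 iterations in
#'   the returned state's `energy_trace`.
#' @return the final `level_set_state` (with `iterations` and `converged`).
#' @export
fiacm_evolve <- function(volume, u, init, params, edge, kernel,
                         trace_energy = FALSE) {
  if (!inherits(volume, "volume_handle")) volume <- as_volume(volume)
  I <- volume$intensity
  uarr <- if (inherits(u, "membership_map")) u$u else as_vol3d(u)
  phi <- init$phi
  stopifnot(identical(dim(I), dim(uarr)), identical(dim(I), dim(phi)))
  sp <- volume$spacing
  G <- edge_stop(gradient_magnitude(volume, edge$smoothing), edge)
  # Membership orientation: the interior residual is damped and the exterior
  # residual amplified where nodule membership is high, so that where the two
  # fitted means coincide (flat regions) the fuzzy term alone drives
  # high-membership voxels inside and low-membership voxels outside.
  w_in <- (1 - uarr)^params$m
  w_out <- uarr^params$m
  n_axes <- sum(dim(I) > 1L)
  it <- 0L
  converged <- FALSE
  check_every <- 10L # phi moves O(tau) per step, so single-step flips are rare
  phi_check <- phi
  energy_trace <- if (trace_energy)
    fiacm_energy(volume, u, init, params, edge, kernel) else NULL
  while (it < params$max_iter) {
    it <- it + 1L
    rf <- region_fitting(volume, level_set_state(phi), kernel, params$epsilon)
    delta <- smoothed_dirac(phi, params$epsilon)
    force <- -params$lambda1 * w_in * (I - rf$f1)^2 +
      params$lambda2 * w_out * (I - rf$f2)^2
    # region terms act on a squared-intensity scale; normalize by a robust
    # quantile of the force in the Dirac-active band and saturate, so the
    # interface advances O(tau) grid units per step everywhere it is driven
    band <- delta > 0.1 * max(delta)
    scale <- stats::quantile(abs(force[band]), 0.95, names = FALSE)
    if (scale > 0) force <- pmin(pmax(force / scale, -1), 1)
    phi_new <- phi + params$tau * delta * force / max(delta)
    if (params$mu > 0) {
      gmagphi <- sqrt(grad_axis(phi, 1)^2 + grad_axis(phi, 2)^2 +
                        grad_axis(phi, 3)^2)
      D <- params$mu * G * delta / pmax(gmagphi, 0.1)
      if (!all(is.finite(D)))
        stop("non-finite diffusivity during evolution (gradient guard failure)",
             call. = FALSE)
      acc <- array(0, dim(phi))
      for (ax in which(dim(I) > 1L))
        acc <- acc + aos_solve_axis(phi_new, D, n_axes * params$tau, ax)
      phi_new <- acc / n_axes
    }
    if (!all(is.finite(phi_new)))
      stop("non-finite level set during evolution", call. = FALSE)
    phi_new <- pmin(pmax(phi_new, -10), 10)
    phi <- phi_new
    if (it %% check_every == 0L) {
      if (trace_energy)
        energy_trace <- c(energy_trace,
                          fiacm_energy(volume, u, level_set_state(phi), params,
                                       edge, kernel))
      changed <- mean((phi > 0) != (phi_check > 0)) / check_every
      phi_check <- phi
      if (changed < params$conv_tol) {
        converged <- TRUE
        break
      }
    }
  }
  out <- level_set_state(phi, iterations = it, converged = converged)
  out$energy_trace <- energy_trace
  out
}

#' Discretized FIACM energy (diagnostic surrogate)
#'
#' Edge term `mu * sum(delta * g * |grad phi|)` plus the pointwise region
#' terms with the current fitting pair; used to monitor that evolution
#' descends the energy.
#' @inheritParams fiacm_evolve
#' @param state current `level_set_state`.
#' @export
fiacm_energy <- function(volume, u, state, params, edge, kernel) {
  if (!inherits(volume, "volume_handle")) volume <- as_volume(volume)
  I <- volume$intensity
  uarr <- if (inherits(u, "membership_map")) u$u else as_vol3d(u)
  phi <- state$phi
  G <- edge_stop(gradient_magnitude(volume, edge$smoothing), edge)
  rf <- region_fitting(volume, state, kernel, params$epsilon)
  H <- smoothed_heaviside(phi, params$epsilon)
  delta <- smoothed_dirac(phi, params$epsilon)
  gmagphi <- sqrt(grad_axis(phi, 1)^2 + grad_axis(phi, 2)^2 + grad_axis(phi, 3)^2)
  params$mu * sum(delta * G * gmagphi) +
    params$lambda1 * sum((1 - uarr)^params$m * (I - rf$f1)^2 * H) +
    params$lambda2 * sum(uarr^params$m * (I - rf$f2)^2 * (1 - H))
}

#' Extract candidate objects from a level set
#'
#' Connected components (26-connectivity) of the interior \{phi > 0\};
#' components smaller than `min_voxels` are dropped.
#'
#' @param state `level_set_state` (or logical mask).
#' @param min_voxels minimum component size.
#' @param volume_id scan identifier stamped on the records.
#' @return list of `candidate_record`s with stage flag `"segmented"`.
#' @export
extract_candidates <- function(state, min_voxels = 10L, volume_id = "vol") {
  mask <- if (inherits(state, "level_set_state")) state$phi > 0 else
    as_vol3d(state) != 0
  lab <- label_components(mask, 26L)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  out <- list()
  next_id <- 1L
  for (comp in ids) {
    cm <- lab == comp
    if (sum(cm) < min_voxels) next
    out[[next_id]] <- candidate_record(next_id, volume_id, cm)
    next_id <- next_id + 1L
  }
  out
}
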