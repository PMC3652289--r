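# Refinement of juxtavascular candidates with a hybrid parametric mixture
# model (PMM): structure-tensor flow directions give a geometric observation,
# intensity and fuzzy membership give appearance; the joint observations are
# modelled as (M-1) multivariate Gaussians plus one fixed-density uniform
# outlier component, fitted by EM, and voxels are reassigned by maximum
# posterior. Only candidates judged vessel-attached are refined, and the
# refinement never adds voxels outside the original mask.

#' Decide whether a candidate needs vessel-attachment refinement
#'
#' A candidate is flagged when it is insufficiently sphere-like: volumetric
#' quotient below `q_attach` or central-slice compactness below `c_attach`.
#'
#' @param candidate a `candidate_record` (unused beyond its presence; the
#'   decision runs on the features).
#' @param features a `feature_vector` for the candidate.
#' @param q_attach,c_attach thresholds (defaults 0.6 / 0.7).
#' @return logical.
#' @export
needs_refinement <- function(candidate, features, q_attach = 0.6, c_attach = 0.7) {
  f <- unclass(features)
  unname(f["volumetric_quotient"] < q_attach | f["compactness"] < c_attach)
}

#' Structure tensor field with per-voxel eigensystem
#'
#' The tensor is the componentwise Gaussian-smoothed outer product of the
#' per-voxel intensity gradient (gradients first, a light smoothing after,
#' so local features are kept). Eigenvalues are sorted ascending
#' `lambda1 <= lambda2 <= lambda3`; along a tube the eigenvector of
#' `lambda1` (least intensity variation) points down the axis.
#'
#' @param volume `volume_handle`, `labeled_volume` or array.
#' @param gradient_scale Gaussian scale (mm) for the gradients.
#' @param tensor_scale Gaussian scale (mm) for smoothing the tensor
#'   components.
#' @param mask optional logical array: eigensystems are computed only there.
#' @return a `structure_tensor_field`: `idx` (linear voxel indices),
#'   `lambda` (n x 3, ascending), `e1` (n x 3 unit eigenvectors of lambda1),
#'   and the grid dimensions.
#' @export
structure_tensor <- function(volume, gradient_scale = 1, tensor_scale = 1.5,
                             mask = NULL) {
  stopifnot(gradient_scale > 0, tensor_scale > 0)
  if (!inherits(volume, "volume_handle")) volume <- as_volume(volume)
  sp <- volume$spacing
  s <- gauss_smooth(volume$intensity, gradient_scale, sp)
  g <- lapply(1:3, function(ax) grad_axis(s, ax, sp[ax]))
  Tc <- list()
  for (i in 1:3) for (j in i:3)
    Tc[[paste0(i, j)]] <- gauss_smooth(g[[i]] * g[[j]], tensor_scale, sp)
  idx <- if (is.null(mask)) seq_along(s) else which(as_vol3d(mask) != 0)
  n <- length(idx)
  lambda <- matrix(0, n, 3)
  e1 <- matrix(0, n, 3)
  for (r in seq_len(n)) {
    v <- idx[r]
    Tm <- matrix(c(Tc[["11"]][v], Tc[["12"]][v], Tc[["13"]][v],
                   Tc[["12"]][v], Tc[["22"]][v], Tc[["23"]][v],
                   Tc[["13"]][v], Tc[["23"]][v], Tc[["33"]][v]), 3, 3)
    es <- eigen(Tm, symmetric = TRUE) # values decreasing
    lambda[r, ] <- pmax(rev(es$values), 0) # PSD up to numerics
    e1[r, ] <- es$vectors[, 3]
  }
  structure(list(idx = idx, lambda = lambda, e1 = e1, dim = dim(s)),
            class = "structure_tensor_field")
}

#' Flow vectors from a structure tensor field
#'
#' `l1 = lambda3 * e1`: direction of least intensity variation, scaled by
#' the largest eigenvalue, so strong tubular structures carry long,
#' axis-aligned vectors.
#'
#' @param tensors a `structure_tensor_field`.
#' @return a `flow_field` with `vectors` (n x 3), `idx` and `dim`.
#' @export
flow_vectors <- function(tensors) {
  stopifnot(inherits(tensors, "structure_tensor_field"))
  structure(list(vectors = tensors$e1 * tensors$lambda[, 3],
                 idx = tensors$idx, dim = tensors$dim, reference = NULL),
            class = "flow_field")
}

#' Regularize flow directions to a common half-space
#'
#' Eigenvector signs are arbitrary; vectors with negative inner product
#' against the unit reference are inverted so the field has a consistent
#' orientation. Magnitudes are unchanged.
#'
#' @param flow a `flow_field`.
#' @param reference unit 3-vector. Defaults to the dominant eigenvector of
#'   the vectors' second-moment matrix (any consistent half-space reference
#'   serves the purpose).
#' @return the `flow_field` with oriented `vectors` and the `reference`.
#' @export
regularize_directions <- function(flow, reference = NULL) {
  stopifnot(inherits(flow, "flow_field"))
  V <- flow$vectors
  if (is.null(reference)) {
    Mm <- crossprod(V)
    reference <- eigen(Mm, symmetric = TRUE)$vectors[, 1]
  }
  nr <- sqrt(sum(reference^2))
  if (nr == 0) stop("zero reference vector", call. = FALSE)
  reference <- reference / nr
  dots <- V %*% reference
  V[dots < 0, ] <- -V[dots < 0, , drop = FALSE]
  flow$vectors <- V
  flow$reference <- reference
  flow
}

## --- Hybrid Gaussian + uniform mixture -------------------------------------

# Log-density of a multivariate Gaussian via Cholesky.
log_dmvn <- function(x, mu, Sigma) {
  ch <- chol(Sigma)
  d <- length(mu)
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(z^2))
}

#' Fit the hybrid parametric mixture model by EM
#'
#' `M - 1` multivariate Gaussian components plus one uniform component of
#' fixed density; the E-step computes responsibilities under the full
#' mixture, the M-step updates all `M` weights and the Gaussian
#' means/covariances in closed form. The log-likelihood is non-decreasing;
#' iteration stops when its relative change falls below `tol`. Collapsing
#' covariances receive a ridge of `1e-6 * trace/d` (logged via a warning);
#' if a covariance is still singular the fit aborts.
#'
#' @param observations numeric matrix, one observation vector per row.
#' @param M total component count (Gaussians + the uniform), >= 2;
#'   observations must number at least `10 * M`.
#' @param uniform_density the fixed outlier density (default `1/pi`; it is a
#'   convention, not a normalized density over the observation domain).
#' @param tol relative log-likelihood tolerance.
#' @param max_iter EM iteration cap.
#' @param seed RNG seed for the k-means initialization of the means.
#' @return a `mixture_model`: `weights` (length M, the last is the uniform),
#'   `means`, `covs`, `uniform_density`, `loglik` trace, `converged`.
#' @export
fit_pmm <- function(observations, M = 3L, uniform_density = 1 / pi,
                    tol = 1e-6, max_iter = 200L, seed = 1L) {
  x <- as.matrix(observations)
  n <- nrow(x); d <- ncol(x); K <- M - 1L
  stopifnot(M >= 2L)
  if (n < 10L * M) stop("need at least 10*M observations", call. = FALSE)
  if (all(apply(x, 2L, function(col) diff(range(col)) == 0)))
    stop("covariance collapse: all observations identical", call. = FALSE)
  km <- with_seed(seed, stats::kmeans(x, centers = min(K, n - 1L), nstart = 3L,
                                      iter.max = 50L))
  means <- lapply(seq_len(K), function(k) km$centers[min(k, nrow(km$centers)), ])
  covs <- rep(list(stats::cov(x) + diag(1e-8, d)), K)
  w <- c(rep(0.9 / K, K), 0.1)
  regularize <- function(S) {
    tr <- sum(diag(S))
    if (tr <= 0) stop("covariance collapse: degenerate component", call. = FALSE)
    ridge <- 1e-6 * tr / d
    for (attempt in 1:8) {
      ok <- tryCatch({ chol(S + diag(ridge, d)); TRUE }, error = function(e) FALSE)
      if (ok) {
        if (attempt > 1L)
          warning("ridge regularization applied to a collapsing covariance",
                  call. = FALSE)
        return(S + diag(ridge, d))
      }
      ridge <- ridge * 100
    }
    stop("covariance collapse: component covariance is singular", call. = FALSE)
  }
  covs <- lapply(covs, regularize)
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logd <- matrix(0, n, M)
    for (k in seq_len(K))
      logd[, k] <- log(w[k]) + log_dmvn(x, means[[k]], covs[[k]])
    logd[, M] <- log(w[M]) + log(uniform_density)
    mx <- apply(logd, 1L, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    loglik <- c(loglik, ll)
    if (it > 1L && abs(ll - loglik[it - 1L]) <=
        tol * max(1, abs(loglik[it - 1L]))) {
      converged <- TRUE
      break
    }
    nk <- colSums(resp)
    w <- pmax(nk / n, 1e-4)
    w <- w / sum(w)
    for (k in seq_len(K)) {
      if (nk[k] < 1e-8) next
      mu <- colSums(resp[, k] * x) / nk[k]
      xc <- sweep(x, 2L, mu, `-`)
      S <- crossprod(xc * sqrt(resp[, k])) / nk[k]
      means[[k]] <- mu
      covs[[k]] <- regularize(S)
    }
  }
  structure(list(M = M, weights = w, means = means, covs = covs,
                 uniform_density = uniform_density, loglik = loglik,
                 converged = converged),
            class = "mixture_model")
}

#' Maximum-posterior assignment under a fitted mixture
#'
#' Posteriors are proportional to `weight_k * density_k(v)`; each
#' observation gets the argmax component, ties broken by the lowest
#' component index. Component `M` is the uniform outlier class.
#'
#' @param observations numeric matrix (same columns as the fit).
#' @param model a `mixture_model`.
#' @return an `assignment_map`: integer `labels` and the posterior matrix
#'   (rows sum to 1).
#' @export
pmm_assign <- function(observations, model) {
  x <- as.matrix(observations)
  n <- nrow(x); M <- model$M; K <- M - 1L
  logd <- matrix(0, n, M)
  for (k in seq_len(K))
    logd[, k] <- log(model$weights[k]) + log_dmvn(x, model$means[[k]],
                                                  model$covs[[k]])
  logd[, M] <- log(model$weights[M]) + log(model$uniform_density)
  mx <- apply(logd, 1L, max)
  post <- exp(logd - mx)
  post <- post / rowSums(post)
  labels <- max.col(post, ties.method = "first")
  structure(list(labels = labels, posteriors = post), class = "assignment_map")
}

#' Refine a vessel-attached candidate with the hybrid PMM
#'
#' Observation vectors `(I, u, o)` — intensity, fuzzy membership and the
#' regularized 3-component flow vector — are built at the voxels of the
#' candidate mask (the structure tensor is computed on the candidate's
#' bounding box dilated by `margin` voxels). Intensity and flow columns are
#' standardized; the membership column keeps its \[0, 1\] scale so component
#' means remain interpretable. The `M = 3` mixture (two Gaussians plus the
#' uniform outlier class) is fitted twice: the Gaussian with the highest
#' mean membership is the nodule component, Gaussians whose mean membership
#' falls below `u_vessel` are recognized as vessel, and voxels whose best
#' structure component is a vessel component are removed; the refit on the
#' remainder catches the attachment collar. When no component is
#' vessel-like nothing is removed, so sphere-like candidates pass through
#' unchanged. The largest connected component of the result is the refined
#' mask; voxels are never added, and if refinement would empty the mask the
#' original is kept and the candidate flagged `refinement_failed`.
#'
#' @param candidate a `candidate_record` with its mask.
#' @param volume `volume_handle`, `labeled_volume` or array.
#' @param u `membership_map` or array on the same grid.
#' @param margin bounding-box dilation (voxels) for the tensor computation.
#' @param u_vessel membership level below which a component is vessel.
#' @param M,uniform_density,tol,max_iter,seed passed to [fit_pmm()].
#' @param gradient_scale,tensor_scale passed to [structure_tensor()].
#' @return the refined `candidate_record` (flag `"refined"` appended).
#' @export
refine_candidate <- function(candidate, volume, u, margin = 3L, u_vessel = 0.5,
                             M = 3L, uniform_density = NULL, tol = 1e-6,
                             max_iter = 200L, seed = 1L,
                             gradient_scale = 1, tensor_scale = 1.5) {
  if (!inherits(volume, "volume_handle")) volume <- as_volume(volume)
  uarr <- if (inherits(u, "membership_map")) u$u else as_vol3d(u)
  mask <- candidate$mask
  bb <- list(lo = candidate$bbox_lo, hi = candidate$bbox_hi)
  Ic <- crop_bbox(volume$intensity, bb, margin)
  mc <- crop_bbox(mask, bb, margin)
  uc <- crop_bbox(uarr, bb, margin)
  sub <- as_volume(Ic, volume$spacing)
  st <- structure_tensor(sub, gradient_scale, tensor_scale, mask = mc)
  fl <- regularize_directions(flow_vectors(st))
  idx <- st$idx
  std <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) s <- 1
    (v - mean(v)) / s
  }
  obs <- cbind(I = std(Ic[idx]), u = uc[idx],
               o1 = std(fl$vectors[, 1]), o2 = std(fl$vectors[, 2]),
               o3 = std(fl$vectors[, 3]))
  if (is.null(uniform_density)) {
    # uniform outlier density over the observation bounding box, so the
    # Gaussians compete with a properly scaled alternative in 5-D
    spans <- pmax(apply(obs, 2L, function(col) diff(range(col))), 1e-3)
    uniform_density <- 1 / prod(spans)
  }
  # Two fitting passes: the first removes the dominant vessel limb, the
  # second (refitted on the remainder) catches the attachment collar whose
  # flow statistics were masked by the full limb. Voxels are dropped when
  # their best Gaussian (posterior among the structure components) is a
  # vessel component; the uniform class stays neutral.
  keep <- rep(TRUE, nrow(obs))
  fail <- FALSE
  for (pass in 1:2) {
    ob <- obs[keep, , drop = FALSE]
    if (nrow(ob) < 10L * M) break
    fit <- try(fit_pmm(ob, M = M, uniform_density = uniform_density, tol = tol,
                       max_iter = max_iter, seed = seed), silent = TRUE)
    if (inherits(fit, "try-error")) {
      fail <- pass == 1L
      break
    }
    mean_u <- vapply(seq_len(M - 1L), function(k) fit$means[[k]]["u"], 0)
    vessel_comps <- setdiff(which(mean_u < u_vessel), which.max(mean_u))
    if (length(vessel_comps) == 0L) break
    asg <- pmm_assign(ob, fit)
    gpost <- asg$posteriors[, seq_len(M - 1L), drop = FALSE]
    # a voxel is removed only if its best structure component is vessel AND
    # its own membership sits below the vessel level — high-membership
    # nodule-shell voxels are never sacrificed to the vessel component
    drop <- max.col(gpost, ties.method = "first") %in% vessel_comps &
      ob[, "u"] < u_vessel
    keep[keep] <- !drop
  }
  if (!fail) {
    refined_c <- array(FALSE, dim(mc))
    refined_c[idx[keep]] <- TRUE
    refined_c <- refined_c & mc
    if (any(refined_c)) {
      lab <- label_components(refined_c, 26L)
      tab <- tabulate(lab[lab > 0L])
      refined_c <- lab == which.max(tab)
    }
    fail <- !any(refined_c)
  }
  if (fail) {
    candidate$refinement_failed <- TRUE
    candidate$flags <- unique(c(candidate$flags, "refined"))
    return(candidate)
  }
  # re-embed the cropped refinement into the full grid; never add voxels
  d <- dim(mask)
  lo <- pmax(bb$lo + 1L - margin, 1L)
  hi <- pmin(bb$hi + margin, d)
  refined <- array(FALSE, d)
  refined[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- refined_c
  refined <- refined & mask
  candidate$mask <- refined
  bbn <- bbox_of(refined)
  candidate$bbox_lo <- bbn$lo
  candidate$bbox_hi <- bbn$hi
  candidate$n_voxels <- sum(refined)
  candidate$flags <- unique(c(candidate$flags, "refined"))
  candidate
}
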