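# Structure tensors, flow regularization, the hybrid Gaussian+uniform
# mixture and juxtavascular refinement.

test_that("refinement triggering follows the sphere-likeness features", {
  v <- sphere_volume(r = 5, pad = 5L)
  cand <- extract_candidates(level_set_state(ifelse(v$labels == 1L, 2, -2)),
                             10L)[[1]]
  fv <- feature_vector(cand, as_volume(v))
  expect_false(needs_refinement(cand, fv))
  vt <- tube_volume(r = 2, len = 40L)
  candt <- extract_candidates(level_set_state(ifelse(vt$labels == 2L, 2, -2)),
                              10L)[[1]]
  fvt <- feature_vector(candt, as_volume(vt))
  expect_true(needs_refinement(candt, fvt))
  expect_false(needs_refinement(candt, fvt, q_attach = 0, c_attach = 0))
})

test_that("structure tensor axes and anisotropy distinguish tube from sphere", {
  vt <- tube_volume(r = 4, len = 40L, soft = 0.5)
  d <- dim(vt$intensity)
  co <- expand.grid(x = seq_len(d[1]) - 0.5, y = seq_len(d[2]) - 0.5,
                    z = seq_len(d[3]) - 0.5)
  shell_t <- array(abs(sqrt((co$x - 8)^2 + (co$y - 8)^2) - 4) < 1 &
                     co$z > 10 & co$z < 30, d)
  st <- structure_tensor(as_volume(vt), 1, 1.5, mask = shell_t)
  expect_true(all(abs(st$e1[, 3]) >= 0.99))
  expect_true(all(st$lambda[, 1] <= st$lambda[, 2] &
                    st$lambda[, 2] <= st$lambda[, 3]))

  vs <- sphere_volume(r = 5, pad = 5L, soft = 0.5)
  ds <- dim(vs$intensity)
  cos_ <- expand.grid(x = seq_len(ds[1]) - 0.5, y = seq_len(ds[2]) - 0.5,
                      z = seq_len(ds[3]) - 0.5)
  rr <- sqrt((cos_$x - ds[1] / 2)^2 + (cos_$y - ds[2] / 2)^2 +
               (cos_$z - ds[3] / 2)^2)
  shell_s <- array(abs(rr - 5) < 1, ds)
  ss <- structure_tensor(as_volume(vs), 1, 1.5, mask = shell_s)
  aniso <- function(f) mean((f$lambda[, 3] - f$lambda[, 1]) /
                              pmax(f$lambda[, 3], 1e-12))
  expect_lt(aniso(ss), aniso(st))

  cz <- structure_tensor(array(3, c(6, 6, 6)), 1, 1)
  expect_true(all(abs(cz$lambda) < 1e-10))
})

test_that("flow vectors scale as lambda3 along e1 and with intensity squared", {
  # crafted tensor via a synthetic field: the eigen-decomposition oracle
  crafted <- structure(list(idx = 1L, lambda = matrix(c(0, 0, 4), 1),
                            e1 = matrix(c(0, 0, 1), 1), dim = c(1L, 1L, 1L)),
                       class = "structure_tensor_field")
  fl <- flow_vectors(crafted)
  expect_equal(as.vector(fl$vectors), c(0, 0, 4))
  zero <- structure(list(idx = 1L, lambda = matrix(0, 1, 3),
                         e1 = matrix(c(1, 0, 0), 1), dim = c(1L, 1L, 1L)),
                    class = "structure_tensor_field")
  expect_equal(as.vector(flow_vectors(zero)$vectors), c(0, 0, 0))
  vt <- tube_volume(r = 3, len = 24L, soft = 0.5)
  mask <- vt$labels == 2L
  f1 <- flow_vectors(structure_tensor(as_volume(vt), 1, 1, mask = mask))
  v2 <- vt; v2$intensity <- (v2$intensity + 900) * 3 - 900
  f2 <- flow_vectors(structure_tensor(as_volume(v2), 1, 1, mask = mask))
  m1 <- sqrt(rowSums(f1$vectors^2)); m2 <- sqrt(rowSums(f2$vectors^2))
  keep <- m1 > stats::quantile(m1, 0.5)
  expect_equal(median(m2[keep] / m1[keep]), 9, tolerance = 0.05)
})

test_that("direction regularization maps every vector into the half-space", {
  fl <- structure(list(vectors = rbind(c(0, 0, 1), c(0, 0, -1)), idx = 1:2,
                       dim = c(1L, 1L, 2L), reference = NULL),
                  class = "flow_field")
  out <- regularize_directions(fl, c(0, 0, 1))
  expect_equal(out$vectors, rbind(c(0, 0, 1), c(0, 0, 1)))
  orth <- structure(list(vectors = rbind(c(1, 0, 0)), idx = 1L,
                         dim = c(1L, 1L, 1L), reference = NULL),
                    class = "flow_field")
  expect_equal(regularize_directions(orth, c(0, 0, 1))$vectors, rbind(c(1, 0, 0)))
  set.seed(4)
  rnd <- structure(list(vectors = matrix(rnorm(300), 100, 3), idx = 1:100,
                        dim = c(10L, 10L, 1L), reference = NULL),
                   class = "flow_field")
  mags <- sqrt(rowSums(rnd$vectors^2))
  reg <- regularize_directions(rnd)
  expect_true(all(reg$vectors %*% reg$reference >= -1e-12))
  expect_equal(sqrt(rowSums(reg$vectors^2)), mags)
  expect_error(regularize_directions(rnd, c(0, 0, 0)), "zero")
})

test_that("EM recovers the parameters of a known Gaussian+uniform mixture", {
  set.seed(42)
  n <- 1500L
  z <- sample(1:3, n, replace = TRUE, prob = c(0.45, 0.45, 0.1))
  x <- matrix(0, n, 3)
  x[z == 1, ] <- matrix(rnorm(sum(z == 1) * 3, 0, 1), ncol = 3)
  x[z == 2, ] <- matrix(rnorm(sum(z == 2) * 3, 5, 1), ncol = 3)
  x[z == 3, ] <- matrix(runif(sum(z == 3) * 3, -5, 10), ncol = 3)
  colnames(x) <- c("a", "b", "u")
  fit <- fit_pmm(x, M = 3L, uniform_density = 1 / 15^3, seed = 1L)
  mns <- do.call(rbind, fit$means)
  ord <- order(mns[, 1])
  expect_true(all(abs(mns[ord[1], ] - 0) < 0.1))
  expect_true(all(abs(mns[ord[2], ] - 5) < 0.1))
  expect_true(all(abs(fit$weights[ord] - c(0.45, 0.45)) < 0.05))
  expect_lt(abs(fit$weights[3] - 0.1), 0.05)
  expect_true(all(diff(fit$loglik) >= -1e-8))
  expect_error(fit_pmm(matrix(1, 60, 3), M = 3L), "collapse")
})

test_that("MAP assignment matches a brute-force density oracle", {
  set.seed(8)
  obs <- matrix(rnorm(50 * 2), 50, 2)
  colnames(obs) <- c("a", "u")
  model <- structure(list(
    M = 3L, weights = c(0.5, 0.3, 0.2),
    means = list(c(a = 0, u = 0), c(a = 2, u = 1)),
    covs = list(diag(2) * 0.8, diag(2) * 1.2),
    uniform_density = 0.01), class = "mixture_model")
  asg <- pmm_assign(obs, model)
  expect_equal(rowSums(asg$posteriors), rep(1, 50), tolerance = 1e-12)
  dens <- cbind(
    0.5 * mvn_dens(obs, c(0, 0), diag(2) * 0.8),
    0.3 * mvn_dens(obs, c(2, 1), diag(2) * 1.2),
    0.2 * 0.01)
  expect_identical(asg$labels, max.col(dens, ties.method = "first"))
  expect_equal(asg$posteriors, dens / rowSums(dens), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("juxtavascular refinement removes the vessel and never adds voxels", {
  jac <- c(); excl <- c()
  for (s in 1:2) {
    v <- phantom_scan(s, "juxtavascular")
    vol <- as_volume(v)
    truth <- v$labels == 1L | v$labels == 3L
    u <- membership_map(vol, seed = s, opening_radius = 1L)
    cands <- extract_candidates(initialize_contour(vol, 9L, 40), 10L)
    ov <- vapply(cands, function(cc) sum(cc$mask & truth), 0L)
    cand <- cands[[which.max(ov)]]
    ref <- refine_candidate(cand, vol, u, seed = s)
    expect_true(all(ref$mask <= cand$mask))          # refined subset of original
    # locality: nothing outside the original bounding box is touched
    out_box <- array(TRUE, dim(cand$mask))
    lo <- cand$bbox_lo + 1L; hi <- cand$bbox_hi
    out_box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- FALSE
    expect_identical(ref$mask[out_box], cand$mask[out_box])
    jac <- c(jac, jaccard_error(ref$mask, truth)$jaccard_error)
    excl <- c(excl, 1 - sum(ref$mask & v$labels == 2L) / sum(v$labels == 2L))
  }
  expect_true(all(excl >= 0.9))
  expect_lte(mean(jac), 0.25)
})

test_that("an isolated sphere passes through forced refinement unchanged", {
  # scene with a nodule and a clearly separated vessel: the candidate under
  # refinement is the sphere alone
  spec <- phantom_spec(c(40L, 40L, 32L),
                       nodules = list(nodule_spec(c(13, 13, 11), 6)),
                       vessels = list(vessel_spec(rbind(c(1, 33, 27),
                                                        c(39, 33, 27)), 2)),
                       noise_sigma = 25, bias_amplitude = 0.05, seed = 13L)
  v <- render_phantom(spec)
  vol <- as_volume(v)
  truth <- v$labels == 1L
  u <- membership_map(vol, seed = 13L, opening_radius = 1L)
  cands <- extract_candidates(initialize_contour(vol, 9L, 40), 10L)
  ov <- vapply(cands, function(cc) sum(cc$mask & truth), 0L)
  cand <- cands[[which.max(ov)]]
  expect_equal(sum(cand$mask & v$labels == 2L), 0L) # really isolated
  ref <- refine_candidate(cand, vol, u, seed = 13L)
  expect_lte(sum(xor(ref$mask, cand$mask)) / cand$n_voxels, 0.02)
})
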