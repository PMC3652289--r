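# FIACM: Heaviside/Dirac pair, posterior edge thresholds, edge-stop
# function, region-scalable fitting, initialization and evolution.

test_that("smoothed Heaviside/Dirac satisfy the defining identities", {
  expect_equal(smoothed_heaviside(0, 1.5), 0.5)
  expect_gt(smoothed_heaviside(1e6, 1.5), 1 - 1e-5)
  z <- seq(-4, 4, by = 0.5)
  expect_equal(smoothed_heaviside(-z, 1), 1 - smoothed_heaviside(z, 1))
  expect_true(all(diff(smoothed_heaviside(z, 1)) > 0))
  h <- 1e-6
  num <- (smoothed_heaviside(0.3 + h, 1) - smoothed_heaviside(0.3 - h, 1)) / (2 * h)
  expect_equal(num, smoothed_dirac(0.3, 1), tolerance = 1e-6)
})

test_that("edge thresholds bracket the decision region of a bimodal sample", {
  set.seed(11)
  t_sample <- c(rnorm(1400, 1, 0.5), rnorm(600, 10, 0.5))
  t_sample <- t_sample[t_sample > 0]
  par <- nodulecad:::fit_edge_gmm(t_sample, p_lo = 0.6, p_hi = 0.95)
  expect_true(par$a > 1 && par$a < par$b && par$b < 10)
  # dense-grid oracle: posteriors really cross p_lo/p_hi near a and b
  grid <- seq(1, 10, length.out = 20000)
  mu <- c(1, 10); sd_ <- c(0.5, 0.5); pr <- c(0.7, 0.3)
  post <- pr[2] * dnorm(grid, 10, 0.5) /
    (pr[2] * dnorm(grid, 10, 0.5) + pr[1] * dnorm(grid, 1, 0.5))
  a_orc <- grid[min(which(post >= 0.6))]
  b_orc <- grid[min(which(post >= 0.95))]
  expect_lt(abs(par$a - a_orc), 0.5)
  expect_lt(abs(par$b - b_orc), 0.5)
  expect_error(estimate_edge_thresholds(array(1, c(6, 6, 6))), "degenerate|constant")
  expect_error(estimate_edge_thresholds(sphere_volume(3, 2L), p_lo = 0.5,
                                        p_hi = 0.5), "p_lo")
})

test_that("edge-stop function follows the four-branch piecewise form", {
  par <- edge_stop_params(1, 3)
  expect_equal(edge_stop(c(0, 0.5, 1), par), c(1, 1, 1))
  expect_equal(edge_stop(c(3.0001, 5, 100), par), c(0, 0, 0))
  expect_equal(edge_stop(2, par), 0.5)           # midpoint of both quadratics
  expect_equal(edge_stop(1.5, par), 0.875)       # 1 - 2*(0.25)^2
  expect_equal(edge_stop(3, par), 0)             # upper threshold
  t <- seq(0, 4, by = 0.01)
  g <- edge_stop(t, par)
  expect_true(all(diff(g) <= 1e-12))             # monotone non-increasing
  h <- 1e-6
  for (t0 in c(1, 2, 3))                          # continuity at the joints
    expect_lt(abs(edge_stop(t0 + h, par) - edge_stop(t0 - h, par)), 1e-5)
  expect_error(edge_stop_params(3, 1), "a < b")
})

test_that("region fitting matches a brute-force windowed-average oracle", {
  set.seed(21)
  I <- array(rnorm(8^3), c(8, 8, 8))
  phi <- array(rnorm(8^3), c(8, 8, 8))
  ker <- kernel_spec(1.2)
  rf <- region_fitting(as_volume(I), level_set_state(phi), ker, epsilon = 1.5)
  orc <- region_fitting_oracle(I, phi, 1.2, 1.5)
  expect_equal(rf$f1, orc$f1, tolerance = 1e-6)
  expect_equal(rf$f2, orc$f2, tolerance = 1e-6)
  # constants are fixed points
  rfc <- region_fitting(as_volume(array(7, c(8, 8, 8))),
                        level_set_state(phi), ker)
  expect_equal(rfc$f1, array(7, c(8, 8, 8)), tolerance = 1e-9)
  expect_equal(rfc$f2, array(7, c(8, 8, 8)), tolerance = 1e-9)
})

test_that("two-region image yields the region constants away from the interface", {
  img <- array(-900, c(24, 24, 1)); img[1:12, , 1] <- 400
  phi <- array(-2, dim(img)); phi[1:12, , 1] <- 2
  rf <- region_fitting(as_volume(img), level_set_state(phi), kernel_spec(2))
  expect_equal(rf$f1[3, 12, 1], 400, tolerance = 1e-6)
  expect_equal(rf$f2[22, 12, 1], -900, tolerance = 1e-6)
})

test_that("kernel scale follows the mean membership with clamping", {
  expect_equal(kernel_sigma_from_membership(array(0.5, c(4, 4, 4)),
                                            sigma_base = 3)$sigma, 3)
  expect_equal(kernel_sigma_from_membership(array(1, c(4, 4, 4)),
                                            sigma_base = 3)$sigma, 4.5)
  sig <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(m0)
    kernel_sigma_from_membership(array(m0, c(4, 4, 4)), sigma_base = 2)$sigma)
  expect_true(all(diff(sig) >= 0))
  expect_equal(range(sig), c(1, 3))
  expect_error(kernel_sigma_from_membership(array(1, c(4, 4, 4)),
                                            window = array(FALSE, c(4, 4, 4))),
               "empty")
})

test_that("adaptive-threshold initialization behaves on anchors", {
  v <- sphere_volume(r = 5, pad = 6L)
  init <- initialize_contour(as_volume(v), window = 9L, offset = 40)
  sphere <- v$labels == 1L
  expect_gte(sum(init$phi > 0 & sphere) / sum(sphere), 0.8)
  const <- initialize_contour(array(5, c(12, 12, 6)), window = 5L, offset = 10)
  expect_true(all(const$phi < 0))
  # duality: inverting the volume and the offset sign complements the mask
  set.seed(2)
  a <- array(rnorm(10^3), c(10, 10, 10))
  m1 <- initialize_contour(a, window = 5L, offset = 0.1, fill = FALSE)$phi > 0
  m2 <- initialize_contour(-a, window = 5L, offset = -0.1, fill = FALSE)$phi > 0
  expect_identical(m2, !m1)
})

test_that("evolution with zero weights leaves the level set unchanged", {
  v <- sphere_volume(r = 4, pad = 3L)
  init <- initialize_contour(as_volume(v), 9L, 40)
  p0 <- fiacm_params(mu = 0, lambda1 = 0, lambda2 = 0, max_iter = 25L,
                     conv_tol = 0)
  st <- fiacm_evolve(as_volume(v), array(0.5, dim(v$intensity)), init, p0,
                     edge_stop_params(1, 3), kernel_spec(2))
  expect_equal(st$phi, init$phi)
})

test_that("FIACM converges on the piecewise-constant disc", {
  fx <- disc_image(64L, c(32, 32), 12)
  vol <- as_volume(fx$img)
  u <- nodulecad:::gauss_smooth(ifelse(fx$disc, 1, 0), 2, c(1, 1, 1))
  edge <- estimate_edge_thresholds(vol, smoothing = 1, seed = 1L)
  st <- fiacm_evolve(vol, u, initialize_contour(vol, 9L, 40),
                     fiacm_params(max_iter = 300L), edge, kernel_spec(3))
  expect_lte(jaccard_error(st$phi > 0, fx$disc)$jaccard_error, 0.05)
  # and from a shifted, dilated initial circle
  co <- expand.grid(x = 1:64 - 0.5, y = 1:64 - 0.5)
  far <- array((co$x - 35)^2 + (co$y - 32)^2 <= 15^2, c(64, 64, 1))
  st2 <- fiacm_evolve(vol, u, level_set_state(ifelse(far, 2, -2)),
                      fiacm_params(max_iter = 300L), edge, kernel_spec(3))
  expect_lte(jaccard_error(st2$phi > 0, fx$disc)$jaccard_error, 0.05)
})

test_that("the discretized energy is non-increasing along the evolution", {
  fx <- disc_image(48L, c(24, 24), 9)
  vol <- as_volume(fx$img)
  u <- nodulecad:::gauss_smooth(ifelse(fx$disc, 1, 0), 2, c(1, 1, 1))
  edge <- estimate_edge_thresholds(vol, smoothing = 1, seed = 1L)
  co <- expand.grid(x = 1:48 - 0.5, y = 1:48 - 0.5)
  init <- array((co$x - 27)^2 + (co$y - 24)^2 <= 13^2, c(48, 48, 1))
  st <- fiacm_evolve(vol, u, level_set_state(ifelse(init, 2, -2)),
                     fiacm_params(max_iter = 120L), edge, kernel_spec(3),
                     trace_energy = TRUE)
  e <- st$energy_trace # one value per 10 iterations up to convergence
  expect_gte(length(e), 3L)
  jitter <- 0.01 * (max(e) - min(e))
  expect_true(all(diff(e) <= jitter))
})

test_that("candidate extraction counts components and filters small ones", {
  spec <- phantom_spec(c(40L, 20L, 20L),
                       nodules = list(nodule_spec(c(10, 10, 10), 4),
                                      nodule_spec(c(30, 10, 10), 4)),
                       seed = 1L)
  v <- render_phantom(spec)
  st <- level_set_state(ifelse(v$labels == 1L, 2, -2))
  expect_length(extract_candidates(st, 10L), 2L)
  expect_length(extract_candidates(level_set_state(array(-2, c(8, 8, 8)))), 0L)
  tiny <- array(FALSE, c(10, 10, 10)); tiny[2:3, 2:3, 2] <- TRUE # 4 voxels
  big <- tiny; big[6:9, 6:9, 6:7] <- TRUE
  st2 <- level_set_state(ifelse(big, 2, -2))
  expect_length(extract_candidates(st2, 10L), 1L)
  expect_length(extract_candidates(st2, 3L), 2L)
})
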