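# Chain code, 2-D/3-D shape descriptors, co-occurrence texture and the
# 21-descriptor feature vector.

test_that("chain code traces closed boundaries with the expected codes", {
  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  cc1 <- trace_chain_code(single)
  expect_length(cc1$codes, 0)
  expect_equal(chain_perimeter(cc1), 4)

  sq <- matrix(FALSE, 4, 4); sq[2:3, 2:3] <- TRUE
  cc2 <- trace_chain_code(sq)
  expect_equal(cc2$n_e, 4L)
  expect_equal(cc2$n_o, 0L)
  expect_equal(chain_perimeter(cc2), 4)
  # closure: follow the moves back to the start
  pos <- cc2$start
  for (code in cc2$codes)
    pos <- pos + c(nodulecad:::CODE_DR[code + 1L], nodulecad:::CODE_DC[code + 1L])
  expect_equal(pos, cc2$start, ignore_attr = TRUE)

  stair <- matrix(FALSE, 4, 4); stair[cbind(2:3, 2:3)] <- TRUE # diagonal domino
  cc3 <- trace_chain_code(stair)
  expect_gt(cc3$n_o, 0L)
  expect_equal(chain_perimeter(cc3), cc3$n_e + sqrt(2) * cc3$n_o)

  expect_error(trace_chain_code(matrix(FALSE, 3, 3)), "empty")
  two <- matrix(FALSE, 5, 5); two[1, 1] <- TRUE; two[5, 5] <- TRUE
  expect_error(trace_chain_code(two), "component")
})

test_that("2-D shape descriptors behave on discs and squares", {
  disc <- disc_mask2d(32, 12)
  f <- shape_features_2d(disc)
  expect_gte(f$compactness, 0.85)
  expect_lte(f$compactness, 1.05)
  expect_equal(f$ellipticity, 1, tolerance = 0.05)
  expect_equal(f$slenderness, 1)
  expect_equal(f$rectangle_degree, pi / 4, tolerance = 0.12) # (2R/(2R+1))^2 bias
  expect_equal(f$concavity_ratio, 0)
  expect_gt(f$circularity, 0.85)

  sq <- matrix(FALSE, 36, 36); sq[3:34, 3:34] <- TRUE
  fs <- shape_features_2d(sq)
  expect_equal(fs$compactness, pi / 4, tolerance = 0.1 * pi / 4)
  expect_equal(fs$slenderness, 1)
  expect_equal(fs$rectangle_degree, 1)
  expect_equal(fs$concavity_ratio, 0)
})

test_that("shape descriptors are translation invariant and scale stable", {
  m <- disc_mask2d(40, 8)
  f0 <- shape_features_2d(m)
  shifted <- matrix(FALSE, 40, 40)
  shifted[(1:40) > 5, (1:40) > 3] <- m[1:35, 1:37]
  f1 <- shape_features_2d(shifted)
  for (nm in c("area", "perimeter", "compactness", "slenderness",
               "rectangle_degree", "ellipticity", "concavity_ratio"))
    expect_equal(f1[[nm]], f0[[nm]], tolerance = 1e-12, label = nm)
  f2 <- shape_features_2d(disc_mask2d(60, 16))
  for (nm in c("compactness", "circularity", "slenderness", "ellipticity"))
    expect_lt(abs(f2[[nm]] - f0[[nm]]), 0.15)
})

test_that("3-D shape separates spheres from tubes via the volumetric quotient", {
  vs <- sphere_volume(r = 6, pad = 4L)
  f3 <- shape_features_3d(vs$labels == 1L, c(1, 1, 1))
  expect_gte(f3$volumetric_quotient, 0.9)
  vt <- tube_volume(r = 2, len = 42L)
  ft <- shape_features_3d(vt$labels == 2L, c(1, 1, 1))
  expect_lte(ft$volumetric_quotient, 0.1)
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(shape_features_3d(one)$volumetric_quotient, 1)
})

test_that("texture features match the pair-counting oracle", {
  cst <- matrix(5, 6, 6)
  t0 <- texture_features(cst, matrix(TRUE, 6, 6), levels = 8L)
  expect_equal(t0, list(energy = 1, contrast = 0, entropy = 0, idm = 1))

  chk <- outer(1:8, 1:8, function(i, j) (i + j) %% 2) # checkerboard 0/1
  t1 <- texture_features(chk, matrix(TRUE, 8, 8), levels = 8L,
                         offsets = list(c(0L, 1L)))
  expect_equal(t1$energy, 0.5)
  expect_equal(t1$contrast, 7^2) # gap of (levels-1) quantized bins

  set.seed(5)
  img <- matrix(sample(0:50, 36, replace = TRUE), 6, 6)
  msk <- matrix(TRUE, 6, 6); msk[1, ] <- FALSE
  got <- texture_features(img, msk, levels = 8L)
  orc <- glcm_oracle(img, msk, 8L)
  expect_equal(got, orc, tolerance = 1e-12)
  expect_error(texture_features(img, matrix(FALSE, 6, 6)), "mask")
})

test_that("the feature vector has exactly 21 finite named entries", {
  v <- sphere_volume(r = 5, pad = 4L)
  cand <- extract_candidates(level_set_state(ifelse(v$labels == 1L, 2, -2)),
                             10L)[[1]]
  fv <- feature_vector(cand, as_volume(v))
  expect_length(fv, 21L)
  expect_true(all(is.finite(fv)))
  expect_false(anyDuplicated(names(fv)) > 0)
  # constant-intensity candidate has zero intensity spread
  vc <- v; vc$intensity[] <- -900; vc$intensity[cand$mask] <- 400
  fvc <- feature_vector(cand, as_volume(vc))
  expect_equal(unname(fvc["sd2d"]), 0)
  expect_equal(unname(fvc["sd3d"]), 0)
  # quotient separates the sphere from a tube candidate
  vt <- tube_volume(r = 2, len = 42L)
  candt <- extract_candidates(level_set_state(ifelse(vt$labels == 2L, 2, -2)),
                              10L)[[1]]
  fvt <- feature_vector(candt, as_volume(vt))
  expect_gt(fv["volumetric_quotient"], fvt["volumetric_quotient"])
})
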