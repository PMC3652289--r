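# Knowledge gate, feature normalization, cost-sensitive SVM and the AUC
# grid search.

test_that("the gate passes spheres, rejects tubes, and is monotone", {
  v <- sphere_volume(r = 5, pad = 4L)
  cand <- extract_candidates(level_set_state(ifelse(v$labels == 1L, 2, -2)),
                             10L)[[1]]
  fv <- feature_vector(cand, as_volume(v))
  rules <- default_gate_rules()
  expect_true(gate(fv, rules))
  vt <- tube_volume(r = 2, len = 42L)
  candt <- extract_candidates(level_set_state(ifelse(vt$labels == 2L, 2, -2)),
                              10L)[[1]]
  fvt <- feature_vector(candt, as_volume(vt))
  expect_false(gate(fvt, rules))
  # relaxing thresholds never converts a pass into a fail
  relaxed <- default_gate_rules(volume_min = 1, volume_max = 1e6,
                                quotient_min = 0, mean3d_min = -2000)
  expect_true(gate(fv, relaxed))
  expect_error(gate_rules(list()), "at least one")
  expect_error(gate(fv[setdiff(names(fv), "volume")], rules), "missing")
})

test_that("min-max normalization learns on train and clamps on application", {
  train <- data.frame(a = c(0, 5, 10), b = c(2, 2, 2))
  nf <- normalize_features(train, apply_to = data.frame(a = c(-5, 5, 20), b = 3))
  expect_equal(nf$train$a, c(0, 0.5, 1))
  expect_equal(nf$train$b, c(0, 0, 0)) # constant feature
  expect_equal(nf$applied$a, c(0, 0.5, 1))
  # inverse transform recovers train values
  back <- nf$train$a * (nf$ranges$max["a"] - nf$ranges$min["a"]) + nf$ranges$min["a"]
  expect_equal(unname(back), train$a, tolerance = 1e-12)
})

test_that("the C-SVM separates, is label-symmetric, and honors class costs", {
  set.seed(6)
  x <- rbind(matrix(rnorm(40, 0, 0.4), 20, 2),
             matrix(rnorm(40, 4, 0.4), 20, 2))
  y <- rep(c(1L, -1L), each = 20L)
  fit <- train_csvm(x, y, C_minus = 2, gamma = 0.5)
  expect_equal(predict(fit, x)$label, y)
  flip <- train_csvm(x, -y, C_minus = 2, gamma = 0.5)
  expect_equal(predict(flip, x)$label, -predict(fit, x)$label)
  expect_error(train_csvm(x, rep(1L, 40)), "both classes")
  # raising C- weakly decreases training false positives on noisy data
  set.seed(7)
  xn <- rbind(matrix(rnorm(60, 0, 1.2), 30, 2), matrix(rnorm(60, 2, 1.2), 30, 2))
  yn <- rep(c(1L, -1L), each = 30L)
  fps <- sapply(c(0.5, 2, 8), function(Cm) {
    f <- train_csvm(xn, yn, C_minus = Cm, gamma = 0.5)
    sum(predict(f, xn)$label == 1L & yn == -1L)
  })
  expect_true(all(diff(fps) <= 0))
})

test_that("grid search maximizes CV AUC with the minimal-parameter tie rule", {
  set.seed(30)
  n_pos <- 30L; n_neg <- 300L
  x <- rbind(cbind(rnorm(n_pos, 2, 1), rnorm(n_pos, 2, 1)),
             cbind(rnorm(n_neg, 0, 1), rnorm(n_neg, 0, 1)))
  x <- cbind(x, runif(n_pos + n_neg)) # one noise feature
  y <- c(rep(1L, n_pos), rep(-1L, n_neg))
  xs <- normalize_features(as.data.frame(x))$train
  gs <- grid_search_auc(xs, y, k = 5L, C_grid = c(0.5, 2), gamma_grid = c(0.25, 1),
                        seed = 1L)
  expect_true(all(gs$auc >= gs$results$AUC - 1e-12)) # selected beats every point
  chosen <- gs$results[gs$results$chosen, ]
  ties <- gs$results[gs$results$AUC >= gs$auc - 1e-12, ]
  expect_equal(chosen$C_minus, min(ties$C_minus))
  one <- grid_search_auc(xs, y, k = 3L, C_grid = 2, gamma_grid = 0.5, seed = 1L)
  expect_true(one$results$chosen)
  expect_error(grid_search_auc(xs[1:20, ], c(rep(1L, 1), rep(-1L, 19)),
                               k = 5L, C_grid = 2, gamma_grid = 0.5, seed = 1L),
               "no positives")
})

test_that("the rank-statistic AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  dec <- rnorm(60)
  y <- ifelse(dec + rnorm(60, 0, 1) > 0, 1L, -1L)
  if (length(unique(y)) < 2L) y[1:2] <- c(1L, -1L)
  ours <- nodulecad:::rank_auc(dec, y)
  ref <- as.numeric(pROC::auc(pROC::roc(response = factor(y, levels = c(-1, 1)),
                                        predictor = dec, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("confusion metrics reproduce the printed cross-validation rows", {
  expect_equal(unname(confusion_metrics(7, 1, 30, 1)), c(0.875, 0.968, 0.949))
  expect_equal(unname(confusion_metrics(7, 1, 32, 3)), c(0.875, 0.914, 0.907))
  expect_error(confusion_metrics(0, 0, 5, 1), "empty class")
  expect_error(confusion_metrics(3, 1, 0, 0), "empty class")
})

test_that("phantom training sets are highly discriminable by CV AUC", {
  aucs <- sapply(1:2, function(s) {
    tr <- make_training_set(18L, 54L, seed = s * 11L)
    m <- train_default_model(tr, seed = s, k = 3L, C_grid = c(0.5, 2, 8),
                             gamma_grid = c(0.125, 0.5, 2))
    m$search$auc
  })
  expect_true(all(aucs > 0.9))
})
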