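# Two-stage false-positive reduction: a knowledge gate of linear half-space
# tests on four 3-D features (volume, volumetric quotient, 3-D intensity
# mean and SD), then a cost-sensitive SVM with RBF kernel, class-dependent
# penalties C+/C-, tuned by grid search on cross-validated AUC.

GATE_FEATURES <- c("volume", "volumetric_quotient", "mean3d", "sd3d")

#' Knowledge-gate rule set
#'
#' An ordered sequence of linear half-space tests over the four gate
#' features; a candidate passes the gate iff it passes every test. Each rule
#' is `coef . x >= threshold` (a single named coefficient covers the common
#' one-feature case).
#'
#' @param rules list of rules, each `list(coef = named numeric, threshold =
#'   numeric)`; at least one.
#' @export
gate_rules <- function(rules) {
  if (length(rules) == 0L) stop("gate needs at least one rule", call. = FALSE)
  for (r in rules) {
    if (is.null(names(r$coef)) || !all(names(r$coef) %in% GATE_FEATURES))
      stop("gate rules may only use: ", paste(GATE_FEATURES, collapse = ", "),
           call. = FALSE)
  }
  structure(rules, class = "gate_rules")
}

#' Default gate: plausible nodule volumes (3-30 mm sphere equivalents) and a
#' minimum volumetric quotient. Thresholds are engineering defaults exposed
#' in the pipeline configuration.
#' @param volume_min,volume_max volume window (mm^3).
#' @param quotient_min minimum volumetric quotient.
#' @param mean3d_min minimum 3-D mean intensity.
#' @export
default_gate_rules <- function(volume_min = 14, volume_max = 14200,
                               quotient_min = 0.25, mean3d_min = -700) {
  gate_rules(list(
    list(coef = c(volume = 1), threshold = volume_min),
    list(coef = c(volume = -1), threshold = -volume_max),
    list(coef = c(volumetric_quotient = 1), threshold = quotient_min),
    list(coef = c(mean3d = 1), threshold = mean3d_min)
  ))
}

#' Apply the knowledge gate to a feature vector
#'
#' @param features `feature_vector` (or named numeric holding the gate
#'   features).
#' @param rules a `gate_rules`.
#' @return TRUE iff every half-space test passes.
#' @export
gate <- function(features, rules) {
  stopifnot(inherits(rules, "gate_rules"))
  f <- unclass(features)
  for (r in rules) {
    need <- names(r$coef)
    if (!all(need %in% names(f)) || any(is.na(f[need])))
      stop("gate feature missing: ", paste(setdiff(need, names(f)), collapse = ", "),
           call. = FALSE)
    if (sum(r$coef * f[need]) < r$threshold) return(FALSE)
  }
  TRUE
}

#' Min-max feature normalization learned on the training table
#'
#' Scales every feature column to \[0, 1\] by the training minima/maxima;
#' applied values are clamped into \[0, 1\]. Constant training features map
#' to 0.
#'
#' @param train numeric data frame / matrix (features only).
#' @param apply_to optional table to transform with the learned ranges.
#' @return list with `train` (scaled), `applied` (scaled `apply_to`, if
#'   given) and `ranges` (min/max per feature).
#' @export
normalize_features <- function(train, apply_to = NULL) {
  train <- as.data.frame(train)
  if (nrow(train) == 0L) stop("empty training table", call. = FALSE)
  mins <- vapply(train, min, 0)
  maxs <- vapply(train, max, 0)
  span <- maxs - mins
  scale_tab <- function(tab) {
    tab <- as.data.frame(tab)[names(train)]
    out <- mapply(function(col, lo, sp) {
      if (sp == 0) rep(0, length(col)) else pmin(pmax((col - lo) / sp, 0), 1)
    }, tab, mins, span, SIMPLIFY = FALSE)
    as.data.frame(out)
  }
  list(train = scale_tab(train),
       applied = if (is.null(apply_to)) NULL else scale_tab(apply_to),
       ranges = list(min = mins, max = maxs))
}

#' Train the cost-sensitive SVM
#'
#' Soft-margin SVM with RBF kernel `K(s1, s2) = exp(-gamma ||s1 - s2||^2)`
#' and class-dependent box constraints: `0 <= a_i <= C+` for positives,
#' `<= C-` for negatives. By default `C+ = C- * (n_neg / n_pos)`, the usual
#' imbalance convention.
#'
#' @param x normalized feature matrix / data frame.
#' @param y labels in \{+1, -1\}.
#' @param C_minus penalty for the negative class.
#' @param gamma RBF width.
#' @param C_plus penalty for the positive class (imbalance-scaled default).
#' @return a `csvm_model` wrapping the e1071 fit.
#' @export
train_csvm <- function(x, y, C_minus = 1, gamma = 0.5, C_plus = NULL) {
  stopifnot(C_minus > 0, gamma > 0)
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1 / -1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  if (is.null(C_plus)) C_plus <- C_minus * sum(y == -1L) / sum(y == 1L)
  yf <- factor(y, levels = c(1L, -1L)) # first level = +1: decision > 0 => nodule
  fit <- e1071::svm(as.matrix(x), yf, type = "C-classification",
                    kernel = "radial", gamma = gamma, cost = 1,
                    class.weights = c("1" = C_plus, "-1" = C_minus),
                    scale = FALSE)
  structure(list(fit = fit, gamma = gamma, C_minus = C_minus, C_plus = C_plus),
            class = "csvm_model")
}

#' Predict labels and decision values from a trained C-SVM
#' @param object a `csvm_model`.
#' @param newdata normalized feature matrix.
#' @param ... unused.
#' @return list with `label` (+1/-1) and `decision` (positive = nodule side).
#' @export
predict.csvm_model <- function(object, newdata, ...) {
  p <- stats::predict(object$fit, as.matrix(newdata), decision.values = TRUE)
  dv <- unname(drop(attr(p, "decision.values")))
  # e1071 orients the decision value toward the first factor level (+1)
  if (!grepl("^1/", colnames(attr(p, "decision.values"))[1])) dv <- -dv
  list(label = ifelse(dv > 0, 1L, -1L), decision = dv)
}

# Rank-statistic (Mann-Whitney) AUC of decision values.
rank_auc <- function(decision, y) {
  pos <- decision[y == 1L]
  neg <- decision[y == -1L]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Seeded stratified fold assignment.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      i <- which(y == cls)
      folds[i] <- sample(rep_len(seq_len(k), length(i)))
    }
  })
  folds
}

#' Grid search on cross-validated AUC
#'
#' Stratified k-fold CV at every `(C-, gamma)` grid point; the AUC is the
#' rank statistic over the pooled out-of-fold decision values. The selected
#' configuration maximizes AUC, ties broken by the smallest `C-` then the
#' smallest `gamma`.
#'
#' @param x normalized feature table.
#' @param y labels in \{+1, -1\}.
#' @param k folds (>= 2).
#' @param C_grid,gamma_grid parameter grids (powers of two by default).
#' @param seed fold-assignment seed.
#' @return list with `best` (C_minus, gamma), `auc`, and `results` — one row
#'   per grid point with TP/FN/TN/FP, sensitivity, specificity, accuracy,
#'   AUC and the chosen flag.
#' @export
grid_search_auc <- function(x, y, k = 10L, C_grid = 2^(-1:3),
                            gamma_grid = 2^(-3:3), seed = 1L) {
  stopifnot(k >= 2L, length(C_grid) >= 1L, length(gamma_grid) >= 1L)
  y <- as.integer(y)
  x <- as.matrix(x)
  folds <- stratified_folds(y, k, seed)
  for (f in seq_len(k)) {
    if (!any(y[folds == f] == 1L))
      stop("fold ", f, " contains no positives; reduce k or rebalance",
           call. = FALSE)
  }
  grid <- expand.grid(C_minus = C_grid, gamma = gamma_grid)
  res <- lapply(seq_len(nrow(grid)), function(gidx) {
    Cm <- grid$C_minus[gidx]; gm <- grid$gamma[gidx]
    dec <- numeric(length(y))
    lab <- integer(length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- train_csvm(x[tr, , drop = FALSE], y[tr], C_minus = Cm, gamma = gm)
      pr <- predict(fit, x[!tr, , drop = FALSE])
      dec[!tr] <- pr$decision
      lab[!tr] <- pr$label
    }
    TP <- sum(lab == 1L & y == 1L); FN <- sum(lab == -1L & y == 1L)
    TN <- sum(lab == -1L & y == -1L); FP <- sum(lab == 1L & y == -1L)
    cm <- confusion_metrics(TP, FN, TN, FP)
    data.frame(C_minus = Cm, gamma = gm, TP = TP, FN = FN, TN = TN, FP = FP,
               sensitivity = cm["sensitivity"], specificity = cm["specificity"],
               accuracy = cm["accuracy"], AUC = rank_auc(dec, y))
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  best_auc <- max(res$AUC)
  cand <- res[res$AUC >= best_auc - 1e-12, ]
  cand <- cand[order(cand$C_minus, cand$gamma), ]
  res$chosen <- res$C_minus == cand$C_minus[1] & res$gamma == cand$gamma[1]
  list(best = list(C_minus = cand$C_minus[1], gamma = cand$gamma[1]),
       auc = cand$AUC[1], results = res)
}

#' Confusion-matrix summary metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy, rounded
#' to 3 decimals for reporting.
#'
#' @param TP,FN,TN,FP non-negative counts with `TP+FN > 0` and `TN+FP > 0`.
#' @return named numeric of the three ratios.
#' @export
confusion_metrics <- function(TP, FN, TN, FP) {
  stopifnot(TP >= 0, FN >= 0, TN >= 0, FP >= 0)
  if (TP + FN == 0 || TN + FP == 0)
    stop("confusion metrics undefined: empty class", call. = FALSE)
  round(c(sensitivity = TP / (TP + FN),
          specificity = TN / (TN + FP),
          accuracy = (TP + TN) / (TP + FN + TN + FP)), 3)
}
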