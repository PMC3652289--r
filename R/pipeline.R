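# End-to-end orchestration: membership -> FIACM segmentation -> PMM
# refinement of vessel-attached candidates -> features -> knowledge gate ->
# C-SVM -> detection report. Also the phantom study generators used for
# training and desk-scale evaluation.

## --- Phantom study scans ---------------------------------------------------

# One synthetic "scan": a 44 x 44 x 36 voxel grid at 1 mm spacing holding one
# nodule (solid, part-solid, nonsolid or juxtavascular) plus a background
# vessel, with additive noise (SD 25) and a 5% bias field. These are the
# study conditions; see the methods vignette.
#' Generate one phantom study scan
#'
#' @param seed scan seed (drives geometry, noise and bias).
#' @param kind nodule configuration.
#' @param shape,spacing grid geometry.
#' @param noise_sigma,bias_amplitude corruption levels.
#' @return a `labeled_volume`.
#' @export
phantom_scan <- function(seed, kind = c("solid", "part_solid", "nonsolid",
                                        "juxtavascular"),
                         shape = c(44L, 44L, 36L), spacing = c(1, 1, 1),
                         noise_sigma = 25, bias_amplitude = 0.05) {
  kind <- match.arg(kind)
  extent <- shape * spacing
  geom <- with_seed(seed * 2L + 1L, {
    list(center = extent / 2 + stats::runif(3, -4, 4),
         radius = stats::runif(1, if (kind == "nonsolid") 5 else 4,
                               if (kind == "nonsolid") 8 else 7),
         vr = stats::runif(1, 1.5, 2.5),
         voff = stats::runif(1, 8, 12) * sample(c(-1, 1), 1L))
  })
  nod <- nodule_spec(geom$center, geom$radius,
                     kind = if (kind == "juxtavascular") "solid" else kind)
  spec <- phantom_spec(shape, spacing, noise_sigma = noise_sigma,
                       bias_amplitude = bias_amplitude, seed = seed)
  if (kind == "juxtavascular") {
    # vessel tangent to the nodule, running across the grid
    line <- rbind(c(1, geom$center[2] + geom$radius + geom$vr - 0.5, geom$center[3]),
                  c(extent[1] - 1, geom$center[2] + geom$radius + geom$vr - 0.5,
                    geom$center[3]))
    ves <- vessel_spec(line, geom$vr)
    juxtavascular_phantom(nod, ves, spec)
  } else {
    # disjoint background vessel offset from the nodule
    zv <- min(max(geom$center[3] + geom$voff, 3), extent[3] - 3)
    line <- rbind(c(1, extent[2] / 2, zv), c(extent[1] - 1, extent[2] / 2, zv))
    spec$nodules <- list(nod)
    spec$vessels <- list(vessel_spec(line, geom$vr))
    render_phantom(spec)
  }
}

## --- Single-scan detection chain -------------------------------------------

#' Run the detection chain on one volume
#'
#' Stages: fuzzy membership map; adaptive-threshold initialization;
#' posterior edge thresholds; FIACM evolution; candidate extraction; feature
#' extraction; PMM refinement of vessel-attached candidates (with refreshed
#' features); knowledge gate; optional C-SVM classification. Candidates
#' failing the gate or classified negative carry label -1.
#'
#' @param volume `volume_handle`, `labeled_volume` or array.
#' @param model optional classifier bundle from [train_default_model()].
#' @param config pipeline configuration ([default_config()]).
#' @param volume_id scan identifier.
#' @param seed per-scan seed for the stochastic stages.
#' @return list: `candidates`, `features` (data frame), `membership`,
#'   `state`.
#' @export
detect_nodules <- function(volume, model = NULL, config = default_config(),
                           volume_id = "scan", seed = 1L) {
  if (!inherits(volume, "volume_handle")) volume <- as_volume(volume)
  mc <- config$membership
  fc <- config$fiacm
  u <- membership_map(volume, sample_quantile = mc$sample_quantile,
                      clusters = mc$clusters, m = mc$m, seed = seed,
                      curvature_scale = mc$curvature_scale,
                      opening_radius = mc$opening_radius)
  # soften the membership across class boundaries: the evolution needs a
  # fuzzy transition band (u near 0.5) where the evidence is ambiguous
  u_evolve <- gauss_smooth(u$u, mc$evolve_smooth %||% 1.5, volume$spacing)
  init <- initialize_contour(volume, window = fc$init_window,
                             offset = fc$init_offset)
  edge <- estimate_edge_thresholds(volume, smoothing = 1, p_lo = fc$p_lo,
                                   p_hi = fc$p_hi, seed = seed)
  kernel <- kernel_sigma_from_membership(u, sigma_base = fc$sigma_base)
  params <- fiacm_params(mu = fc$mu, lambda1 = fc$lambda1, lambda2 = fc$lambda2,
                         m = fc$m, epsilon = fc$epsilon, tau = fc$tau,
                         max_iter = fc$max_iter, conv_tol = fc$conv_tol)
  state <- fiacm_evolve(volume, u_evolve, init, params, edge, kernel)
  cands <- extract_candidates(state, min_voxels = fc$min_voxels, volume_id)
  rc <- config$refine
  feats <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    fv <- feature_vector(cands[[i]], volume)
    if (needs_refinement(cands[[i]], fv, rc$q_attach, rc$c_attach)) {
      cands[[i]] <- refine_candidate(cands[[i]], volume, u, margin = rc$margin,
                                     M = rc$M,
                                     uniform_density = rc$uniform_density,
                                     tol = rc$tol, max_iter = rc$max_iter,
                                     seed = seed)
      fv <- feature_vector(cands[[i]], volume)
    }
    feats[[i]] <- fv
  }
  rules <- do.call(default_gate_rules, config$gate)
  for (i in seq_along(cands)) {
    if (!gate(feats[[i]], rules)) {
      cands[[i]]$label <- -1L
    } else {
      cands[[i]]$flags <- unique(c(cands[[i]]$flags, "gated"))
    }
  }
  if (!is.null(model)) {
    live <- which(vapply(cands, function(cc) is.na(cc$label) || cc$label != -1L,
                         TRUE))
    if (length(live)) {
      tab <- do.call(rbind, lapply(feats[live], function(f) as.data.frame(t(unclass(f)))))
      xs <- normalize_features(model$train_features, tab)$applied
      pr <- predict(model$model, xs)
      for (k in seq_along(live)) {
        cands[[live[k]]]$label <- pr$label[k]
        cands[[live[k]]]$flags <- unique(c(cands[[live[k]]]$flags, "classified"))
      }
    }
  }
  ftab <- do.call(rbind, lapply(seq_along(cands), function(i) {
    cbind(data.frame(candidate_id = cands[[i]]$id, volume_id = volume_id,
                     label = cands[[i]]$label %||% NA_integer_),
          as.data.frame(t(unclass(feats[[i]]))))
  }))
  list(candidates = cands, features = ftab, membership = u, state = state)
}

## --- Training set and default model ----------------------------------------

#' Build a labelled phantom training set
#'
#' Positive candidates come from single-nodule phantoms (solid, part-solid
#' and nonsolid in rotation), negatives from vessel-only phantoms and from
#' noise blobs, all segmented by the adaptive-threshold initializer so the
#' masks carry realistic segmentation noise.
#'
#' @param n_pos,n_neg candidate counts (>= 30 / >= 100 for a usable model).
#' @param seed master seed.
#' @return data frame: 21 feature columns plus `label` (+1/-1).
#' @export
make_training_set <- function(n_pos = 30L, n_neg = 100L, seed = 1L) {
  kinds <- c("solid", "part_solid", "nonsolid")
  rows <- list()
  grab <- function(vol, want_big, volume_id, take = 1L) {
    init <- initialize_contour(vol, window = 9L, offset = 40)
    cands <- extract_candidates(init, min_voxels = 10L, volume_id)
    if (length(cands) == 0L) return(NULL)
    sizes <- vapply(cands, `[[`, 0L, "n_voxels")
    ord <- order(sizes, decreasing = want_big)
    cands[ord[seq_len(min(take, length(cands)))]]
  }
  for (i in seq_len(n_pos)) {
    vol <- phantom_scan(seed * 1000L + i, kinds[(i - 1L) %% 3L + 1L])
    # nodule-only view: blank the background vessel so the candidate is the nodule
    vol2 <- vol
    vol2$intensity[vol$labels == 2L] <- PHANTOM_DEFAULTS$background
    cc <- grab(as_volume(vol2), want_big = TRUE, paste0("pos", i))
    if (!is.null(cc))
      rows[[length(rows) + 1L]] <-
        cbind(as.data.frame(t(unclass(feature_vector(cc[[1]], as_volume(vol2))))),
              label = 1L)
  }
  i <- 0L
  while (sum(vapply(rows, function(r) r$label == -1L, TRUE)) < n_neg) {
    i <- i + 1L
    vseed <- seed * 2000L + i
    if (i %% 2L == 1L) {
      # vessel fragments
      spec <- with_seed(vseed, {
        extent <- c(44, 44, 36)
        z <- stats::runif(1, 6, 30)
        y <- stats::runif(1, 6, 38)
        phantom_spec(c(44L, 44L, 36L),
                     vessels = list(vessel_spec(
                       rbind(c(1, y, z), c(43, y + stats::runif(1, -8, 8),
                                           z + stats::runif(1, -6, 6))),
                       stats::runif(1, 1.5, 3))),
                     noise_sigma = 25, bias_amplitude = 0.05, seed = vseed)
      })
      vol <- render_phantom(spec)
      cc <- grab(as_volume(vol), want_big = TRUE, paste0("neg", i), take = 2L)
    } else {
      # noise blobs
      spec <- phantom_spec(c(28L, 28L, 24L), noise_sigma = 45,
                           bias_amplitude = 0.05, seed = vseed)
      vol <- render_phantom(spec)
      init <- initialize_contour(as_volume(vol), window = 7L, offset = 30)
      cc <- extract_candidates(init, min_voxels = 5L, paste0("neg", i))
      if (length(cc) > 2L) cc <- cc[1:2]
    }
    if (is.null(cc) || length(cc) == 0L) next
    for (one in cc)
      rows[[length(rows) + 1L]] <-
        cbind(as.data.frame(t(unclass(feature_vector(one, as_volume(vol))))),
              label = -1L)
    if (i > 10L * n_neg) break # safety
  }
  df <- do.call(rbind, rows)
  neg <- which(df$label == -1L)
  if (length(neg) > n_neg) df <- df[-neg[-seq_len(n_neg)], ]
  rownames(df) <- NULL
  df
}

#' Train the default phantom classifier
#'
#' Normalizes the training features to \[0, 1\], grid-searches (C-, gamma)
#' by stratified-CV AUC, then fits the final cost-sensitive SVM with the
#' selected configuration on the full set.
#'
#' @param training data frame from [make_training_set()] (built at `seed`
#'   when omitted).
#' @param seed RNG seed.
#' @param k,C_grid,gamma_grid grid-search settings.
#' @return classifier bundle: `model`, `train_features`, `search`.
#' @export
train_default_model <- function(training = NULL, seed = 1L, k = 5L,
                                C_grid = 2^(-1:3), gamma_grid = 2^(-3:3)) {
  if (is.null(training)) training <- make_training_set(seed = seed)
  y <- training$label
  x <- training[setdiff(names(training), "label")]
  xs <- normalize_features(x)$train
  search <- grid_search_auc(xs, y, k = k, C_grid = C_grid,
                            gamma_grid = gamma_grid, seed = seed)
  model <- train_csvm(xs, y, C_minus = search$best$C_minus,
                      gamma = search$best$gamma)
  list(model = model, train_features = x, search = search)
}

## --- Study driver and pipeline entry ---------------------------------------

#' Run the desk-scale phantom detection study
#'
#' Generates `n_scans` phantom scans cycling through solid, part-solid,
#' nonsolid and juxtavascular configurations, runs the full chain on each
#' with the supplied (or freshly trained) model, and aggregates detection
#' rate, FPs/scan and the mean Jaccard error of matched nodules.
#'
#' @param n_scans number of scans.
#' @param seed master seed.
#' @param model classifier bundle ([train_default_model()]); trained at
#'   `seed` when omitted.
#' @param config pipeline configuration.
#' @return list: combined `report`, per-scan `reports`, `scan_kinds`.
#' @export
run_detection_study <- function(n_scans = 10L, seed = 1L, model = NULL,
                                config = default_config()) {
  if (is.null(model)) model <- train_default_model(seed = seed)
  kinds <- rep_len(c("solid", "juxtavascular", "nonsolid", "part_solid"), n_scans)
  reports <- vector("list", n_scans)
  for (s in seq_len(n_scans)) {
    truth <- phantom_scan(seed * 100L + s, kinds[s])
    res <- detect_nodules(truth, model = model, config = config,
                          volume_id = paste0("scan", s), seed = seed * 100L + s)
    reports[[s]] <- match_detections(res$candidates, truth,
                                     overlap_min = config$evaluate$overlap_min)
  }
  list(report = combine_reports(reports), reports = reports, scan_kinds = kinds)
}

#' Run the pipeline from a configuration file
#'
#' The configuration (YAML, see [default_config()]) either lists `scans`
#' (volume paths) or a `study` section (phantom scan count); artifacts —
#' resolved configuration, per-scan candidate tables and masks, and the JSON
#' detection report — are written under `output_dir`. Fully reproducible
#' from the configuration and its seed.
#'
#' @param config path to a YAML configuration or a configuration list.
#' @param output_dir artifact directory (config `output_dir` by default).
#' @return the combined `detection_report` (invisibly the full result list).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  out <- output_dir %||% cfg$output_dir %||% stop("no output_dir configured")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- run_log(file.path(out, "run.log"))
  write_config(cfg, file.path(out, "config_resolved.yaml"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  model <- stage("classify", {
    if (!is.null(cfg$model_path)) {
      if (!file.exists(cfg$model_path))
        stop("model file not found: ", cfg$model_path)
      readRDS(cfg$model_path)
    } else {
      log("classify", "training default phantom model")
      m <- train_default_model(seed = cfg$seed,
                               k = min(cfg$classify$k, 5L),
                               C_grid = cfg$classify$C_grid,
                               gamma_grid = cfg$classify$gamma_grid)
      saveRDS(m, file.path(out, "model.rds"))
      utils::write.csv(m$search$results, file.path(out, "cv_report.csv"),
                       row.names = FALSE)
      m
    }
  })
  reports <- list()
  if (!is.null(cfg$scans)) {
    for (s in seq_along(cfg$scans)) {
      id <- paste0("scan", s)
      log(id, paste("reading", cfg$scans[[s]]))
      vol <- stage("read", read_volume(cfg$scans[[s]]))
      res <- stage("segment", detect_nodules(vol, model = model, config = cfg,
                                             volume_id = id,
                                             seed = cfg$seed + s))
      write_candidates(res$candidates, file.path(out, paste0(id, "_candidates.csv")),
                       ref = vol)
      utils::write.csv(res$features, file.path(out, paste0(id, "_features.csv")),
                       row.names = FALSE)
    }
  } else {
    n <- cfg$study$n_scans %||% 10L
    study <- stage("segment", run_detection_study(n, seed = cfg$seed,
                                                  model = model, config = cfg))
    reports <- study$reports
    for (s in seq_along(reports)) log(paste0("scan", s), sprintf(
      "%d/%d detected, %d FP", reports[[s]]$detected,
      reports[[s]]$total_nodules, reports[[s]]$fp))
  }
  combined <- if (length(reports)) combine_reports(reports) else NULL
  if (!is.null(combined)) {
    jsonlite::write_json(
      list(total_nodules = combined$total_nodules, detected = combined$detected,
           detection_rate_pct = combined$detection_rate_pct,
           fp_per_scan = combined$fp_per_scan,
           mean_jaccard = combined$mean_jaccard, n_scans = combined$n_scans),
      file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
    log("evaluate", sprintf("detection rate %.1f%%, %.2f FPs/scan",
                            combined$detection_rate_pct, combined$fp_per_scan))
  }
  invisible(list(report = combined, reports = reports, output_dir = out))
}
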