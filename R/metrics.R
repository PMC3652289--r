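# Segmentation and detection evaluation: Tanimoto/Jaccard error between a
# computed and a reference mask, and the detection-rate / FPs-per-scan
# bookkeeping over candidate lists.

#' Tanimoto/Jaccard segmentation error
#'
#' `A(Cm, Co) = 1 - |Cm intersect Co| / |Cm union Co|` on voxel counts:
#' 0 iff the (nonempty) masks coincide, 1 iff they are disjoint.
#'
#' @param mask_m,mask_o binary arrays of identical shape, union nonempty.
#' @return a `seg_score`: `jaccard_error`, `intersection`, `union`.
#' @export
jaccard_error <- function(mask_m, mask_o) {
  m <- as_vol3d(mask_m) != 0
  o <- as_vol3d(mask_o) != 0
  if (!identical(dim(m), dim(o))) stop("mask shapes differ", call. = FALSE)
  uni <- sum(m | o)
  if (uni == 0L) stop("both masks are empty", call. = FALSE)
  int <- sum(m & o)
  structure(list(jaccard_error = 1 - int / uni, intersection = int, union = uni),
            class = "seg_score")
}

# Truth nodule instances: connected components of labels {1, 3} (the
# attachment zone belongs to the nodule ground truth).
truth_nodule_masks <- function(truth) {
  stopifnot(inherits(truth, "labeled_volume"))
  lab <- label_components(truth$labels == 1L | truth$labels == 3L, 26L)
  lapply(setdiff(unique(as.vector(lab)), 0L), function(i) lab == i)
}

#' Match positive candidates against ground-truth nodules
#'
#' A truth nodule is detected iff some positively classified candidate
#' overlaps at least `overlap_min` of its volume; matching is greedy by
#' overlap and one-to-one. Unmatched positive candidates count as false
#' positives. Candidates explicitly labelled -1 are ignored; unlabelled
#' candidates are treated as positives.
#'
#' @param candidates list of `candidate_record`s with masks.
#' @param truth a `labeled_volume`.
#' @param overlap_min required fraction of the truth nodule, in (0, 1].
#' @return a `detection_report` for one scan, including per-nodule Jaccard
#'   errors of the matched candidates.
#' @export
match_detections <- function(candidates, truth, overlap_min = 0.25) {
  stopifnot(overlap_min > 0, overlap_min <= 1)
  nodules <- truth_nodule_masks(truth)
  pos <- Filter(function(cc) is.na(cc$label) || cc$label != -1, candidates)
  n_nod <- length(nodules)
  if (length(pos) == 0L || n_nod == 0L) {
    return(detection_report(total = n_nod, detected = 0L, fp = length(pos),
                            n_scans = 1L, n_candidates = length(candidates)))
  }
  ov <- matrix(0, length(pos), n_nod)
  for (i in seq_along(pos)) for (j in seq_len(n_nod))
    ov[i, j] <- sum(pos[[i]]$mask & nodules[[j]]) / sum(nodules[[j]])
  matched_c <- logical(length(pos))
  matched_n <- logical(n_nod)
  jac <- rep(NA_real_, n_nod)
  ord <- order(ov, decreasing = TRUE)
  for (lin in ord) {
    if (ov[lin] < overlap_min) break
    i <- (lin - 1L) %% length(pos) + 1L
    j <- (lin - 1L) %/% length(pos) + 1L
    if (matched_c[i] || matched_n[j]) next
    matched_c[i] <- TRUE
    matched_n[j] <- TRUE
    jac[j] <- jaccard_error(pos[[i]]$mask, nodules[[j]])$jaccard_error
  }
  detection_report(total = n_nod, detected = sum(matched_n),
                   fp = sum(!matched_c), n_scans = 1L,
                   n_candidates = length(candidates), jaccard = jac)
}

#' Detection report bookkeeping
#'
#' @param total,detected truth-nodule counts.
#' @param fp false-positive count.
#' @param n_scans scan count (for FPs/scan).
#' @param n_candidates raw candidate count.
#' @param jaccard per-nodule Jaccard errors of matched candidates.
#' @return a `detection_report`; `detection_rate_pct` is reported in percent
#'   to one decimal.
#' @export
detection_report <- function(total, detected, fp, n_scans = 1L,
                             n_candidates = NA_integer_, jaccard = numeric(0)) {
  structure(list(
    total_nodules = total, detected = detected, fp = fp, n_scans = n_scans,
    n_candidates = n_candidates,
    detection_rate = if (total > 0) detected / total else NA_real_,
    detection_rate_pct = if (total > 0) round(100 * detected / total, 1) else NA_real_,
    fp_per_scan = fp / n_scans,
    jaccard = jaccard,
    mean_jaccard = if (any(!is.na(jaccard))) mean(jaccard, na.rm = TRUE) else NA_real_
  ), class = "detection_report")
}

#' Combine per-scan detection reports
#' @param reports list of `detection_report`s.
#' @export
combine_reports <- function(reports) {
  detection_report(
    total = sum(vapply(reports, `[[`, 0, "total_nodules")),
    detected = sum(vapply(reports, `[[`, 0, "detected")),
    fp = sum(vapply(reports, `[[`, 0, "fp")),
    n_scans = sum(vapply(reports, `[[`, 0, "n_scans")),
    n_candidates = sum(vapply(reports, function(r) r$n_candidates %||% 0L, 0L)),
    jaccard = unlist(lapply(reports, `[[`, "jaccard"))
  )
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("detection_report: %d/%d nodules detected (%.1f%%), %.1f FPs/scan over %d scan(s)\n",
              x$detected, x$total_nodules, x$detection_rate_pct %||% NA,
              x$fp_per_scan, x$n_scans))
  if (any(!is.na(x$jaccard)))
    cat(sprintf("  mean Jaccard error of matched nodules: %.3f\n", x$mean_jaccard))
  invisible(x)
}
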