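# The 21-descriptor candidate feature catalogue: intensity (4), position
# (1), 2-D and 3-D shape (12) and co-occurrence texture (4). 2-D features
# run on the candidate's largest-area axial slice (largest in-slice
# component); 3-D features on the full mask in mm.

# Clockwise sweep of the 8 Freeman codes in image coordinates (row down):
# E, SE, S, SW, W, NW, N, NE.
CW_CODES <- c(0L, 7L, 6L, 5L, 4L, 3L, 2L, 1L)
CODE_DR <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)   # row step for code 0..7
CODE_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)   # col step for code 0..7

single_component_2d <- function(mask2d) {
  m3 <- mask2d
  dim(m3) <- c(dim(mask2d), 1L)
  lab <- label_components(m3, 26L)[, , 1L]
  n <- max(lab)
  if (n == 0L) stop("empty mask", call. = FALSE)
  if (n > 1L) stop("mask has more than one 8-connected component", call. = FALSE)
  invisible(TRUE)
}

#' Trace the boundary chain code of a 2-D mask
#'
#' Moore boundary tracing, clockwise, starting from the top-left foreground
#' pixel (smallest row, then smallest column); 8-connectivity Freeman codes
#' 0-7 (0 = east, counterclockwise numbering). A single pixel yields an
#' empty code sequence.
#'
#' @param mask2d logical matrix with exactly one 8-connected component.
#' @return a `chain_code`: `start` (row, col), `codes`, and the even/odd
#'   counts `n_e` / `n_o`.
#' @export
trace_chain_code <- function(mask2d) {
  mask2d <- as.matrix(mask2d) != 0
  single_component_2d(mask2d)
  nr <- nrow(mask2d); nc <- ncol(mask2d)
  fg <- which(mask2d, arr.ind = TRUE)
  fg <- fg[order(fg[, 1], fg[, 2]), , drop = FALSE]
  start <- fg[1L, ]
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask2d[r, c]
  if (sum(mask2d) == 1L)
    return(structure(list(start = start, codes = integer(0), n_e = 0L, n_o = 0L),
                     class = "chain_code"))
  codes <- integer(0)
  P <- start
  back_code <- 4L # backtrack pixel = west of start (background by start choice)
  first_move <- NA_integer_
  guard <- 8L * sum(mask2d) + 8L
  repeat {
    sweep_from <- match(back_code, CW_CODES) %% 8L + 1L
    found <- NA_integer_
    for (s in 0:7) {
      pos <- (sweep_from - 1L + s) %% 8L + 1L
      code <- CW_CODES[pos]
      r <- P[1] + CODE_DR[code + 1L]; c <- P[2] + CODE_DC[code + 1L]
      if (inside(r, c)) {
        found <- code
        prev_pos <- (pos - 2L) %% 8L + 1L
        back_code <- CW_CODES[prev_pos]
        P <- c(r, c)
        break
      }
    }
    if (is.na(found)) break # isolated after all (cannot happen past the 1-pixel case)
    codes <- c(codes, found)
    if (is.na(first_move)) first_move <- found
    if (all(P == start) && length(codes) > 1L) {
      # Jacob's criterion: stop once the start is re-entered and the next
      # move would repeat the first
      sweep_from2 <- match(back_code, CW_CODES) %% 8L + 1L
      nxt <- NA_integer_
      for (s in 0:7) {
        pos <- (sweep_from2 - 1L + s) %% 8L + 1L
        code <- CW_CODES[pos]
        r <- P[1] + CODE_DR[code + 1L]; c <- P[2] + CODE_DC[code + 1L]
        if (inside(r, c)) { nxt <- code; break }
      }
      if (is.na(nxt) || nxt == first_move) break
    }
    if (length(codes) > guard) break
  }
  n_e <- sum(codes %% 2L == 0L)
  structure(list(start = start, codes = codes, n_e = n_e,
                 n_o = length(codes) - n_e),
            class = "chain_code")
}

#' Perimeter from a chain code
#'
#' Axis moves (even codes) count 1 pixel side, diagonal moves (odd codes)
#' `sqrt(2)`; the degenerate single-pixel code counts the 4 sides of the
#' pixel.
#' @param code a `chain_code`.
#' @export
chain_perimeter <- function(code) {
  stopifnot(inherits(code, "chain_code"))
  if (length(code$codes) == 0L) return(4)
  code$n_e + sqrt(2) * code$n_o
}

#' 2-D shape descriptors of a single-component mask
#'
#' Area, centroid, moment-based long/short axes and ellipticity,
#' inscribed/circumscribed-circle circularity, slenderness, rectangle
#' degree, chain-code compactness and convex-hull concavity ratio. Second
#' moments include the 1/12 unit-square pixel term so degenerate masks stay
#' finite.
#'
#' @param mask2d logical matrix, one 8-connected component.
#' @return named list of descriptors (see the feature catalogue).
#' @export
shape_features_2d <- function(mask2d) {
  mask2d <- as.matrix(mask2d) != 0
  single_component_2d(mask2d)
  px <- which(mask2d, arr.ind = TRUE)
  A <- nrow(px)
  i0 <- mean(px[, 1]); j0 <- mean(px[, 2])
  di <- px[, 1] - i0; dj <- px[, 2] - j0
  mu20 <- sum(di^2) + A / 12
  mu02 <- sum(dj^2) + A / 12
  mu11 <- sum(di * dj)
  root <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  long_axis <- 2 * sqrt(2 * (mu20 + mu02 + root) / A)
  short_axis <- 2 * sqrt(pmax(2 * (mu20 + mu02 - root) / A, 1e-12))
  cc <- trace_chain_code(mask2d)
  L <- chain_perimeter(cc)
  # the region contour runs half a pixel outside the centre path; a closed
  # convex offset adds exactly pi * h, which keeps compactness of rasterized
  # discs near 1 instead of overshooting
  L_contour <- if (length(cc$codes) == 0L) 4 else L + pi
  # inscribed radius: largest distance from a foreground pixel to background
  bg <- which(!mask2d, arr.ind = TRUE)
  r_i <- if (nrow(bg) == 0L) max(dim(mask2d)) / 2 else {
    best <- 0
    for (chunk in split(seq_len(nrow(px)), ceiling(seq_len(nrow(px)) / 256))) {
      d2 <- outer(px[chunk, 1], bg[, 1], `-`)^2 + outer(px[chunk, 2], bg[, 2], `-`)^2
      best <- max(best, sqrt(apply(d2, 1L, min)))
    }
    best
  }
  r_c <- max(sqrt(di^2 + dj^2)) + 0.5
  W <- diff(range(px[, 2])) + 1L
  H <- diff(range(px[, 1])) + 1L
  hull_area <- if (A >= 3L) {
    h <- grDevices::chull(px[, 2], px[, 1])
    xh <- px[h, 2]; yh <- px[h, 1]
    abs(sum(xh * c(yh[-1], yh[1]) - c(xh[-1], xh[1]) * yh)) / 2
  } else 0
  list(
    area = A,
    centroid = c(i0, j0),
    perimeter = L,
    diameter = long_axis,
    ellipticity = long_axis / short_axis,
    circularity = min(r_i / r_c, 1),
    slenderness = min(W, H) / max(W, H),
    rectangle_degree = A / (W * H),
    compactness = 4 * pi * A / L_contour^2,
    concavity_ratio = max(0, hull_area - A) / A
  )
}

#' 3-D shape descriptors
#'
#' Volume (mm^3), the long axis (maximal pairwise extent of the boundary
#' voxels, mm) and the volumetric quotient — volume over the volume of the
#' circumsphere whose radius is half the long axis, clamped to 1. Spheres
#' score near 1, tubes far below.
#'
#' @param mask3d logical array.
#' @param spacing voxel spacing (mm).
#' @export
shape_features_3d <- function(mask3d, spacing = c(1, 1, 1)) {
  mask3d <- as_vol3d(mask3d) != 0
  n <- sum(mask3d)
  if (n == 0L) stop("empty mask", call. = FALSE)
  vol <- n * prod(spacing)
  if (n == 1L)
    return(list(volume = vol, long_axis_3d = prod(spacing)^(1 / 3),
                volumetric_quotient = 1))
  # boundary voxels: any 6-neighbour outside the mask (or the grid)
  interior <- mask3d
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    off <- c(0L, 0L, 0L); off[ax] <- s
    interior <- interior & shift_arr(mask3d, off, pad = 0)
  }
  bd <- which(mask3d & !interior, arr.ind = TRUE)
  if (nrow(bd) == 0L) bd <- which(mask3d, arr.ind = TRUE)
  pts <- sweep(bd, 2L, spacing, `*`)
  longest <- 0
  for (chunk in split(seq_len(nrow(pts)), ceiling(seq_len(nrow(pts)) / 128))) {
    d2 <- outer(pts[chunk, 1], pts[, 1], `-`)^2 +
      outer(pts[chunk, 2], pts[, 2], `-`)^2 +
      outer(pts[chunk, 3], pts[, 3], `-`)^2
    longest <- max(longest, sqrt(max(d2)))
  }
  longest <- longest + 0.5 * mean(spacing) # half-voxel beyond the centres,
  # balancing the slight volume overshoot of occupancy-counted masks
  q <- min(vol / ((4 / 3) * pi * (longest / 2)^3), 1)
  list(volume = vol, long_axis_3d = longest, volumetric_quotient = q)
}

#' Gray-level co-occurrence texture descriptors
#'
#' Intensities under the mask are quantized to `levels` gray levels; for
#' each offset the co-occurrence matrix over in-mask pixel pairs is
#' symmetrized and normalized, matrices are averaged over the offsets, and
#' energy, contrast, entropy (natural log, 0 log 0 = 0) and the inverse
#' difference moment are read off.
#'
#' @param image2d numeric matrix.
#' @param mask2d logical matrix, >= 2 pixels.
#' @param levels number of gray levels (>= 2).
#' @param offsets list of integer (row, col) offsets; default the 4
#'   distance-1 directions.
#' @export
texture_features <- function(image2d, mask2d, levels = 32L,
                             offsets = list(c(0L, 1L), c(1L, 0L),
                                            c(1L, 1L), c(1L, -1L))) {
  stopifnot(levels >= 2L)
  image2d <- as.matrix(image2d)
  mask2d <- as.matrix(mask2d) != 0
  if (sum(mask2d) < 2L) stop("mask smaller than 2 pixels", call. = FALSE)
  vals <- image2d[mask2d]
  rng <- range(vals)
  q <- if (diff(rng) == 0) array(1L, dim(image2d)) else
    pmin(1L + floor((image2d - rng[1]) / diff(rng) * levels), levels)
  nr <- nrow(image2d); nc <- ncol(image2d)
  P <- matrix(0, levels, levels)
  used <- 0L
  for (off in offsets) {
    r1 <- seq_len(nr - abs(off[1]))
    if (off[1] < 0) r1 <- r1 + abs(off[1])
    c1 <- seq_len(nc - abs(off[2]))
    if (off[2] < 0) c1 <- c1 + abs(off[2])
    i1 <- as.matrix(expand.grid(r = r1, c = c1))
    i2 <- cbind(i1[, 1] + off[1], i1[, 2] + off[2])
    ok <- mask2d[i1] & mask2d[i2]
    if (!any(ok)) next
    g1 <- q[i1[ok, , drop = FALSE]]
    g2 <- q[i2[ok, , drop = FALSE]]
    Po <- matrix(tabulate(g1 + (g2 - 1L) * levels, nbins = levels^2),
                 levels, levels)
    Po <- Po + t(Po) # symmetrize
    P <- P + Po / sum(Po)
    used <- used + 1L
  }
  if (used == 0L) stop("no in-mask pixel pairs for any offset", call. = FALSE)
  P <- P / used
  ij <- outer(seq_len(levels), seq_len(levels), `-`)
  ent_terms <- ifelse(P > 0, -P * log(P), 0)
  list(energy = sum(P^2), contrast = sum(ij^2 * P), entropy = sum(ent_terms),
       idm = sum(P / (1 + ij^2)))
}

#' The 21-descriptor feature vector of a candidate
#'
#' Intensity mean/SD in 2-D (largest-area axial slice, largest in-slice
#' component) and 3-D; one position scalar (distance of the 3-D centroid
#' from the volume centre, mm); twelve 2-D/3-D shape descriptors; four
#' texture descriptors. Always exactly 21 finite values.
#'
#' @param candidate a `candidate_record` with its mask.
#' @param volume `volume_handle`, `labeled_volume` or array.
#' @param levels GLCM gray levels.
#' @return a named `feature_vector` of length 21.
#' @export
feature_vector <- function(candidate, volume, levels = 32L) {
  if (!inherits(volume, "volume_handle")) volume <- as_volume(volume)
  I <- volume$intensity
  mask <- candidate$mask
  stopifnot(identical(dim(mask), dim(I)), sum(mask) > 0)
  sp <- volume$spacing
  slice_counts <- apply(mask, 3L, sum)
  z <- which.max(slice_counts)
  m2 <- mask[, , z]
  lab <- label_components(array(m2, c(dim(m2), 1L)), 26L)[, , 1L]
  if (max(lab) > 1L) {
    keep <- which.max(tabulate(lab[lab > 0L]))
    m2 <- lab == keep
  }
  i2 <- I[, , z]
  vals2 <- i2[m2]
  vals3 <- I[mask]
  sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)
  ctr <- which(mask, arr.ind = TRUE)
  centroid_mm <- colMeans(sweep(ctr, 2L, sp, `*`))
  center_mm <- dim(I) * sp / 2
  s2 <- shape_features_2d(m2)
  s3 <- shape_features_3d(mask, sp)
  tx <- if (sum(m2) >= 2L) texture_features(i2, m2, levels) else
    list(energy = 1, contrast = 0, entropy = 0, idm = 1)
  out <- c(
    mean2d = mean(vals2), sd2d = sd0(vals2),
    mean3d = mean(vals3), sd3d = sd0(vals3),
    position = sqrt(sum((centroid_mm - center_mm)^2)),
    area = s2$area, perimeter = s2$perimeter, diameter = s2$diameter,
    ellipticity = s2$ellipticity, circularity = s2$circularity,
    slenderness = s2$slenderness, rectangle_degree = s2$rectangle_degree,
    compactness = s2$compactness, concavity_ratio = s2$concavity_ratio,
    volume = s3$volume, volumetric_quotient = s3$volumetric_quotient,
    long_axis_3d = s3$long_axis_3d,
    energy = tx$energy, contrast = tx$contrast, entropy = tx$entropy,
    idm = tx$idm
  )
  structure(out, class = c("feature_vector", "numeric"))
}

#' Feature table over a candidate list
#'
#' @param candidates list of `candidate_record`s.
#' @param volume the scan they were segmented from.
#' @return data frame, one row per candidate, stable column names.
#' @export
feature_table <- function(candidates, volume, levels = 32L) {
  rows <- lapply(candidates, function(cand) {
    fv <- feature_vector(cand, volume, levels)
    cbind(data.frame(candidate_id = cand$id, volume_id = cand$volume_id),
          as.data.frame(t(unclass(fv))))
  })
  do.call(rbind, rows)
}
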