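# Internal array helpers shared by all stages. Volumes are plain 3-D numeric
# arrays (2-D inputs are carried as single-slice volumes); spacing is mm/voxel.

#' @importFrom mclust Mclust mclustBIC
#' @importFrom stats predict
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
as_vol3d <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("expected a 2-D or 3-D array", call. = FALSE)
  x
}

#' @noRd
gauss_kernel1d <- function(sigma, truncate = 3) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve along one axis with an odd-length kernel, zero padding, via a band
# matrix product; cheap for the grid sizes used here.
#' @noRd
conv_axis <- function(a, k, axis) {
  d <- dim(a)
  n <- d[axis]
  if (length(k) == 1L) return(a * k)
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n)
    j <- idx + off
    ok <- j >= 1L & j <= n
    K[cbind(idx[ok], j[ok])] <- k[off + r + 1L]
  }
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- aperm(a, perm)
  dm <- dim(m)
  dim(m) <- c(n, prod(dm[-1L]))
  m <- K %*% m
  dim(m) <- dm
  aperm(m, order(perm))
}

# Separable Gaussian smoothing; sigma in mm, converted per-axis by the voxel
# spacing. Renormalized against a smoothed unit volume so borders and
# constants are preserved exactly.
#' @noRd
gauss_smooth <- function(a, sigma, spacing = c(1, 1, 1), renormalize = TRUE) {
  a <- as_vol3d(a)
  if (sigma <= 0) return(a)
  out <- a
  ones <- array(1, dim(a))
  for (ax in 1:3) {
    if (dim(a)[ax] == 1L) next
    k <- gauss_kernel1d(sigma / spacing[ax])
    out <- conv_axis(out, k, ax)
    ones <- conv_axis(ones, k, ax)
  }
  if (renormalize) out / ones else out
}

# Raw (zero-padded, un-renormalized) separable convolution with a discretely
# normalized Gaussian; used where numerator and denominator share the kernel.
#' @noRd
gauss_conv_raw <- function(a, sigma_vox, truncate = 3) {
  a <- as_vol3d(a)
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) {
    if (dim(a)[ax] == 1L) next
    a <- conv_axis(a, gauss_kernel1d(sigma_vox[ax], truncate), ax)
  }
  a
}

# Central differences (one-sided at the borders), spacing-aware.
#' @noRd
grad_axis <- function(a, axis, h = 1) {
  d <- dim(a)
  n <- d[axis]
  if (n == 1L) return(array(0, d))
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  sel <- function(ord) {
    idx <- rep(list(quote(expr = )), 3L)
    idx[[axis]] <- ord
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  den <- (ip - im) * h
  perm <- c(axis, setdiff(1:3, axis))
  den_arr <- aperm(array(den, d[perm]), order(perm))
  (sel(ip) - sel(im)) / den_arr
}

#' @noRd
shift_arr <- function(a, s, pad = 0) {
  d <- dim(a)
  out <- array(pad, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]
    if (abs(s[ax]) >= n) return(out)
    if (s[ax] >= 0) {
      dst[[ax]] <- (1L + s[ax]):n
      src[[ax]] <- 1L:(n - s[ax])
    } else {
      dst[[ax]] <- 1L:(n + s[ax])
      src[[ax]] <- (1L - s[ax]):n
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Voxel-centre world coordinates (mm), 0-based indexing convention:
# coordinate of index i (1-based R index) is (i - 0.5) * spacing.
#' @noRd
vox_coords <- function(dm, spacing) {
  list(
    x = array(rep((seq_len(dm[1]) - 0.5) * spacing[1], times = dm[2] * dm[3]), dm),
    y = array(rep(rep((seq_len(dm[2]) - 0.5) * spacing[2], each = dm[1]), times = dm[3]), dm),
    z = array(rep((seq_len(dm[3]) - 0.5) * spacing[3], each = dm[1] * dm[2]), dm)
  )
}

# Connected components of a logical 3-D mask, 26- or 6-connectivity,
# via igraph on the foreground voxels. Returns an integer array (0 = bg).
#' @noRd
label_components <- function(mask, connectivity = 26L) {
  mask <- as_vol3d(mask)
  d <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, d)
  if (length(fg) == 0L) return(lab)
  pos <- arrayInd(fg, d)
  id <- array(0L, d)
  id[fg] <- seq_along(fg)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1L, , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(pos, 2L, offs[r, ], `+`)
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
      nb[, 3] >= 1L & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    nb_id <- id[nb_lin]
    hit <- nb_id > 0L
    if (any(hit)) edges[[r]] <- cbind(which(ok)[hit], nb_id[hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

# Fill enclosed background cavities: background components (6-connectivity)
# not touching the grid border become foreground.
#' @noRd
fill_holes <- function(mask) {
  mask <- as_vol3d(mask) != 0
  lab <- label_components(!mask, 6L)
  d <- dim(mask)
  border <- unique(c(
    lab[c(1L, d[1]), , ], lab[, c(1L, d[2]), ],
    if (d[3] > 1L) lab[, , c(1L, d[3])]))
  hole <- array(as.vector(lab) != 0L &
                  !(as.vector(lab) %in% setdiff(border, 0L)), d)
  mask | hole
}

#' @noRd
bbox_of <- function(mask) {
  idx <- which(as_vol3d(mask), arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no bounding box", call. = FALSE)
  lo <- apply(idx, 2L, min)
  hi <- apply(idx, 2L, max)
  # half-open, 0-based: [lo-1, hi)
  list(lo = as.integer(lo - 1L), hi = as.integer(hi))
}

#' @noRd
crop_bbox <- function(a, bb, margin = 0L) {
  d <- dim(a)
  lo <- pmax(bb$lo + 1L - margin, 1L)
  hi <- pmin(bb$hi + margin, d)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
}

#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
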