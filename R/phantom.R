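# Synthetic CT phantoms: spherical nodules (solid / part-solid / nonsolid),
# tubular vessels, juxtavascular attachments, Gaussian noise and a smooth
# multiplicative bias field, each with a ground-truth label volume.
# Labels: 0 background, 1 nodule, 2 vessel, 3 attachment zone.

# Default contrast scale (HU-like): lung background -900, solid nodules and
# vessels +400 above a notional 0, nonsolid (GGO) +120 so they stay faint.
PHANTOM_DEFAULTS <- list(
  background = -900, solid_peak = 400, nonsolid_peak = 120, vessel_intensity = 400
)

#' Specify a spherical nodule for the phantom generator
#'
#' @param center numeric length-3, world coordinates of the centre (mm).
#' @param radius sphere radius (mm), > 0.
#' @param kind one of `"solid"`, `"part_solid"`, `"nonsolid"`. Part-solid
#'   nodules have a solid core of half the radius surrounded by a faint
#'   (ground-glass) halo; nonsolid nodules are entirely faint.
#' @param peak_intensity peak contrast above the notional soft-tissue zero.
#'   Defaults to +400 for solid/part-solid and +120 for nonsolid.
#' @param edge_softness Gaussian falloff length (mm) beyond the radius, >= 0.
#' @return an object of class `nodule_spec`.
#' @export
nodule_spec <- function(center, radius, kind = c("solid", "part_solid", "nonsolid"),
                        peak_intensity = NULL, edge_softness = 1) {
  kind <- match.arg(kind)
  stopifnot(length(center) == 3L, is.numeric(center), radius > 0, edge_softness >= 0)
  if (is.null(peak_intensity)) {
    peak_intensity <- if (kind == "nonsolid") PHANTOM_DEFAULTS$nonsolid_peak else
      PHANTOM_DEFAULTS$solid_peak
  }
  if (kind == "nonsolid" && peak_intensity >= PHANTOM_DEFAULTS$solid_peak)
    stop("nonsolid (GGO) nodules must be fainter than the solid default", call. = FALSE)
  structure(list(center = as.numeric(center), radius = radius, kind = kind,
                 peak_intensity = peak_intensity, edge_softness = edge_softness),
            class = "nodule_spec")
}

#' Specify a tubular vessel for the phantom generator
#'
#' The vessel is a tube around the piecewise-linearly interpolated centerline,
#' with a per-control-point radius profile.
#'
#' @param centerline numeric matrix, one control point per row (mm), >= 2 rows.
#' @param radius_profile radii at the control points (mm), recycled to the
#'   number of control points; all > 0.
#' @param intensity tube contrast (defaults to the solid-nodule level, the
#'   similar-intensity premise of juxtavascular cases).
#' @param edge_softness Gaussian falloff length (mm).
#' @return an object of class `vessel_spec`.
#' @export
vessel_spec <- function(centerline, radius_profile,
                        intensity = PHANTOM_DEFAULTS$vessel_intensity,
                        edge_softness = 0.5) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2L || ncol(centerline) != 3L)
    stop("centerline needs >= 2 control points with 3 coordinates each", call. = FALSE)
  radius_profile <- rep_len(as.numeric(radius_profile), nrow(centerline))
  if (any(radius_profile <= 0)) stop("all vessel radii must be > 0", call. = FALSE)
  structure(list(centerline = centerline, radius_profile = radius_profile,
                 intensity = intensity, edge_softness = edge_softness),
            class = "vessel_spec")
}

#' Specify a complete phantom scene
#'
#' @param shape integer length-3 grid size (voxels).
#' @param spacing numeric length-3 voxel spacing (mm), all > 0.
#' @param nodules list of [nodule_spec()] objects.
#' @param vessels list of [vessel_spec()] objects.
#' @param noise_sigma additive Gaussian noise SD (intensity units), >= 0.
#' @param bias_amplitude strength of the smooth multiplicative bias field
#'   (0 disables it; must be < 1 so the field stays strictly positive).
#' @param background background intensity.
#' @param seed integer; rendering is deterministic given the seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing = c(1, 1, 1), nodules = list(),
                         vessels = list(), noise_sigma = 0, bias_amplitude = 0,
                         background = PHANTOM_DEFAULTS$background, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), length(spacing) == 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive", call. = FALSE)
  stopifnot(noise_sigma >= 0, bias_amplitude >= 0, bias_amplitude < 1)
  if (inherits(nodules, "nodule_spec")) nodules <- list(nodules)
  if (inherits(vessels, "vessel_spec")) vessels <- list(vessels)
  structure(list(shape = shape, spacing = as.numeric(spacing), nodules = nodules,
                 vessels = vessels, noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude, background = background,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Half-maximum extension of a soft edge: the object's spatial support is
# taken where its contrast is at least half the peak, i.e. out to
# radius + sqrt(2 ln 2) * edge_softness (FWHM convention). Ground-truth
# labels use this extended radius; intensity uses the nominal one.
fwhm_extension <- function(struct) {
  sqrt(2 * log(2)) * struct$edge_softness
}

# Signed "inside" quantity (distance - radius <= 0) for one structure at
# supersample offset `off` (mm). Returns the array d - r.
signed_excess <- function(struct, coords, off) {
  x <- coords$x + off[1]; y <- coords$y + off[2]; z <- coords$z + off[3]
  if (inherits(struct, "nodule_spec")) {
    d <- sqrt((x - struct$center[1])^2 + (y - struct$center[2])^2 +
                (z - struct$center[3])^2)
    return(d - struct$radius)
  }
  cl <- struct$centerline
  rp <- struct$radius_profile
  best <- NULL
  for (s in seq_len(nrow(cl) - 1L)) {
    p0 <- cl[s, ]; v <- cl[s + 1L, ] - p0
    vv <- sum(v^2)
    t <- ((x - p0[1]) * v[1] + (y - p0[2]) * v[2] + (z - p0[3]) * v[3]) / vv
    t <- pmin(pmax(t, 0), 1)
    d <- sqrt((x - p0[1] - t * v[1])^2 + (y - p0[2] - t * v[2])^2 +
                (z - p0[3] - t * v[3])^2)
    ex <- d - (rp[s] + t * (rp[s + 1L] - rp[s]))
    best <- if (is.null(best)) ex else pmin(best, ex)
  }
  best
}

# Intensity contribution (above background) of one structure at the voxel
# centres; peak intensities are absolute values, so the contribution scales
# the background-to-peak contrast.
struct_intensity <- function(struct, coords, background) {
  ex <- signed_excess(struct, coords, c(0, 0, 0))
  soft <- struct$edge_softness
  falloff <- function(excess, peak) {
    contrast <- peak - background
    if (soft > 0) contrast * exp(-pmax(0, excess)^2 / (2 * soft^2)) else
      contrast * (excess <= 0)
  }
  if (inherits(struct, "vessel_spec")) return(falloff(ex, struct$intensity))
  if (struct$kind == "part_solid") {
    core <- falloff(ex + struct$radius / 2, struct$peak_intensity)
    halo <- falloff(ex, PHANTOM_DEFAULTS$nonsolid_peak)
    pmax(core, halo)
  } else {
    falloff(ex, struct$peak_intensity)
  }
}

# Partial occupancy by 2x supersampling per axis (8 sub-voxel probes),
# against the half-maximum (FWHM) support of the structure.
struct_occupancy <- function(struct, coords, spacing) {
  occ <- 0
  ext <- fwhm_extension(struct)
  for (ox in c(-0.25, 0.25)) for (oy in c(-0.25, 0.25)) for (oz in c(-0.25, 0.25)) {
    occ <- occ + (signed_excess(struct, coords, c(ox, oy, oz) * spacing) <= ext)
  }
  occ / 8
}

# Smooth strictly positive multiplicative bias field, mean ~1: three random
# low-frequency cosine modes, scaled so |deviation| <= bias_amplitude < 1.
bias_field <- function(dm, spacing, amplitude) {
  if (amplitude <= 0) return(array(1, dm))
  coords <- vox_coords(dm, spacing)
  extent <- dm * spacing
  s <- array(0, dm)
  for (j in 1:3) {
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    freq <- stats::runif(1, 0.4, 1.2) / max(extent) # cycles per mm, band-limited
    phase <- stats::runif(1, 0, 2 * pi)
    s <- s + cos(2 * pi * freq *
                   (coords$x * dir[1] + coords$y * dir[2] + coords$z * dir[3]) + phase)
  }
  s <- s / max(abs(s))
  b <- 1 + amplitude * s
  b / mean(b)
}

#' Render a phantom scene to a labelled volume
#'
#' Composes all structures (intensity contributions combined by maximum, so
#' overlapping nodule/vessel pairs keep their shared intensity), assigns each
#' voxel the label of the structure with the highest partial occupancy
#' (>= 0.5, nodules take precedence over vessels on ties), then applies the
#' multiplicative bias field and additive Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @return a `labeled_volume`: list with `intensity` and `labels` arrays and
#'   `spacing`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$shape
  coords <- vox_coords(dm, spec$spacing)
  extent <- dm * spec$spacing
  for (nd in spec$nodules) {
    if (any(nd$center < -nd$radius) || any(nd$center > extent + nd$radius))
      stop("nodule lies fully outside the grid", call. = FALSE)
  }
  structs <- c(spec$nodules, spec$vessels)
  classes <- c(rep(1L, length(spec$nodules)), rep(2L, length(spec$vessels)))
  intensity <- array(0, dm)
  best_occ <- array(0, dm)
  labels <- array(0L, dm)
  occs <- vector("list", length(structs))
  for (i in seq_along(structs)) {
    intensity <- pmax(intensity, struct_intensity(structs[[i]], coords, spec$background))
    occ <- struct_occupancy(structs[[i]], coords, spec$spacing)
    occs[[i]] <- occ
    win <- occ > best_occ # strict: earlier (nodule) structures win ties
    labels[win] <- classes[i]
    best_occ <- pmax(best_occ, occ)
  }
  labels[best_occ < 0.5] <- 0L
  intensity <- intensity + spec$background
  with_seed(spec$seed, {
    intensity <- intensity * bias_field(dm, spec$spacing, spec$bias_amplitude)
    if (spec$noise_sigma > 0)
      intensity <- intensity + stats::rnorm(length(intensity), 0, spec$noise_sigma)
  })
  dim(intensity) <- dm
  structure(list(intensity = intensity, labels = labels, spacing = spec$spacing,
                 occupancies = occs, classes = classes),
            class = "labeled_volume")
}

#' Render a juxtavascular case (nodule attached to a vessel)
#'
#' The nodule and vessel must overlap; voxels inside both structures are
#' marked with the attachment-zone label 3. By default both structures share
#' the same intensity, the configuration that makes juxtavascular
#' segmentation hard.
#'
#' @param nodule a [nodule_spec()].
#' @param vessel a [vessel_spec()].
#' @param spec a [phantom_spec()] supplying grid, noise and bias settings; its
#'   own structure lists are ignored.
#' @return a `labeled_volume` with labels in \{0, 1, 2, 3\}.
#' @export
juxtavascular_phantom <- function(nodule, vessel, spec) {
  stopifnot(inherits(nodule, "nodule_spec"), inherits(vessel, "vessel_spec"))
  # precondition: centerline passes within nodule radius + vessel radius
  cl <- vessel$centerline
  mind <- Inf
  for (s in seq_len(nrow(cl) - 1L)) {
    p0 <- cl[s, ]; v <- cl[s + 1L, ] - p0
    t <- min(max(sum((nodule$center - p0) * v) / sum(v^2), 0), 1)
    mind <- min(mind, sqrt(sum((nodule$center - p0 - t * v)^2)))
  }
  if (mind >= nodule$radius + max(vessel$radius_profile))
    stop("structures are disjoint: not a juxtavascular case", call. = FALSE)
  sp <- spec
  sp$nodules <- list(nodule)
  sp$vessels <- list(vessel)
  vol <- render_phantom(sp)
  both <- vol$occupancies[[1]] >= 0.5 & vol$occupancies[[2]] >= 0.5
  vol$labels[both] <- 3L
  vol
}

#' Serialize a phantom specification to a plain (YAML-ready) list
#'
#' Inverse of [phantom_from_config()]; matrices become row lists so the
#' result survives a YAML round trip via [write_config()]/[read_config()].
#' @param spec a [phantom_spec()].
#' @export
phantom_to_config <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  list(
    shape = as.integer(spec$shape), spacing = spec$spacing,
    background = spec$background, noise_sigma = spec$noise_sigma,
    bias_amplitude = spec$bias_amplitude, seed = spec$seed,
    nodules = lapply(spec$nodules, function(n)
      list(center = n$center, radius = n$radius, kind = n$kind,
           peak_intensity = n$peak_intensity, edge_softness = n$edge_softness)),
    vessels = lapply(spec$vessels, function(v)
      list(centerline = apply(v$centerline, 1L, as.numeric, simplify = FALSE),
           radius_profile = v$radius_profile, intensity = v$intensity,
           edge_softness = v$edge_softness))
  )
}

#' @rdname phantom_to_config
#' @param cfg a list as produced by [phantom_to_config()] (or parsed YAML).
#' @export
phantom_from_config <- function(cfg) {
  phantom_spec(
    shape = cfg$shape, spacing = cfg$spacing,
    nodules = lapply(cfg$nodules, function(n)
      nodule_spec(n$center, n$radius, n$kind, n$peak_intensity, n$edge_softness)),
    vessels = lapply(cfg$vessels, function(v)
      vessel_spec(do.call(rbind, v$centerline), v$radius_profile, v$intensity,
                  v$edge_softness)),
    noise_sigma = cfg$noise_sigma, bias_amplitude = cfg$bias_amplitude,
    background = cfg$background, seed = cfg$seed
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("labeled_volume:", paste(dim(x$intensity), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 3), collapse = "/"), "mm\n")
  tab <- table(factor(x$labels, levels = 0:3,
                      labels = c("background", "nodule", "vessel", "attachment")))
  print(tab)
  invisible(x)
}
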