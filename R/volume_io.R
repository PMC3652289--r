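# Reading/writing medical volumes and masks, candidate tables, pipeline
# configuration and run logging.
#
# Conventions fixed here and used by every stage: voxel indices are 0-based,
# bounding boxes half-open [lo, hi), world coordinates follow the volume
# header (voxel centre of index i at origin + (i + 0.5) * spacing when the
# orientation is identity).

#' Construct a volume handle from an array
#'
#' @param intensity 2-D or 3-D numeric array.
#' @param spacing voxel spacing (mm), strictly positive.
#' @param origin world origin (mm).
#' @param orientation 3x3 orthonormal direction matrix.
#' @param path source path, if any.
#' @return a `volume_handle`.
#' @export
as_volume <- function(intensity, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      orientation = diag(3), path = NA_character_) {
  if (inherits(intensity, "labeled_volume")) {
    spacing <- intensity$spacing
    intensity <- intensity$intensity
  }
  intensity <- as_vol3d(intensity)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be strictly positive", call. = FALSE)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation matrix must be orthonormal", call. = FALSE)
  structure(list(intensity = intensity, spacing = spacing,
                 origin = as.numeric(origin), orientation = orientation,
                 path = path),
            class = "volume_handle")
}

#' @export
print.volume_handle <- function(x, ...) {
  cat("volume_handle:", paste(dim(x$intensity), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = "/"), "mm",
      if (!is.na(x$path)) paste0("[", x$path, "]") else "", "\n")
  invisible(x)
}

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.mhd$|\\.mha$", path)) "metaimage"
  else if (dir.exists(path)) "dicom_series"
  else stop("cannot guess volume format from path: ", path, call. = FALSE)
}

#' Read a medical volume
#'
#' Supports NIfTI (`.nii`/`.nii.gz`, via RNifti) and MetaImage
#' (`.mhd` + raw / `.mha`). Integer intensities are preserved losslessly;
#' spacing, origin and orientation are taken from the header. DICOM series
#' are not supported by this build and are rejected with a diagnostic.
#'
#' @param path file path.
#' @param format `"nifti"`, `"metaimage"` or `"dicom_series"`; guessed from
#'   the path by default.
#' @return a `volume_handle`.
#' @export
read_volume <- function(path, format = guess_format(path)) {
  format <- match.arg(format, c("nifti", "metaimage", "dicom_series"))
  if (format == "dicom_series")
    stop("DICOM series reading is not supported by this build; ",
         "convert to NIfTI or MetaImage", call. = FALSE)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as_vol3d(array(as.numeric(img), dim(img)))
    sp <- rep_len(RNifti::pixdim(img), 3L)
    xf <- try(RNifti::xform(img), silent = TRUE)
    origin <- c(0, 0, 0); orient <- diag(3)
    if (!inherits(xf, "try-error") && is.matrix(xf) && all(dim(xf) == c(4, 4))) {
      origin <- xf[1:3, 4]
      R <- xf[1:3, 1:3] %*% diag(1 / sp)
      if (max(abs(crossprod(R) - diag(3))) < 1e-3) orient <- R
    }
    if (any(!is.finite(sp)) || any(sp <= 0))
      stop("volume header carries no usable spacing", call. = FALSE)
    return(as_volume(arr, spacing = sp, origin = origin, orientation = orient,
                     path = path))
  }
  read_metaimage(path)
}

#' Write a volume
#'
#' @param vol a `volume_handle` (or array, taken at unit spacing).
#' @param path destination (`.nii`, `.nii.gz`, `.mhd` or `.mha`).
#' @param datatype storage type: `"auto"` stores 16-bit integers when the
#'   values are integral and in range, otherwise 32-bit float.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, datatype = c("auto", "int16", "float", "double")) {
  datatype <- match.arg(datatype)
  if (!inherits(vol, "volume_handle")) vol <- as_volume(vol)
  v <- vol$intensity
  if (datatype == "auto") {
    integral <- all(v == round(v)) && min(v) >= -32768 && max(v) <= 32767
    datatype <- if (integral) "int16" else "double"
  }
  fmt <- guess_format(path)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(v)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path, datatype = datatype)
  } else {
    write_metaimage(vol, path, datatype)
  }
  invisible(path)
}

#' Write a binary mask with a reference volume's geometry
#'
#' @param mask logical/0-1 array, same shape as the reference.
#' @param ref `volume_handle` supplying spacing/origin/orientation.
#' @param path destination path.
#' @export
write_mask <- function(mask, ref, path) {
  mask <- as_vol3d(mask)
  if (!identical(dim(mask), dim(ref$intensity)))
    stop("mask shape does not match the reference volume", call. = FALSE)
  m <- array(as.integer(mask != 0), dim(mask))
  write_volume(as_volume(m, ref$spacing, ref$origin, ref$orientation), path,
               datatype = "int16")
}

## --- MetaImage (.mhd/.mha): text key = value header plus raw voxels -------

meta_types <- c(int16 = "MET_SHORT", float = "MET_FLOAT", double = "MET_DOUBLE")
meta_sizes <- c(MET_CHAR = 1L, MET_UCHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
                MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

write_metaimage <- function(vol, path, datatype) {
  et <- meta_types[[datatype]]
  local_raw <- grepl("\\.mha$", path)
  rawfile <- if (local_raw) "LOCAL" else sub("\\.mhd$", ".raw", basename(path))
  hdr <- c(
    "ObjectType = Image", "NDims = 3", "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("TransformMatrix =", paste(as.vector(vol$orientation), collapse = " ")),
    paste("Offset =", paste(vol$origin, collapse = " ")),
    paste("ElementSpacing =", paste(vol$spacing, collapse = " ")),
    paste("DimSize =", paste(dim(vol$intensity), collapse = " ")),
    paste("ElementType =", et),
    paste("ElementDataFile =", rawfile)
  )
  vals <- as.vector(vol$intensity)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  write_payload <- function(con2) {
    if (datatype == "int16") writeBin(as.integer(vals), con2, size = 2L)
    else writeBin(as.numeric(vals), con2, size = meta_sizes[[et]])
  }
  if (local_raw) write_payload(con) else {
    con2 <- file(file.path(dirname(path), rawfile), "wb")
    on.exit(close(con2), add = TRUE)
    write_payload(con2)
  }
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated MetaImage header", call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  dm <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  orient <- diag(3)
  if (!is.null(hdr$TransformMatrix))
    orient <- matrix(as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]]), 3, 3)
  et <- hdr$ElementType
  if (!et %in% names(meta_sizes))
    stop("unsupported MetaImage element type: ", et, call. = FALSE)
  n <- prod(dm)
  read_payload <- function(con2) {
    if (et %in% c("MET_FLOAT", "MET_DOUBLE"))
      readBin(con2, "numeric", n = n, size = meta_sizes[[et]])
    else readBin(con2, "integer", n = n, size = meta_sizes[[et]],
                 signed = !grepl("^MET_U", et) || meta_sizes[[et]] > 2L)
  }
  vals <- if (identical(hdr$ElementDataFile, "LOCAL")) read_payload(con) else {
    con2 <- file(file.path(dirname(path), hdr$ElementDataFile), "rb")
    on.exit(close(con2), add = TRUE)
    read_payload(con2)
  }
  as_volume(array(as.numeric(vals), dm), spacing = rep_len(sp, 3L),
            origin = origin, orientation = orient, path = path)
}

## --- Candidate records -----------------------------------------------------

#' Construct a candidate record
#'
#' A candidate is one segmented connected component. The mask is carried
#' in-memory as a logical array over the full volume grid; on disk it is
#' referenced by a relative path. Stage flags are monotone: a candidate is
#' segmented before it can be refined, gated or classified.
#'
#' @param id integer candidate id (unique within a volume).
#' @param volume_id character scan identifier.
#' @param mask logical array (full grid).
#' @param flags character vector of completed stages.
#' @param label +1 nodule, -1 non-nodule, or NA when unknown.
#' @export
candidate_record <- function(id, volume_id, mask, flags = "segmented", label = NA) {
  mask <- as_vol3d(mask) != 0
  bb <- bbox_of(mask)
  order_ok <- match(flags, c("segmented", "refined", "gated", "classified"))
  if (anyNA(order_ok) || is.unsorted(order_ok))
    stop("stage flags must be a prefix-ordered subset of ",
         "segmented < refined < gated < classified", call. = FALSE)
  if (!"segmented" %in% flags) stop("a candidate must at least be segmented", call. = FALSE)
  structure(list(id = as.integer(id), volume_id = as.character(volume_id),
                 bbox_lo = bb$lo, bbox_hi = bb$hi, mask = mask,
                 flags = flags, label = label, n_voxels = sum(mask),
                 refinement_failed = FALSE, mask_path = NA_character_),
            class = "candidate_record")
}

#' Write a candidate table as CSV
#'
#' One row per candidate with a fixed, stable header; masks referenced by
#' relative path (written alongside when a reference volume is given).
#'
#' @param records list of `candidate_record`s.
#' @param path CSV destination.
#' @param ref optional `volume_handle`; when given, each mask is written as
#'   `<csv stem>_mask<id>.nii.gz` next to the table.
#' @export
write_candidates <- function(records, path, ref = NULL) {
  ids <- vapply(records, function(r) paste(r$volume_id, r$id), "")
  if (anyDuplicated(ids)) stop("duplicate candidate ids", call. = FALSE)
  rows <- lapply(records, function(r) {
    mask_path <- r$mask_path
    if (!is.null(ref)) {
      mask_path <- paste0(sub("\\.csv$", "", basename(path)), "_mask", r$id, ".nii.gz")
      write_mask(r$mask, ref, file.path(dirname(path), mask_path))
    }
    data.frame(candidate_id = r$id, volume_id = r$volume_id,
               bbox_lo_x = r$bbox_lo[1], bbox_lo_y = r$bbox_lo[2],
               bbox_lo_z = r$bbox_lo[3], bbox_hi_x = r$bbox_hi[1],
               bbox_hi_y = r$bbox_hi[2], bbox_hi_z = r$bbox_hi[3],
               n_voxels = r$n_voxels, flags = paste(r$flags, collapse = ";"),
               label = ifelse(is.na(r$label), NA_integer_, as.integer(r$label)),
               mask_path = mask_path, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a candidate table written by [write_candidates()]
#'
#' @param path CSV path.
#' @param load_masks reload the referenced mask volumes when present.
#' @return a list of `candidate_record`s (masks NULL unless reloaded).
#' @export
read_candidates <- function(path, load_masks = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    mask <- NULL
    if (load_masks && nzchar(r$mask_path %||% "")) {
      mv <- read_volume(file.path(dirname(path), r$mask_path))
      mask <- mv$intensity != 0
    }
    structure(list(id = r$candidate_id, volume_id = r$volume_id,
                   bbox_lo = c(r$bbox_lo_x, r$bbox_lo_y, r$bbox_lo_z),
                   bbox_hi = c(r$bbox_hi_x, r$bbox_hi_y, r$bbox_hi_z),
                   mask = mask, flags = strsplit(r$flags, ";")[[1]],
                   label = if (is.na(r$label)) NA else r$label,
                   n_voxels = r$n_voxels, refinement_failed = FALSE,
                   mask_path = r$mask_path),
              class = "candidate_record")
  })
}

## --- Configuration and run log --------------------------------------------

#' Default pipeline configuration
#'
#' One document holding every stage's tunable parameters; see the methods
#' vignette for what each controls.
#' @export
default_config <- function() {
  list(
    membership = list(clusters = 2L, m = 2, curvature_scale = 1.5,
                      opening_radius = 1L, sample_quantile = 0.25,
                      evolve_smooth = 1.5),
    fiacm = list(mu = 0.2, lambda1 = 1, lambda2 = 1, m = 2, epsilon = 1.5,
                 tau = 1, max_iter = 150L, conv_tol = 1e-4,
                 sigma_base = 3, p_lo = 0.6, p_hi = 0.95,
                 init_window = 9L, init_offset = 40, min_voxels = 10L),
    refine = list(q_attach = 0.6, c_attach = 0.7, M = 3L, margin = 3L,
                  uniform_density = NULL, tol = 1e-6, max_iter = 200L),
    gate = list(volume_min = 14, volume_max = 14200, quotient_min = 0.25,
                mean3d_min = -700),
    classify = list(k = 10L, C_grid = 2^(-1:3), gamma_grid = 2^(-3:3)),
    evaluate = list(overlap_min = 0.25),
    seed = 1L
  )
}

#' Read / write the pipeline YAML configuration
#'
#' Unspecified fields fall back to [default_config()].
#' @param path YAML file.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (sec in names(user)) {
    if (is.list(user[[sec]]) && is.list(cfg[[sec]]))
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    else cfg[[sec]] <- user[[sec]]
  }
  cfg
}

#' @rdname read_config
#' @param cfg configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Minimal structured run log: timestamped lines to a connection or file.
run_log <- function(logfile = NULL) {
  function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    if (is.null(logfile)) message(line) else cat(line, "\n", file = logfile,
                                                 append = TRUE)
  }
}
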