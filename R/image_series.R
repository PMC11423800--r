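#' Image series container
#'
#' A stack of 2-D magnitude images indexed by an acquisition axis (train
#' time, preparation time or inversion time, in ms). This is the common
#' currency between the simulator, the dictionary matcher and the
#' least-squares fitters.
#'
#' @param data Numeric array `x * y * frames`.
#' @param frame_axis Numeric vector, ms, one value per frame.
#' @param fov_mm Field of view, mm.
#' @param protocol_name Free-text tag of the generating protocol.
#' @param protocol_fingerprint Hash tag of the generating protocol, if any.
#' @return A `samba_image_series` object.
#' @export
image_series <- function(data, frame_axis, fov_mm,
                         protocol_name = NA_character_,
                         protocol_fingerprint = NA_character_) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[3L] != length(frame_axis))
    stop("frame count of `data` does not match `frame_axis` length",
         call. = FALSE)
  structure(list(data = data, frame_axis = as.numeric(frame_axis),
                 fov_mm = fov_mm, protocol_name = protocol_name,
                 protocol_fingerprint = protocol_fingerprint),
            class = "samba_image_series")
}

#' @export
print.samba_image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<samba_image_series> %dx%d, %d frames (%s), FOV %g mm\n",
              d[1L], d[2L], d[3L],
              if (is.na(x$protocol_name)) "untagged" else x$protocol_name,
              x$fov_mm))
  invisible(x)
}

#' @exportS3Method
as_tibble.samba_image_series <- function(x, ...) {
  d <- dim(x$data)
  axis_ms <- rep(x$frame_axis, each = d[1L] * d[2L])
  intensity <- as.vector(x$data)
  tibble::tibble(
    x = rep.int(rep.int(seq_len(d[1L]), d[2L]), d[3L]),
    y = rep.int(rep(seq_len(d[2L]), each = d[1L]), d[3L]),
    frame = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    axis_ms = axis_ms, intensity = intensity)
}

#' Per-voxel parameter map
#'
#' Container for a voxel-wise T1 or T2 estimate with an M0 channel, a
#' validity mask and a per-voxel quality channel (match score for
#' dictionary matching, fit residual RMS for least squares).
#'
#' @param values Numeric matrix of parameter estimates, ms (`NA` where
#'   invalid).
#' @param param_name `"T1"` or `"T2"`.
#' @param m0 Numeric matrix of M0 estimates.
#' @param quality Numeric matrix (match score or residual RMS).
#' @param valid Logical matrix marking usable voxels.
#' @param fov_mm Field of view, mm.
#' @param method Method tag, e.g. `"MBA"` or `"LSF"`.
#' @return A `samba_parameter_map` object.
#' @export
parameter_map <- function(values, param_name, m0 = NULL, quality = NULL,
                          valid = NULL, fov_mm = NA_real_,
                          method = NA_character_) {
  stopifnot(is.matrix(values), param_name %in% c("T1", "T2"))
  if (is.null(valid)) valid <- is.finite(values)
  if (is.null(m0)) m0 <- matrix(NA_real_, nrow(values), ncol(values))
  if (is.null(quality)) quality <- matrix(NA_real_, nrow(values), ncol(values))
  stopifnot(identical(dim(values), dim(valid)),
            identical(dim(values), dim(m0)),
            identical(dim(values), dim(quality)))
  structure(list(values = values, param_name = param_name, m0 = m0,
                 quality = quality, valid = valid, fov_mm = fov_mm,
                 method = method),
            class = "samba_parameter_map")
}

#' @export
print.samba_parameter_map <- function(x, ...) {
  cat(sprintf("<samba_parameter_map> %s [%s], %dx%d, %d valid voxels\n",
              x$param_name,
              if (is.na(x$method)) "untagged" else x$method,
              nrow(x$values), ncol(x$values), sum(x$valid)))
  if (any(x$valid))
    cat(sprintf("  range %.4g..%.4g ms, median %.4g ms\n",
                min(x$values[x$valid]), max(x$values[x$valid]),
                stats::median(x$values[x$valid])))
  invisible(x)
}

#' @exportS3Method
as_tibble.samba_parameter_map <- function(x, ...) {
  nx <- nrow(x$values); ny <- ncol(x$values)
  value_ms <- as.vector(x$values)
  m0 <- as.vector(x$m0)
  quality <- as.vector(x$quality)
  valid <- as.vector(x$valid)
  tibble::tibble(x = rep.int(seq_len(nx), ny),
                 y = rep(seq_len(ny), each = nx),
                 value_ms = value_ms, m0 = m0, quality = quality,
                 valid = valid)
}

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Write / read an image series as NIfTI plus a JSON sidecar
#'
#' The voxel data go into a 4-D NIfTI volume (`x, y, 1, frame`, axis-aligned
#' isotropic in-plane affine); the acquisition axis and protocol tags go
#' into a JSON sidecar next to the image (`<stem>.json`). The round trip is
#' lossless to 32-bit float representation of the voxel data (exact when
#' `datatype = "double"`).
#'
#' @param series A [image_series()] object.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype NIfTI storage type; `"double"` for lossless round trips.
#' @return `write_image_series` returns `path` invisibly;
#'   `read_image_series` returns the reconstructed series.
#' @export
write_image_series <- function(series, path, datatype = "double") {
  stopifnot(inherits(series, "samba_image_series"))
  d <- dim(series$data)
  vol <- array(series$data, dim = c(d[1L], d[2L], 1L, d[3L]))
  pix <- series$fov_mm / d[1L]
  attr(vol, "pixdim") <- c(pix, pix, 1, 1)
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = datatype), path)
  jsonlite::write_json(
    list(frame_axis_ms = series$frame_axis, fov_mm = series$fov_mm,
         protocol_name = series$protocol_name,
         protocol_fingerprint = series$protocol_fingerprint),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_series
#' @export
read_image_series <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing sidecar file: expected ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  if (length(d) != 4L)
    stop("expected a 4-D NIfTI volume (x, y, 1, frame): ", path,
         call. = FALSE)
  if (d[4L] != length(meta$frame_axis_ms))
    stop("frame count in ", path, " (", d[4L],
         ") does not match sidecar frame_axis_ms length (",
         length(meta$frame_axis_ms), ")", call. = FALSE)
  image_series(array(as.numeric(vol), dim = c(d[1L], d[2L], d[4L])),
               frame_axis = meta$frame_axis_ms, fov_mm = meta$fov_mm,
               protocol_name = meta$protocol_name,
               protocol_fingerprint = meta$protocol_fingerprint)
}

#' Write / read a parameter map as NIfTI plus a JSON sidecar
#'
#' The estimate, M0, quality and validity channels are stacked along the
#' fourth axis; the sidecar records the parameter name (with ms units),
#' method tag and channel order.
#'
#' @param map A [parameter_map()] object.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `write_parameter_map` returns `path` invisibly;
#'   `read_parameter_map` the reconstructed map.
#' @export
write_parameter_map <- function(map, path) {
  stopifnot(inherits(map, "samba_parameter_map"))
  d <- dim(map$values)
  vol <- array(c(map$values, map$m0, map$quality, map$valid * 1),
               dim = c(d[1L], d[2L], 1L, 4L))
  pix <- if (is.finite(map$fov_mm)) map$fov_mm / d[1L] else 1
  attr(vol, "pixdim") <- c(pix, pix, 1, 1)
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "double"), path)
  jsonlite::write_json(
    list(param_name = map$param_name, units = "ms", method = map$method,
         fov_mm = map$fov_mm,
         channels = c("value_ms", "m0", "quality", "valid")),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameter_map
#' @export
read_parameter_map <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing sidecar file: expected ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  vol <- array(as.numeric(vol), dim = d)
  parameter_map(values = vol[, , 1L, 1L], param_name = meta$param_name,
                m0 = vol[, , 1L, 2L], quality = vol[, , 1L, 3L],
                valid = vol[, , 1L, 4L] > 0.5, fov_mm = meta$fov_mm,
                method = meta$method)
}
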