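#' Default dictionary grids
#'
#' The candidate relaxation values used when no grid is supplied: T1 from
#' 50 to 5000 ms in 10 ms steps; T2 from 5 to 100 ms in 1 ms steps and from
#' 102 to 500 ms in 2 ms steps. These spans bracket the sampling ranges of
#' the spin-echo comparator protocols, with a step below the expected
#' noise-induced estimation error.
#'
#' @param param `"T1"` or `"T2"`.
#' @return Numeric vector of grid values, ms, strictly increasing.
#' @export
default_grid <- function(param = c("T1", "T2")) {
  param <- match.arg(param)
  if (param == "T1") seq(50, 5000, by = 10)
  else c(seq(5, 100, by = 1), seq(102, 500, by = 2))
}

#' Build a matching dictionary from a signal model
#'
#' Simulates the protocol's signal for every candidate relaxation value and
#' stores the magnitude time-courses as unit-L2-norm atoms. The
#' pre-normalization norm of each atom is kept so that matching can recover
#' M0. Magnitude atoms (`|signed model|`) are the default because measured
#' images are magnitude images; `signed = TRUE` retains the signed
#' evolution for complex/synthetic data.
#'
#' @param grid Strictly increasing vector of candidate T1 or T2 values, ms.
#'   `NULL` selects [default_grid()] for the protocol's parameter.
#' @param protocol A protocol object; its signal model generates the atoms.
#' @param signed Keep atom polarity instead of taking magnitudes.
#' @param ... Passed to [protocol_signal()] (e.g. `n_dummy_shots`).
#' @return A `samba_dictionary` with fields `param_name`, `grid`, `atoms`
#'   (rows = grid values, unit L2 norm), `raw_norms`, `signed` and
#'   `protocol_fingerprint`.
#' @examples
#' d <- build_dictionary(seq(200, 2000, by = 100), samba_t1_protocol())
#' @export
build_dictionary <- function(grid = NULL, protocol, signed = FALSE, ...) {
  stopifnot(inherits(protocol, "samba_protocol"))
  param_name <- switch(protocol_type(protocol),
                       samba_t1_protocol = "T1",
                       se_ir_protocol = "T1",
                       samba_t2_protocol = "T2",
                       se_t2_protocol = "T2")
  if (is.null(grid)) grid <- default_grid(param_name)
  if (length(grid) == 0L) stop("`grid` is empty", call. = FALSE)
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be strictly increasing and positive", call. = FALSE)

  n_frames <- length(protocol_frame_axis(protocol))
  atoms <- matrix(NA_real_, nrow = length(grid), ncol = n_frames)
  raw_norms <- numeric(length(grid))
  for (i in seq_along(grid)) {
    tis <- if (param_name == "T1") tissue_params(t1 = grid[i], t2 = 1e6)
           else tissue_params(t1 = 1e6, t2 = grid[i])
    s <- protocol_signal(tis, protocol, ...)
    if (!signed) s <- abs(s)
    nrm <- sqrt(sum(s^2))
    if (nrm == 0)
      stop(sprintf("grid value %g ms yields an all-zero signal", grid[i]),
           call. = FALSE)
    atoms[i, ] <- s / nrm
    raw_norms[i] <- nrm
  }
  structure(list(param_name = param_name, grid = as.numeric(grid),
                 atoms = atoms, raw_norms = raw_norms, signed = signed,
                 protocol_fingerprint = protocol_fingerprint(protocol)),
            class = "samba_dictionary")
}

#' @export
print.samba_dictionary <- function(x, ...) {
  cat(sprintf(
    "<samba_dictionary> %s: %d atoms x %d frames, grid %g..%g ms (%s)\n",
    x$param_name, length(x$grid), ncol(x$atoms), min(x$grid), max(x$grid),
    if (x$signed) "signed" else "magnitude"))
  invisible(x)
}

#' @exportS3Method
as_tibble.samba_dictionary <- function(x, ...) {
  tibble::tibble(grid_index = seq_along(x$grid),
                 !!x$param_name := x$grid,
                 raw_norm = x$raw_norms,
                 atom = lapply(seq_along(x$grid), function(i) x$atoms[i, ]))
}

#' Write / read a dictionary as a JSON container
#'
#' Single-file container with a header (parameter name, grid, protocol
#' fingerprint, signed flag, package version) and the atom matrix. The
#' round trip preserves atoms to 15 significant digits (JSON decimal
#' representation).
#'
#' @param dictionary A [build_dictionary()] result.
#' @param path Output path (`.json`).
#' @return `write_dictionary` returns `path` invisibly; `read_dictionary`
#'   the reconstructed dictionary.
#' @export
write_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "samba_dictionary"))
  jsonlite::write_json(
    list(header = list(
           param_name = dictionary$param_name,
           grid = dictionary$grid,
           signed = dictionary$signed,
           protocol_fingerprint = dictionary$protocol_fingerprint,
           package_version =
             as.character(utils::packageVersion("samba"))),
         raw_norms = dictionary$raw_norms,
         atoms = dictionary$atoms),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  atoms <- obj$atoms
  if (!is.matrix(atoms))
    atoms <- matrix(atoms, nrow = length(obj$header$grid), byrow = TRUE)
  structure(list(param_name = obj$header$param_name,
                 grid = as.numeric(obj$header$grid),
                 atoms = atoms,
                 raw_norms = as.numeric(obj$raw_norms),
                 signed = isTRUE(obj$header$signed),
                 protocol_fingerprint = obj$header$protocol_fingerprint),
            class = "samba_dictionary")
}

#' Match one measured time-course against a dictionary
#'
#' Finds the atom with maximal inner product against the L2-normalized
#' signal (cosine similarity). The winning atom's grid value is the
#' parameter estimate; M0 is recovered as the un-normalized inner product
#' divided by the atom's pre-normalization norm. Ties break toward the
#' smaller grid value.
#'
#' @param signal Magnitude time-course, length equal to the atom length.
#' @param dictionary A [build_dictionary()] result.
#' @return A `samba_match` list: `param_value` (ms), `m0_estimate`,
#'   `match_score` in `[0, 1]`, `grid_index`, `valid`. An all-zero signal
#'   returns an invalid result (`valid = FALSE`) rather than an error.
#' @export
match_signal <- function(signal, dictionary) {
  stopifnot(inherits(dictionary, "samba_dictionary"))
  if (length(signal) != ncol(dictionary$atoms))
    stop("signal length does not match dictionary atom length",
         call. = FALSE)
  nrm <- sqrt(sum(signal^2))
  if (nrm == 0 || !is.finite(nrm)) {
    return(structure(list(param_value = NA_real_, m0_estimate = NA_real_,
                          match_score = NA_real_, grid_index = NA_integer_,
                          valid = FALSE), class = "samba_match"))
  }
  ip <- as.numeric(dictionary$atoms %*% signal)     # <atom_i, signal>
  best <- which.max(ip)                             # first max: smaller grid
  structure(list(param_value = dictionary$grid[best],
                 m0_estimate = ip[best] / dictionary$raw_norms[best],
                 match_score = ip[best] / nrm,
                 grid_index = as.integer(best),
                 valid = TRUE), class = "samba_match")
}

#' @export
print.samba_match <- function(x, ...) {
  if (!x$valid) cat("<samba_match> invalid (degenerate signal)\n")
  else cat(sprintf("<samba_match> %g ms (score %.6f, M0 %.4g)\n",
                   x$param_value, x$match_score, x$m0_estimate))
  invisible(x)
}

#' @exportS3Method
tidy.samba_match <- function(x, ...) {
  tibble::tibble(param_value = x$param_value, m0_estimate = x$m0_estimate,
                 match_score = x$match_score, grid_index = x$grid_index,
                 valid = x$valid)
}

#' Voxel-wise dictionary matching over an image series
#'
#' Applies [match_signal()] to every in-mask voxel of a magnitude image
#' series (vectorized as one inner-product matrix multiply) and assembles
#' the winning grid values into a parameter map, with the match score kept
#' as a per-voxel quality channel. Out-of-mask and degenerate (all-zero)
#' voxels are marked invalid.
#'
#' @param series An [image_series] object.
#' @param dictionary A [build_dictionary()] result with atom length equal
#'   to the series frame count.
#' @param mask Optional logical matrix (`matrix_size` square); default
#'   matches every voxel.
#' @return A [parameter_map] object.
#' @export
match_series <- function(series, dictionary, mask = NULL) {
  stopifnot(inherits(series, "samba_image_series"),
            inherits(dictionary, "samba_dictionary"))
  n_frames <- dim(series$data)[3L]
  if (n_frames != ncol(dictionary$atoms))
    stop("series frame count does not match dictionary atom length",
         call. = FALSE)
  nx <- dim(series$data)[1L]; ny <- dim(series$data)[2L]
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  stopifnot(identical(dim(mask), c(nx, ny)))

  sig <- matrix(series$data, nrow = nx * ny, ncol = n_frames)
  idx <- which(as.vector(mask))
  values <- matrix(NA_real_, nx, ny)
  m0 <- matrix(NA_real_, nx, ny)
  score <- matrix(NA_real_, nx, ny)
  valid <- matrix(FALSE, nx, ny)
  if (length(idx)) {
    s <- sig[idx, , drop = FALSE]
    nrm <- sqrt(rowSums(s^2))
    ok <- is.finite(nrm) & nrm > 0
    if (any(ok)) {
      ip <- s[ok, , drop = FALSE] %*% t(dictionary$atoms)
      best <- max.col(ip, ties.method = "first")
      sel <- cbind(seq_along(best), best)
      vi <- idx[ok]
      values[vi] <- dictionary$grid[best]
      m0[vi] <- ip[sel] / dictionary$raw_norms[best]
      score[vi] <- ip[sel] / nrm[ok]
      valid[vi] <- TRUE
    }
  }
  parameter_map(values = values, param_name = dictionary$param_name,
                m0 = m0, quality = score, valid = valid,
                fov_mm = series$fov_mm, method = "MBA")
}
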