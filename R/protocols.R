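#' Tissue relaxation parameters
#'
#' Bundle of the per-voxel (or per-tube) physical parameters driving every
#' signal model in the package: the longitudinal relaxation time T1, the
#' transverse relaxation time T2 and the equilibrium magnetization M0
#' (proton density, arbitrary units).
#'
#' T2 > T1 is permitted: phantom tubes need not respect biological tissue
#' constraints.
#'
#' @param t1 Longitudinal relaxation time, ms. Must be finite and positive.
#' @param t2 Transverse relaxation time, ms. Must be finite and positive.
#' @param m0 Equilibrium magnetization, arbitrary units; non-negative.
#' @return An object of class `tissue_params`.
#' @examples
#' tissue_params(t1 = 1000, t2 = 80)
#' @export
tissue_params <- function(t1, t2, m0 = 1) {
  if (!is.numeric(t1) || length(t1) != 1L || !is.finite(t1) || t1 <= 0)
    stop("`t1` must be a single finite positive number (ms)", call. = FALSE)
  if (!is.numeric(t2) || length(t2) != 1L || !is.finite(t2) || t2 <= 0)
    stop("`t2` must be a single finite positive number (ms)", call. = FALSE)
  if (!is.numeric(m0) || length(m0) != 1L || !is.finite(m0) || m0 < 0)
    stop("`m0` must be a single finite non-negative number", call. = FALSE)
  structure(list(t1 = t1, t2 = t2, m0 = m0), class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("<tissue_params> T1 = %g ms, T2 = %g ms, M0 = %g\n",
              x$t1, x$t2, x$m0))
  invisible(x)
}

new_protocol <- function(fields, subclass) {
  structure(fields, class = c(subclass, "samba_protocol"))
}

#' Inversion-prepared Look-Locker spiral protocol (SAMBA T1)
#'
#' Sequence-parameter record for the T1 mapping protocol: a single adiabatic
#' inversion followed by a train of small-flip-angle excitations with a
#' spiral readout after each. Defaults are the published acquisition
#' parameters (TR 14 s, 50 readouts spaced 265 ms, 20 degree excitation,
#' 5 spiral interleaves of 3535 points, NSA 3, 30 mm FOV, 128 matrix).
#'
#' @param tr Repetition time (one inversion train per TR), ms.
#' @param te Echo time, ms. T2 decay over TE is neglected by the signal
#'   model (TE of 1.66 ms is far below the readout spacing).
#' @param n_readouts Number of excitations/readouts in the train.
#' @param readout_spacing Time between successive excitations, ms.
#' @param inversion_flip_deg Nominal inversion flip angle, degrees.
#' @param excitation_flip_deg Excitation flip angle, degrees.
#' @param inversion_efficiency Inversion efficiency in `[0, 1]`; 1 models an
#'   ideal adiabatic inversion.
#' @param n_interleaves,n_points_per_interleaf Spiral geometry.
#' @param nsa Number of signal averages.
#' @param fov_mm,matrix_size,slice_thickness_mm Image geometry.
#' @param first_delay Delay from inversion to the first readout, ms.
#'   Defaults to one `readout_spacing`.
#' @return A `samba_t1_protocol` object.
#' @export
samba_t1_protocol <- function(tr = 14000, te = 1.66, n_readouts = 50,
                              readout_spacing = 265,
                              inversion_flip_deg = 180,
                              excitation_flip_deg = 20,
                              inversion_efficiency = 1,
                              n_interleaves = 5,
                              n_points_per_interleaf = 3535,
                              nsa = 3, fov_mm = 30, matrix_size = 128,
                              slice_thickness_mm = 1,
                              first_delay = readout_spacing) {
  stopifnot(n_readouts >= 1, readout_spacing > 0, tr > 0,
            inversion_efficiency >= 0, inversion_efficiency <= 1,
            nsa >= 1, n_interleaves >= 1, n_points_per_interleaf >= 1,
            first_delay > 0)
  if (n_readouts * readout_spacing > tr)
    stop("readout train (n_readouts * readout_spacing) does not fit in TR",
         call. = FALSE)
  new_protocol(list(
    tr = tr, te = te, n_readouts = as.integer(n_readouts),
    readout_spacing = readout_spacing,
    inversion_flip_deg = inversion_flip_deg,
    excitation_flip_deg = excitation_flip_deg,
    inversion_efficiency = inversion_efficiency,
    n_interleaves = as.integer(n_interleaves),
    n_points_per_interleaf = as.integer(n_points_per_interleaf),
    nsa = as.integer(nsa), fov_mm = fov_mm,
    matrix_size = as.integer(matrix_size),
    slice_thickness_mm = slice_thickness_mm,
    first_delay = first_delay), "samba_t1_protocol")
}

#' T2-prepared single-shot spiral protocol (SAMBA T2)
#'
#' Sequence-parameter record for the T2 mapping protocol: a variable-length
#' 90-180-90 T2 preparation followed by a single spiral acquisition per
#' preparation time. Defaults are the published parameters (TR 5 s, seven
#' preparation times 12-400 ms, 5 interleaves of 11393 points, NSA 2,
#' 160 matrix).
#'
#' @param tr Repetition time, ms.
#' @param prep_times Ordered vector of T2 preparation times, ms.
#' @param excitation_flip_deg Excitation flip angle, degrees.
#' @inheritParams samba_t1_protocol
#' @return A `samba_t2_protocol` object.
#' @export
samba_t2_protocol <- function(tr = 5000,
                              prep_times = c(12, 25, 50, 75, 100, 200, 400),
                              excitation_flip_deg = 90,
                              n_interleaves = 5,
                              n_points_per_interleaf = 11393,
                              nsa = 2, fov_mm = 30, matrix_size = 160,
                              slice_thickness_mm = 1) {
  stopifnot(tr > 0, length(prep_times) >= 1, all(prep_times > 0),
            nsa >= 1, n_interleaves >= 1)
  if (is.unsorted(prep_times, strictly = TRUE))
    stop("`prep_times` must be strictly increasing", call. = FALSE)
  new_protocol(list(
    tr = tr, prep_times = as.numeric(prep_times),
    excitation_flip_deg = excitation_flip_deg,
    n_interleaves = as.integer(n_interleaves),
    n_points_per_interleaf = as.integer(n_points_per_interleaf),
    nsa = as.integer(nsa), fov_mm = fov_mm,
    matrix_size = as.integer(matrix_size),
    slice_thickness_mm = slice_thickness_mm), "samba_t2_protocol")
}

#' Inversion-recovery spin-echo protocol (gold-standard T1)
#'
#' Cartesian spin-echo inversion-recovery record. Defaults are the published
#' comparator protocol: 13 inversion times from 26 to 9250 ms, TR 10 s,
#' NSA 3, 128 matrix.
#'
#' @param tr,te Repetition and echo times, ms.
#' @param inversion_times Ordered vector of inversion times, ms.
#' @param n_phase_encodes Phase-encode count (Cartesian lines per image).
#' @inheritParams samba_t1_protocol
#' @return A `se_ir_protocol` object.
#' @export
se_ir_protocol <- function(tr = 10000, te = 3.61,
                           inversion_times = c(26, 79, 265, 530, 790, 1050,
                                               1320, 1590, 1860, 2120, 3970,
                                               6610, 9250),
                           inversion_efficiency = 1,
                           nsa = 3, fov_mm = 30, matrix_size = 128,
                           n_phase_encodes = matrix_size,
                           slice_thickness_mm = 1) {
  stopifnot(tr > 0, length(inversion_times) >= 1, all(inversion_times > 0),
            inversion_efficiency >= 0, inversion_efficiency <= 1, nsa >= 1)
  if (is.unsorted(inversion_times, strictly = TRUE))
    stop("`inversion_times` must be strictly increasing", call. = FALSE)
  new_protocol(list(
    tr = tr, te = te, inversion_times = as.numeric(inversion_times),
    inversion_efficiency = inversion_efficiency,
    nsa = as.integer(nsa), fov_mm = fov_mm,
    matrix_size = as.integer(matrix_size),
    n_phase_encodes = as.integer(n_phase_encodes),
    slice_thickness_mm = slice_thickness_mm), "se_ir_protocol")
}

#' T2-prepared spin-echo protocol (gold-standard T2)
#'
#' Cartesian T2-prepared spin-echo record. Defaults mirror the published
#' comparator: the same seven preparation times as the spiral T2 protocol,
#' TR 5 s, NSA 2, 160 matrix.
#'
#' @inheritParams samba_t2_protocol
#' @inheritParams se_ir_protocol
#' @return A `se_t2_protocol` object.
#' @export
se_t2_protocol <- function(tr = 5000,
                           prep_times = c(12, 25, 50, 75, 100, 200, 400),
                           nsa = 2, fov_mm = 30, matrix_size = 160,
                           n_phase_encodes = matrix_size,
                           slice_thickness_mm = 1) {
  stopifnot(tr > 0, length(prep_times) >= 1, all(prep_times > 0), nsa >= 1)
  if (is.unsorted(prep_times, strictly = TRUE))
    stop("`prep_times` must be strictly increasing", call. = FALSE)
  new_protocol(list(
    tr = tr, prep_times = as.numeric(prep_times),
    nsa = as.integer(nsa), fov_mm = fov_mm,
    matrix_size = as.integer(matrix_size),
    n_phase_encodes = as.integer(n_phase_encodes),
    slice_thickness_mm = slice_thickness_mm), "se_t2_protocol")
}

protocol_type <- function(protocol) class(protocol)[[1L]]

#' Named protocol presets
#'
#' Returns one of the four published acquisition protocols by name:
#' `"samba-t1"`, `"samba-t2"`, `"se-ir-t1"`, `"se-t2prep"`.
#'
#' @param name Preset name.
#' @return A protocol object with all published sequence parameters.
#' @examples
#' protocol_preset("samba-t1")
#' @export
protocol_preset <- function(name = c("samba-t1", "samba-t2", "se-ir-t1",
                                     "se-t2prep")) {
  name <- match.arg(name)
  switch(name,
         "samba-t1" = samba_t1_protocol(),
         "samba-t2" = samba_t2_protocol(),
         "se-ir-t1" = se_ir_protocol(),
         "se-t2prep" = se_t2_protocol())
}

#' @export
print.samba_protocol <- function(x, ...) {
  cat(sprintf("<%s>\n", protocol_type(x)))
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %s: %s\n", nm, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

#' Write / read a protocol as a YAML config file
#'
#' Protocols serialize to a human-editable YAML file carrying a `type` tag
#' and every sequence parameter, so that a protocol round-trips losslessly.
#'
#' @param protocol A protocol object.
#' @param path File path.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   returns the reconstructed protocol object.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "samba_protocol"))
  out <- c(list(type = protocol_type(protocol)), unclass(protocol))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$type))
    stop("protocol config lacks a `type` field: ", path, call. = FALSE)
  ctor <- switch(cfg$type,
                 samba_t1_protocol = samba_t1_protocol,
                 samba_t2_protocol = samba_t2_protocol,
                 se_ir_protocol = se_ir_protocol,
                 se_t2_protocol = se_t2_protocol,
                 stop("unknown protocol type: ", cfg$type, call. = FALSE))
  cfg$type <- NULL
  do.call(ctor, cfg)
}

protocol_fingerprint <- function(protocol) {
  s <- paste(protocol_type(protocol),
             paste(vapply(unclass(protocol),
                          function(v) paste(format(v, digits = 12),
                                            collapse = ","),
                          character(1)), collapse = ";"))
  # small stable polynomial hash; only used to tag derived artifacts
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
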