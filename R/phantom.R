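#' Default relaxation values for the synthetic tube set
#'
#' Eight tubes spanning the dynamic ranges sampled by the spin-echo
#' comparator protocols (inversion times 26-9250 ms, preparation times
#' 12-400 ms): T1 from 300 to 3000 ms, T2 from 20 to 400 ms, unit proton
#' density.
#'
#' @return A tibble with columns `tube`, `t1`, `t2`, `m0`.
#' @export
default_tube_values <- function() {
  tibble::tibble(tube = 1:8,
                 t1 = c(300, 500, 800, 1100, 1500, 2000, 2500, 3000),
                 t2 = c(20, 40, 60, 90, 120, 180, 250, 400),
                 m0 = rep(1, 8))
}

#' Synthetic multi-tube relaxation phantom
#'
#' Builds a 2-D digital phantom of disjoint circular tubes on a ring layout
#' (a single tube sits at the center). Every tube is rasterized by stamping
#' one disk template at integer pixel shifts, so all labels cover exactly
#' the same number of pixels. The layout is deterministic for a given tube
#' count.
#'
#' @param n_tubes Number of tubes (>= 1).
#' @param t1_values,t2_values,m0_values Per-tube relaxation values (ms) and
#'   proton densities; defaults come from [default_tube_values()].
#' @param matrix_size Label-map resolution.
#' @param fov_mm Field of view, mm.
#' @return A `samba_phantom`: `label_map` (integer matrix, 0 = background),
#'   `tubes` (tibble of per-label [tissue_params()] values plus center and
#'   radius), `fov_mm`, `matrix_size`.
#' @examples
#' ph <- make_tube_phantom(8, matrix_size = 64)
#' table(ph$label_map)
#' @export
make_tube_phantom <- function(n_tubes = 8,
                              t1_values = default_tube_values()$t1[seq_len(n_tubes)],
                              t2_values = default_tube_values()$t2[seq_len(n_tubes)],
                              m0_values = rep(1, n_tubes),
                              matrix_size = 128, fov_mm = 30) {
  stopifnot(n_tubes >= 1,
            length(t1_values) == n_tubes,
            length(t2_values) == n_tubes,
            length(m0_values) == n_tubes)
  n <- as.integer(matrix_size)
  delta <- fov_mm / n
  if (n_tubes == 1L) {
    centers <- cbind(0, 0)
    radius_mm <- 0.25 * fov_mm
  } else {
    ring_r <- 0.32 * fov_mm
    ang <- 2 * pi * (seq_len(n_tubes) - 1L) / n_tubes
    centers <- cbind(ring_r * cos(ang), ring_r * sin(ang))
    radius_mm <- min(0.8 * ring_r * sin(pi / n_tubes), 0.12 * fov_mm)
  }
  # disjointness check (ring guarantees it for the default radius rule)
  if (n_tubes > 1L) {
    dmin <- min(stats::dist(centers))
    if (dmin <= 2 * radius_mm)
      stop("too many tubes to place disjointly on the ring layout",
           call. = FALSE)
  }
  radius_px <- radius_mm / delta
  if (radius_px < 1.5)
    stop("too many tubes to rasterize disjointly at this matrix size",
         call. = FALSE)
  # one disk template, stamped at integer shifts: equal areas by construction
  half <- ceiling(radius_px) + 1L
  tmpl_idx <- expand.grid(dx = -half:half, dy = -half:half)
  tmpl_idx <- tmpl_idx[tmpl_idx$dx^2 + tmpl_idx$dy^2 <= radius_px^2, ]
  label_map <- matrix(0L, n, n)
  cx_px <- round(centers[, 1L] / delta + n / 2 + 0.5)
  cy_px <- round(centers[, 2L] / delta + n / 2 + 0.5)
  for (t in seq_len(n_tubes)) {
    ix <- cx_px[t] + tmpl_idx$dx
    iy <- cy_px[t] + tmpl_idx$dy
    keep <- ix >= 1L & ix <= n & iy >= 1L & iy <= n
    if (!all(keep))
      stop("tube ", t, " does not fit inside the field of view",
           call. = FALSE)
    label_map[cbind(ix, iy)] <- t
  }
  tubes <- tibble::tibble(tube = seq_len(n_tubes),
                          t1 = as.numeric(t1_values),
                          t2 = as.numeric(t2_values),
                          m0 = as.numeric(m0_values),
                          center_x_px = cx_px, center_y_px = cy_px,
                          radius_px = radius_px)
  structure(list(label_map = label_map, tubes = tubes, fov_mm = fov_mm,
                 matrix_size = n),
            class = "samba_phantom")
}

#' @export
print.samba_phantom <- function(x, ...) {
  cat(sprintf("<samba_phantom> %d tubes, %dx%d, FOV %g mm\n",
              nrow(x$tubes), x$matrix_size, x$matrix_size, x$fov_mm))
  invisible(x)
}

#' Rescale a phantom's label map to another matrix size
#'
#' Re-rasterizes the same physical tube layout at a different resolution
#' (the two acquisition geometries share one phantom but use different
#' matrix sizes).
#'
#' @param phantom A [make_tube_phantom()] result.
#' @param matrix_size Target resolution.
#' @return A `samba_phantom` at the new resolution.
#' @export
rescale_phantom <- function(phantom, matrix_size) {
  make_tube_phantom(n_tubes = nrow(phantom$tubes),
                    t1_values = phantom$tubes$t1,
                    t2_values = phantom$tubes$t2,
                    m0_values = phantom$tubes$m0,
                    matrix_size = matrix_size, fov_mm = phantom$fov_mm)
}

#' Analysis ROI labels for a phantom
#'
#' Tube labels shrunk by a margin (default 1.5 pixels) so that ROI
#' statistics exclude edge voxels subject to partial-volume and gridding
#' ringing effects, mirroring how ROIs are drawn inside tubes in practice.
#'
#' @param phantom A phantom.
#' @param margin_px Erosion margin in pixels.
#' @return Integer label matrix.
#' @export
phantom_roi_labels <- function(phantom, margin_px = 1.5) {
  n <- phantom$matrix_size
  out <- matrix(0L, n, n)
  r2 <- pmax(phantom$tubes$radius_px - margin_px, 1)^2
  ix <- rep.int(seq_len(n), n); iy <- rep(seq_len(n), each = n)
  for (t in seq_len(nrow(phantom$tubes))) {
    d2 <- (ix - phantom$tubes$center_x_px[t])^2 +
      (iy - phantom$tubes$center_y_px[t])^2
    out[d2 <= r2[t]] <- t
  }
  out
}

#' Write / read a phantom definition as a YAML config
#'
#' Serializes the tube values and geometry; the label map is re-rasterized
#' deterministically on read, so the round trip reproduces the phantom
#' exactly.
#'
#' @param phantom A [make_tube_phantom()] result.
#' @param path YAML file path.
#' @return `write_phantom` returns `path` invisibly; `read_phantom` the
#'   reconstructed phantom.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "samba_phantom"))
  yaml::write_yaml(list(n_tubes = nrow(phantom$tubes),
                        t1 = phantom$tubes$t1, t2 = phantom$tubes$t2,
                        m0 = phantom$tubes$m0,
                        matrix_size = phantom$matrix_size,
                        fov_mm = phantom$fov_mm), path)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  cfg <- yaml::read_yaml(path)
  make_tube_phantom(cfg$n_tubes, cfg$t1, cfg$t2, cfg$m0,
                    matrix_size = cfg$matrix_size, fov_mm = cfg$fov_mm)
}

#' k-space noise model
#'
#' I.i.d. complex Gaussian noise added to every k-space sample — the
#' standard MRI noise mechanism, which yields Rician-distributed magnitude
#' images after reconstruction. `kspace_sigma` is expressed relative to
#' the DC (k = 0) signal of a unit-M0 tube, so `kspace_sigma = 1/50`
#' corresponds to a k-space SNR of 50 — the default simulation condition.
#'
#' @param kspace_sigma Relative complex-noise standard deviation (>= 0).
#' @param seed Integer seed making every simulation reproducible.
#' @return A `samba_noise_model`.
#' @export
noise_model <- function(kspace_sigma = 1 / 50, seed = 1L) {
  stopifnot(kspace_sigma >= 0)
  structure(list(kspace_sigma = kspace_sigma, seed = as.integer(seed)),
            class = "samba_noise_model")
}

# DC k-space amplitude of one unit-M0 tube: its pixel count (the k = 0
# sample of the unnormalized DFT of a unit disk)
phantom_dc_unit <- function(phantom) {
  sum(phantom$label_map == phantom$tubes$tube[1L])
}

frame_images <- function(phantom, protocol, ...) {
  # per-tube signed signal for every frame; frames assembled by label lookup
  sig <- t(vapply(seq_len(nrow(phantom$tubes)), function(t) {
    tis <- tissue_params(phantom$tubes$t1[t], phantom$tubes$t2[t],
                         phantom$tubes$m0[t])
    protocol_signal(tis, protocol, ...)
  }, numeric(length(protocol_frame_axis(protocol)))))
  lut <- rbind(0, sig)      # background = 0
  lapply(seq_len(ncol(sig)), function(f) {
    matrix(lut[phantom$label_map + 1L, f], phantom$matrix_size,
           phantom$matrix_size)
  })
}

#' Simulate an image series for a phantom under a protocol
#'
#' Full forward simulation of one scan. Each frame's signed signal image is
#' computed from the protocol's relaxometry model; spiral protocols then
#' sample the interleaved spiral trajectory, add complex Gaussian k-space
#' noise, and gridding-reconstruct; spin-echo protocols transform to
#' Cartesian k-space by FFT, add noise, and inverse-transform. Magnitudes
#' are taken at the end, so Rician image statistics emerge naturally. The
#' `nsa` signal averages of the protocol are simulated as independent noise
#' draws averaged in k-space.
#'
#' @param phantom A [make_tube_phantom()] result (its matrix size must
#'   match the protocol's).
#' @param protocol Any protocol object.
#' @param noise A [noise_model()].
#' @param ... Passed to the signal model (e.g. `n_dummy_shots`).
#' @return An [image_series()]; frame axis per [protocol_frame_axis()].
#' @export
simulate_series <- function(phantom, protocol, noise = noise_model(), ...) {
  stopifnot(inherits(phantom, "samba_phantom"),
            inherits(protocol, "samba_protocol"),
            inherits(noise, "samba_noise_model"))
  if (phantom$matrix_size != protocol$matrix_size ||
      phantom$fov_mm != protocol$fov_mm)
    stop("phantom and protocol geometry (matrix size / FOV) do not match",
         call. = FALSE)
  frames <- frame_images(phantom, protocol, ...)
  sigma <- noise$kspace_sigma * phantom_dc_unit(phantom)
  n <- phantom$matrix_size
  spiral <- protocol_type(protocol) %in% c("samba_t1_protocol",
                                           "samba_t2_protocol")
  out <- withr::with_seed(noise$seed, {
    if (spiral) {
      traj <- density_compensation(
        design_spiral(protocol$fov_mm, n, protocol$n_interleaves,
                      protocol$n_points_per_interleaf))
      op <- gridding_operator(traj, n)
      lapply(frames, function(img) {
        s <- sample_kspace(img, traj, method = "grid", op = op)
        if (sigma > 0) {
          acc <- 0
          for (a in seq_len(protocol$nsa)) {
            acc <- acc + s + sigma *
              complex(real = stats::rnorm(length(s)),
                      imaginary = stats::rnorm(length(s)))
          }
          s <- acc / protocol$nsa
        }
        Mod(reconstruct_gridding(s, traj, n, op = op))
      })
    } else {
      lapply(frames, function(img) {
        ks <- fftshift2(stats::fft(ifftshift2(img + 0i)))
        if (sigma > 0) {
          acc <- 0
          for (a in seq_len(protocol$nsa)) {
            acc <- acc + ks + sigma *
              complex(real = stats::rnorm(length(ks)),
                      imaginary = stats::rnorm(length(ks)))
          }
          ks <- matrix(acc / protocol$nsa, n, n)
        }
        Mod(fftshift2(stats::fft(ifftshift2(ks), inverse = TRUE)) / n^2)
      })
    }
  })
  image_series(array(unlist(out), dim = c(n, n, length(frames))),
               frame_axis = protocol_frame_axis(protocol),
               fov_mm = phantom$fov_mm,
               protocol_name = protocol_type(protocol),
               protocol_fingerprint = protocol_fingerprint(protocol))
}

#' Repeated scans for repeatability assessment
#'
#' Runs [simulate_series()] `n_repeats` times with consecutive seeds
#' (`seed, seed + 1, ...`), emulating the repeated back-to-back scans of a
#' repeatability experiment. Deterministic given the base seed.
#'
#' @inheritParams simulate_series
#' @param n_repeats Number of repeats (>= 1).
#' @return List of [image_series()] objects, length `n_repeats`.
#' @export
repeat_scans <- function(phantom, protocol, noise = noise_model(),
                         n_repeats = 8, ...) {
  stopifnot(n_repeats >= 1)
  lapply(seq_len(n_repeats) - 1L, function(i) {
    nm <- noise_model(noise$kspace_sigma, noise$seed + i)
    simulate_series(phantom, protocol, nm, ...)
  })
}
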