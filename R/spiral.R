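#' Design an interleaved Archimedean spiral trajectory
#'
#' Constant-angular-density Archimedean spiral with uniform parameter
#' sampling: interleaf m follows
#' \deqn{k(u) = k_{max}\, u\, e^{i(2\pi n_{turns} u + \varphi_m)}, \quad
#'       u \in [0, 1],}
#' with \eqn{\varphi_m = 2\pi m / n_{il}}, turn count
#' \eqn{n_{turns} = N / (2 n_{il})} (azimuthal Nyquist) and
#' \eqn{k_{max} = N / (2\,FOV)} cycles/mm. Gradient/slew constraints are
#' not modeled; only the interleaf and sample counts of the acquisition
#' are reproduced.
#'
#' @param fov_mm Field of view, mm.
#' @param matrix_size Image matrix size N.
#' @param n_interleaves Number of spiral arms.
#' @param n_points_per_interleaf Samples per arm.
#' @return A `samba_spiral_trajectory` with `kx`, `ky`
#'   (`n_points_per_interleaf x n_interleaves` matrices, cycles/mm), `dcf`
#'   (`NULL` until [density_compensation()] is run), and the geometry
#'   fields.
#' @examples
#' traj <- design_spiral(30, 128, 5, 3535)
#' @export
design_spiral <- function(fov_mm, matrix_size, n_interleaves,
                          n_points_per_interleaf) {
  stopifnot(fov_mm > 0, matrix_size >= 2, n_interleaves >= 1,
            n_points_per_interleaf >= 2)
  if (n_interleaves > matrix_size / 2)
    stop("n_interleaves > matrix_size/2: spiral would be under-determined",
         call. = FALSE)
  k_max <- matrix_size / (2 * fov_mm)
  n_turns <- matrix_size / (2 * n_interleaves)
  u <- seq(0, 1, length.out = n_points_per_interleaf)
  phi <- 2 * pi * (seq_len(n_interleaves) - 1L) / n_interleaves
  ang <- outer(2 * pi * n_turns * u, rep(1, n_interleaves)) +
    outer(rep(1, n_points_per_interleaf), phi)
  r <- k_max * u
  structure(list(kx = r * cos(ang), ky = r * sin(ang), dcf = NULL,
                 fov_mm = fov_mm, matrix_size = as.integer(matrix_size),
                 n_interleaves = as.integer(n_interleaves),
                 n_points_per_interleaf = as.integer(n_points_per_interleaf),
                 k_max = k_max, n_turns = n_turns),
            class = "samba_spiral_trajectory")
}

#' @export
print.samba_spiral_trajectory <- function(x, ...) {
  cat(sprintf(
    "<samba_spiral_trajectory> %d x %d samples, k_max %.4f cycles/mm, %s\n",
    x$n_points_per_interleaf, x$n_interleaves, x$k_max,
    if (is.null(x$dcf)) "no dcf" else "dcf attached"))
  invisible(x)
}

#' @exportS3Method
as_tibble.samba_spiral_trajectory <- function(x, ...) {
  tibble::tibble(
    interleaf = rep(seq_len(x$n_interleaves),
                    each = x$n_points_per_interleaf),
    index = rep.int(seq_len(x$n_points_per_interleaf), x$n_interleaves),
    kx = as.vector(x$kx), ky = as.vector(x$ky),
    dcf = if (is.null(x$dcf)) NA_real_ else as.vector(x$dcf))
}

#' Export / import a trajectory as CSV
#'
#' Plain-text columns `interleaf, index, kx, ky, dcf` (cycles/mm).
#'
#' @param traj A trajectory.
#' @param path CSV path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` a tibble of the samples.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(tibble::as_tibble(traj)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Compute density-compensation weights
#'
#' Non-uniform spiral sampling must be density-weighted before gridding.
#' Two estimators are provided; both normalize the weights so their total
#' equals the area of the sampled k-space disk (\eqn{\pi k_{max}^2}).
#'
#' `"analytic"`: per-sample weight proportional to
#' \eqn{\|k\| \cdot \Delta\|k\|} along the arm (annulus area shared across
#' interleaves), with a nonzero floor at the k-space center.
#'
#' `"voronoi"`: discretized Voronoi cell areas — a fine Cartesian grid over
#' the Nyquist disk is assigned to the nearest sample (across all
#' interleaves) and each sample's weight is its share of the disk area.
#' Clipping at the Nyquist boundary is inherent to the disk support.
#'
#' @param traj A [design_spiral()] trajectory.
#' @param method `"analytic"` or `"voronoi"`.
#' @param voronoi_grid Resolution of the discretization grid per axis.
#' @return The trajectory with its `dcf` field filled.
#' @export
density_compensation <- function(traj, method = c("analytic", "voronoi"),
                                 voronoi_grid = 301L) {
  stopifnot(inherits(traj, "samba_spiral_trajectory"))
  method <- match.arg(method)
  r <- sqrt(traj$kx^2 + traj$ky^2)
  if (method == "analytic") {
    npts <- traj$n_points_per_interleaf
    if (npts < 3L)
      stop("analytic density compensation needs >= 3 points per interleaf",
           call. = FALSE)
    dr <- apply(r, 2L, function(ri) {
      d <- abs(c(ri[2L] - ri[1L], (ri[seq(3, npts)] - ri[seq(1, npts - 2)]) / 2,
                 ri[npts] - ri[npts - 1L]))
      d
    })
    if (all(dr < 1e-12 * max(traj$k_max, 1)))
      dr[] <- 1                      # degenerate (e.g. ring): uniform spacing
    r_floor <- stats::median(dr[dr > 0]) / 2
    w <- pmax(r, r_floor) * dr
  } else {
    g <- seq(-traj$k_max, traj$k_max, length.out = voronoi_grid)
    pts <- expand.grid(kx = g, ky = g)
    pts <- pts[pts$kx^2 + pts$ky^2 <= traj$k_max^2, ]
    nn <- class::knn1(train = cbind(as.vector(traj$kx), as.vector(traj$ky)),
                      test = as.matrix(pts),
                      cl = factor(seq_along(traj$kx)))
    counts <- tabulate(as.integer(as.character(nn)), nbins = length(traj$kx))
    cell <- (g[2L] - g[1L])^2
    w <- matrix(counts * cell, nrow = traj$n_points_per_interleaf)
  }
  w <- w * (pi * traj$k_max^2) / sum(w)
  traj$dcf <- w
  traj
}

# --- Kaiser-Bessel gridding machinery ---------------------------------------

kb_width <- 4          # kernel width, oversampled-grid cells
kb_oversamp <- 2       # grid oversampling factor

kb_beta <- function(width = kb_width, os = kb_oversamp) {
  # standard Beatty prescription for minimal aliasing error
  pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)
}

kb_kernel <- function(u, width = kb_width, beta = kb_beta()) {
  out <- numeric(length(u))
  inside <- abs(u) <= width / 2
  arg <- sqrt(pmax(1 - (2 * u[inside] / width)^2, 0))
  out[inside] <- besselI(beta * arg, 0) / besselI(beta, 0)
  out
}

kb_deapod <- function(n_offsets, grid_size, width = kb_width,
                      beta = kb_beta()) {
  # inverse Fourier transform of the kernel, evaluated at image offsets
  # (pixels from center) for an oversampled grid of grid_size cells
  # exact continuous FT pair of the unit-spacing sampled kernel:
  # I0(b*sqrt(1-(2u/W)^2)) <-> W*sinh(sqrt(b^2-(pi W x)^2))/sqrt(...)
  x <- n_offsets / grid_size
  t2 <- beta^2 - (pi * width * x)^2
  width * ifelse(t2 >= 0,
                 sinh(sqrt(t2)) / sqrt(t2),
                 sin(sqrt(-t2)) / sqrt(-t2)) / besselI(beta, 0)
}

# sparse real matrix times complex vector (Matrix has no complex support)
sp_mult <- function(S, z) {
  as.vector(S %*% Re(z)) + 1i * as.vector(S %*% Im(z))
}

sp_crossprod <- function(S, z) {
  as.vector(Matrix::crossprod(S, Re(z))) +
    1i * as.vector(Matrix::crossprod(S, Im(z)))
}

fftshift2 <- function(m) {
  d <- dim(m)
  m[c(seq(d[1L] / 2 + 1, d[1L]), seq_len(d[1L] / 2)),
    c(seq(d[2L] / 2 + 1, d[2L]), seq_len(d[2L] / 2))]
}

ifftshift2 <- fftshift2   # even sizes only (all grids here are even)

#' Gridding operator for a spiral trajectory
#'
#' Precomputes the sparse Kaiser-Bessel interpolation matrix, the
#' deapodization image and the grid geometry tying a trajectory to an image
#' matrix. [sample_kspace()] and [reconstruct_gridding()] accept the
#' operator to amortize this setup over many frames.
#'
#' @param traj A [design_spiral()] trajectory.
#' @param matrix_size Image matrix size; defaults to the trajectory's.
#' @return A `samba_gridding_operator` (sparse interpolator `S`, oversampled
#'   grid size `grid_size`, deapodization matrix, geometry).
#' @export
gridding_operator <- function(traj, matrix_size = traj$matrix_size) {
  stopifnot(inherits(traj, "samba_spiral_trajectory"))
  n <- as.integer(matrix_size)
  g_size <- kb_oversamp * n
  # sample positions in oversampled-grid units, DC at matrix index g_size/2
  gx <- as.vector(traj$kx) * kb_oversamp * traj$fov_mm
  gy <- as.vector(traj$ky) * kb_oversamp * traj$fov_mm
  n_samp <- length(gx)
  w <- kb_width
  offs <- seq_len(w) - 1L
  base_x <- floor(gx) - w / 2 + 1
  base_y <- floor(gy) - w / 2 + 1
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  # 16 neighbor cells per sample, built one (dx, dy) offset pair at a time
  kx_w <- lapply(offs, function(o) kb_kernel(gx - (base_x + o)))
  ky_w <- lapply(offs, function(o) kb_kernel(gy - (base_y + o)))
  ix <- lapply(offs, function(o) ((base_x + o + g_size / 2) %% g_size) + 1L)
  iy <- lapply(offs, function(o) ((base_y + o + g_size / 2) %% g_size) + 1L)
  rows <- rep.int(seq_len(n_samp), w * w)
  cols <- integer(n_samp * w * w)
  vals <- numeric(n_samp * w * w)
  p <- 0L
  for (ox in seq_len(w)) {
    for (oy in seq_len(w)) {
      idx <- seq.int(p * n_samp + 1L, (p + 1L) * n_samp)
      cols[idx] <- (iy[[oy]] - 1L) * g_size + ix[[ox]]
      vals[idx] <- kx_w[[ox]] * ky_w[[oy]]
      p <- p + 1L
    }
  }
  S <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(n_samp, g_size^2))
  deapod <- outer(kb_deapod(seq_len(n) - 1 - n / 2, g_size),
                  kb_deapod(seq_len(n) - 1 - n / 2, g_size))
  structure(list(S = S, grid_size = g_size, matrix_size = n,
                 deapod = deapod, fov_mm = traj$fov_mm, n_samples = n_samp),
            class = "samba_gridding_operator")
}

embed_center <- function(img, g_size) {
  n <- nrow(img)
  out <- matrix(0 + 0i, g_size, g_size)
  o <- (g_size - n) / 2
  out[o + seq_len(n), o + seq_len(n)] <- img
  out
}

crop_center <- function(img, n) {
  o <- (nrow(img) - n) / 2
  img[o + seq_len(n), o + seq_len(n)]
}

#' Sample k-space along a trajectory (forward model)
#'
#' Evaluates \eqn{s(k_j) = \sum_r x(r) e^{-2\pi i k_j \cdot r}} over image
#' pixels at physical positions (mm, image center at the origin).
#' `method = "grid"` interpolates from a 2x-oversampled FFT grid through
#' the Kaiser-Bessel kernel (fast path); `method = "direct"` evaluates the
#' sum exactly and serves as the testing oracle at small sizes.
#'
#' @param image Complex or numeric `matrix_size` square matrix.
#' @param traj A [design_spiral()] trajectory with matching geometry.
#' @param method `"grid"` (fast) or `"direct"` (exact, O(samples x pixels)).
#' @param op Optional precomputed [gridding_operator()].
#' @return Complex vector of samples, interleaf-major
#'   (`n_points_per_interleaf * n_interleaves`).
#' @export
sample_kspace <- function(image, traj, method = c("grid", "direct"),
                          op = NULL) {
  stopifnot(inherits(traj, "samba_spiral_trajectory"))
  method <- match.arg(method)
  n <- nrow(image)
  if (nrow(image) != ncol(image))
    stop("image must be square", call. = FALSE)
  if (n != traj$matrix_size)
    stop("image size does not match trajectory matrix_size", call. = FALSE)
  if (method == "direct") {
    delta <- traj$fov_mm / n
    pos <- (seq_len(n) - 1 - n / 2) * delta
    rx <- rep.int(pos, n)
    ry <- rep(pos, each = n)
    v <- as.vector(image)
    kx <- as.vector(traj$kx); ky <- as.vector(traj$ky)
    out <- complex(length(kx))
    chunk <- max(1L, floor(2e6 / (n * n)))
    for (start in seq(1L, length(kx), by = chunk)) {
      j <- seq(start, min(start + chunk - 1L, length(kx)))
      ph <- outer(kx[j], rx) + outer(ky[j], ry)
      out[j] <- exp(-2i * pi * ph) %*% v
    }
    return(out)
  }
  if (is.null(op)) op <- gridding_operator(traj, n)
  x <- as.matrix(image) / op$deapod
  grid <- fftshift2(stats::fft(ifftshift2(embed_center(x, op$grid_size))))
  sp_mult(op$S, as.vector(grid))
}

#' Adjoint gridding without density weights
#'
#' The exact adjoint of the `"grid"` forward model in [sample_kspace()]:
#' spreads samples onto the oversampled grid through the transpose of the
#' interpolation matrix, inverse-FFTs, crops and deapodizes, with no
#' density compensation and no physical scaling. Used by the adjoint test
#' and internally by [reconstruct_gridding()].
#'
#' @param samples Complex sample vector.
#' @param traj Trajectory.
#' @param matrix_size Output image size.
#' @param op Optional precomputed operator.
#' @return Complex `matrix_size` square matrix.
#' @export
adjoint_kspace <- function(samples, traj, matrix_size = traj$matrix_size,
                           op = NULL) {
  if (is.null(op)) op <- gridding_operator(traj, matrix_size)
  if (length(samples) != op$n_samples)
    stop("sample count does not match trajectory", call. = FALSE)
  grid <- matrix(sp_crossprod(op$S, samples), op$grid_size, op$grid_size)
  img <- fftshift2(stats::fft(ifftshift2(grid), inverse = TRUE))
  crop_center(img, op$matrix_size) / op$deapod
}

#' Gridding reconstruction of spiral samples
#'
#' Adjoint gridding of density-weighted samples: weight by the trajectory's
#' density-compensation function, spread onto a 2x-oversampled Cartesian
#' grid with the Kaiser-Bessel kernel, inverse FFT, deapodize, crop, and
#' scale by the pixel area so that a fully sampled spiral round-trips a
#' band-limited image.
#'
#' @param samples Complex sample vector (interleaf-major).
#' @param traj Trajectory; must carry density-compensation weights
#'   (run [density_compensation()] first).
#' @param matrix_size Output matrix size.
#' @param op Optional precomputed operator.
#' @return Complex reconstructed image (`matrix_size` square); take `Mod()`
#'   for a magnitude image.
#' @export
reconstruct_gridding <- function(samples, traj,
                                 matrix_size = traj$matrix_size, op = NULL) {
  stopifnot(inherits(traj, "samba_spiral_trajectory"))
  if (is.null(traj$dcf))
    stop("trajectory has no density-compensation weights; ",
         "run density_compensation() first", call. = FALSE)
  delta <- traj$fov_mm / matrix_size
  adjoint_kspace(samples * as.vector(traj$dcf), traj, matrix_size, op) *
    delta^2
}
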