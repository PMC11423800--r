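test_that("spiral geometry obeys the Nyquist relations", {
  t1 <- design_spiral(30, 128, 5, 3535)
  expect_equal(t1$k_max, 128 / (2 * 30), tolerance = 1e-12)
  expect_equal(length(t1$kx), 5 * 3535)
  t2 <- design_spiral(30, 160, 5, 500)
  expect_equal(t2$k_max, 160 / (2 * 30), tolerance = 1e-12)
  # every sample inside the Nyquist disk
  expect_lt(max(sqrt(t1$kx^2 + t1$ky^2)), t1$k_max + 1e-9)
  # every interleaf starts at the k-space center
  expect_equal(unname(t1$kx[1, ]), rep(0, 5))
  expect_equal(unname(t1$ky[1, ]), rep(0, 5))
  expect_error(design_spiral(30, 8, 5, 100), "under-determined")
})

test_that("interleaves are rotated copies of the first arm", {
  traj <- design_spiral(30, 64, 5, 400)
  th <- 2 * pi / 5
  for (m in 2:5) {
    rot <- (m - 1) * th
    kx_rot <- traj$kx[, 1] * cos(rot) - traj$ky[, 1] * sin(rot)
    ky_rot <- traj$kx[, 1] * sin(rot) + traj$ky[, 1] * cos(rot)
    expect_equal(traj$kx[, m], kx_rot, tolerance = 1e-9)
    expect_equal(traj$ky[, m], ky_rot, tolerance = 1e-9)
  }
})

test_that("density weights: symmetry, monotonicity, normalization", {
  # a uniform ring gets equal weights from both estimators
  ring <- design_spiral(30, 32, 4, 100)
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  ring$kx <- matrix(0.4 * cos(th), ncol = 4)
  ring$ky <- matrix(0.4 * sin(th), ncol = 4)
  ring$n_points_per_interleaf <- 25L
  ra <- density_compensation(ring, "analytic")
  expect_lt(diff(range(ra$dcf)) / mean(ra$dcf), 1e-9)

  traj <- density_compensation(design_spiral(30, 64, 5, 600), "analytic")
  r <- sqrt(traj$kx[, 1]^2 + traj$ky[, 1]^2)
  w <- traj$dcf[, 1]
  away <- r > 0.1 * traj$k_max
  expect_true(all(diff(w[away]) >= -1e-12))
  expect_equal(sum(traj$dcf), pi * traj$k_max^2, tolerance = 1e-9)
  expect_true(all(traj$dcf >= 0))
})

test_that("voronoi and analytic weight profiles agree", {
  traj <- design_spiral(30, 32, 5, 500)
  ta <- density_compensation(traj, "analytic")
  tv <- density_compensation(traj, "voronoi", voronoi_grid = 201L)
  expect_gt(stats::cor(as.vector(ta$dcf), as.vector(tv$dcf)), 0.95)
  expect_equal(sum(tv$dcf), pi * traj$k_max^2, tolerance = 1e-9)
})

test_that("forward sampling: delta and zero images are exact", {
  n <- 32
  traj <- design_spiral(30, n, 5, 300)
  imp <- matrix(0, n, n); imp[n / 2 + 1, n / 2 + 1] <- 1
  s <- sample_kspace(imp, traj, method = "direct")
  expect_lt(max(Mod(s - 1)), 1e-12)
  s0 <- sample_kspace(matrix(0, n, n), traj, method = "direct")
  expect_equal(max(Mod(s0)), 0)
  sg0 <- sample_kspace(matrix(0, n, n), traj, method = "grid")
  expect_equal(max(Mod(sg0)), 0)
})

test_that("gridded sampling agrees with the direct-DFT oracle", {
  n <- 32
  traj <- design_spiral(30, n, 5, 700)
  pos <- seq_len(n) - 1 - n / 2
  disk <- outer(pos, pos, function(x, y) as.numeric(x^2 + y^2 <= 100))
  blur <- outer(exp(-pos^2 / 40), exp(-pos^2 / 40))
  img <- disk * 0.3 + blur
  sd_ <- sample_kspace(img, traj, method = "direct")
  sg <- sample_kspace(img, traj, method = "grid")
  expect_lt(max(Mod(sg - sd_)) / max(Mod(sd_)), 1e-3)
})

test_that("gridding round-trip reconstructs a smooth phantom", {
  n <- 32
  traj <- density_compensation(design_spiral(30, n, 5, 700))
  pos <- seq_len(n) - 1 - n / 2
  img <- outer(exp(-pos^2 / 30), exp(-pos^2 / 30)) +
    0.5 * outer(exp(-(pos - 4)^2 / 20), exp(-(pos + 3)^2 / 20))
  rec <- reconstruct_gridding(sample_kspace(img, traj), traj)
  nrmse <- sqrt(mean(Mod(rec - img)^2)) / sqrt(mean(img^2))
  expect_lt(nrmse, 0.05)
  # all-zero samples give an all-zero image
  z <- reconstruct_gridding(rep(0 + 0i, length(traj$kx)), traj)
  expect_equal(max(Mod(z)), 0)
})

test_that("sampling and gridding are exact adjoints", {
  set.seed(3)
  n <- 24
  traj <- design_spiral(30, n, 4, 300)
  op <- gridding_operator(traj, n)
  x <- matrix(complex(real = stats::rnorm(n^2),
                      imaginary = stats::rnorm(n^2)), n, n)
  y <- complex(real = stats::rnorm(1200), imaginary = stats::rnorm(1200))
  lhs <- sum(sample_kspace(x, traj, op = op) * Conj(y))
  rhs <- sum(x * Conj(adjoint_kspace(y, traj, op = op)))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
})

test_that("reconstruction is linear in the samples", {
  set.seed(4)
  n <- 24
  traj <- density_compensation(design_spiral(30, n, 4, 300))
  ns <- length(traj$kx)
  s1 <- complex(real = stats::rnorm(ns), imaginary = stats::rnorm(ns))
  s2 <- complex(real = stats::rnorm(ns), imaginary = stats::rnorm(ns))
  a <- 2.5 - 1i; b <- -0.7 + 3i
  lhs <- reconstruct_gridding(a * s1 + b * s2, traj)
  rhs <- a * reconstruct_gridding(s1, traj) +
    b * reconstruct_gridding(s2, traj)
  expect_lt(max(Mod(lhs - rhs)) / max(Mod(lhs)), 1e-9)
})

test_that("quarter-turn image rotation commutes with reconstruction", {
  # with 4 interleaves the trajectory is invariant under a 90-degree
  # rotation, so rotating the object must simply rotate the reconstruction
  # (coarse smoke test of the sampling symmetry)
  n <- 32
  traj <- density_compensation(design_spiral(30, n, 4, 400))
  pos <- seq_len(n) - 1 - n / 2
  f <- function(x, y) exp(-(x - 3)^2 / 25) * exp(-y^2 / 35)
  img <- outer(pos, pos, f)
  img_rot <- outer(pos, pos, function(x, y) f(y, -x))
  rec1 <- reconstruct_gridding(sample_kspace(img, traj), traj)
  rec2 <- reconstruct_gridding(sample_kspace(img_rot, traj), traj)
  # rotate rec1 by 90 degrees on the grid (interior; the even grid has no
  # symmetric partner for the first row/column)
  expected <- matrix(0 + 0i, n, n)
  for (ix in 2:n) expected[ix, ] <- rec1[, n + 2 - ix]
  err <- Mod(rec2[2:n, ] - expected[2:n, ])
  expect_lt(max(err) / max(Mod(rec1)), 0.01)
})

test_that("trajectory CSV export round-trips", {
  traj <- density_compensation(design_spiral(30, 16, 2, 50))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  tab <- read_trajectory_csv(f)
  expect_equal(nrow(tab), 100)
  expect_equal(tab$kx, as.vector(traj$kx), tolerance = 1e-12)
  expect_equal(tab$dcf, as.vector(traj$dcf), tolerance = 1e-12)
})

test_that("geometry mismatches are rejected with instructions", {
  traj <- design_spiral(30, 16, 2, 50)
  expect_error(reconstruct_gridding(rep(0 + 0i, 100), traj),
               "density_compensation")
  expect_error(sample_kspace(matrix(0, 8, 8), traj), "matrix_size")
})
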