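# loop-based dictionary oracle, independent of build_dictionary internals
dictionary_oracle <- function(grid, protocol) {
  n_frames <- length(protocol_frame_axis(protocol))
  atoms <- matrix(NA_real_, length(grid), n_frames)
  for (i in seq_along(grid)) {
    s <- abs(protocol_signal(tissue_params(grid[i], 1e6, 1), protocol))
    atoms[i, ] <- s / sqrt(sum(s^2))
  }
  atoms
}

test_that("atoms are unit norm and distinguishable", {
  p <- samba_t1_protocol()
  d1 <- build_dictionary(100, p)
  expect_equal(sqrt(sum(d1$atoms[1, ]^2)), 1, tolerance = 1e-12)

  d2 <- build_dictionary(c(400, 900), p)
  expect_lt(sum(d2$atoms[1, ] * d2$atoms[2, ]), 1)
  expect_true(all(abs(sqrt(rowSums(d2$atoms^2)) - 1) < 1e-9))
})

test_that("dictionary equals the loop-based oracle on the default T1 grid", {
  p <- samba_t1_protocol()
  grid <- default_grid("T1")
  d <- build_dictionary(grid, p)
  expect_equal(d$atoms, dictionary_oracle(grid, p), tolerance = 1e-12)
  expect_equal(d$grid, grid)
  expect_true(is.unsorted(d$grid) == FALSE)
})

test_that("degenerate and invalid grids are rejected", {
  p <- samba_t1_protocol()
  expect_error(build_dictionary(numeric(0), p), "empty")
  expect_error(build_dictionary(c(200, 100), p), "increasing")
})

test_that("self-match returns the atom's own grid value, score 1, M0 = c", {
  p <- samba_t2_protocol()
  d <- build_dictionary(seq(20, 400, by = 20), p)
  i <- 7L; c_ <- 4.2
  sig <- c_ * d$raw_norms[i] * d$atoms[i, ]
  m <- match_signal(sig, d)
  expect_equal(m$grid_index, i)
  expect_equal(m$param_value, d$grid[i])
  expect_equal(m$match_score, 1, tolerance = 1e-9)
  expect_equal(m$m0_estimate, c_, tolerance = 1e-9)
  # tiny perturbation does not move the match
  m2 <- match_signal(sig + 1e-9, d)
  expect_equal(m2$grid_index, i)
})

test_that("matching agrees exactly with exhaustive argmax on random signals", {
  set.seed(42)
  p <- samba_t1_protocol()
  d <- build_dictionary(seq(100, 3000, by = 50), p)
  for (rep in 1:200) {
    sig <- abs(stats::rnorm(50))
    m <- match_signal(sig, d)
    sn <- sig / sqrt(sum(sig^2))
    scores <- apply(d$atoms, 1, function(a) sum(a * sn))
    expect_identical(m$grid_index, which.max(scores))
  }
})

test_that("off-grid noiseless signals match the best atom by inner product", {
  p <- samba_t1_protocol()
  d <- build_dictionary(seq(200, 2000, by = 100), p)
  for (t1 in c(333, 847, 1651)) {
    sig <- abs(ll_ir_signal(tissue_params(t1, 50, 1), p))
    m <- match_signal(sig, d)
    sn <- sig / sqrt(sum(sig^2))
    best <- which.max(apply(d$atoms, 1, function(a) sum(a * sn)))
    expect_identical(m$grid_index, best)
    expect_lt(abs(d$grid[m$grid_index] - t1), 100)  # within one grid step
  }
})

test_that("matching is scale invariant and flags all-zero signals", {
  p <- samba_t2_protocol()
  d <- build_dictionary(seq(20, 200, by = 10), p)
  sig <- abs(t2prep_signal(tissue_params(1000, 67, 1), p$prep_times))
  m1 <- match_signal(sig, d); m2 <- match_signal(17.3 * sig, d)
  expect_equal(m1$param_value, m2$param_value)
  expect_equal(m1$match_score, m2$match_score, tolerance = 1e-12)
  expect_equal(m2$m0_estimate / m1$m0_estimate, 17.3, tolerance = 1e-9)

  z <- match_signal(rep(0, 7), d)
  expect_false(z$valid)
  expect_true(is.na(z$param_value))
})

test_that("noiseless on-grid recovery is exact for every grid point", {
  p <- samba_t2_protocol()
  grid <- seq(20, 400, by = 20)
  d <- build_dictionary(grid, p)
  rec <- vapply(grid, function(t2) {
    sig <- abs(t2prep_signal(tissue_params(1000, t2, 1), p$prep_times))
    match_signal(sig, d)$param_value
  }, numeric(1))
  expect_identical(rec, as.numeric(grid))
})

test_that("halving the grid step never increases noiseless matching error", {
  p <- samba_t1_protocol()
  coarse <- build_dictionary(seq(100, 3000, by = 80), p)
  fine <- build_dictionary(seq(100, 3000, by = 40), p)
  t1s <- c(317, 571, 946, 1333, 2108, 2719)
  err <- function(d) vapply(t1s, function(t1) {
    sig <- abs(ll_ir_signal(tissue_params(t1, 50, 1), p))
    abs(match_signal(sig, d)$param_value - t1)
  }, numeric(1))
  expect_true(all(err(fine) <= err(coarse) + 1e-12))
})

test_that("series matching round-trips atom-synthesized regions", {
  p <- samba_t2_protocol(matrix_size = 32)
  grid <- c(40, 90, 160, 300)
  d <- build_dictionary(grid, p)
  lab <- matrix(0L, 32, 32)
  lab[5:12, 5:12] <- 1L; lab[20:27, 5:12] <- 2L
  lab[5:12, 20:27] <- 3L; lab[20:27, 20:27] <- 4L
  dat <- array(0, dim = c(32, 32, 7))
  for (t in 1:4) {
    sig <- d$raw_norms[t] * d$atoms[t, ]
    for (f in 1:7) dat[, , f][lab == t] <- sig[f]
  }
  ser <- image_series(dat, p$prep_times, fov_mm = 30)
  map <- match_series(ser, d)
  for (t in 1:4)
    expect_true(all(map$values[lab == t] == grid[t]))
  # all-zero background voxels are invalid, no crash
  expect_true(all(!map$valid[lab == 0]))
  expect_true(all(is.na(map$values[lab == 0])))
  # quality channel stores the match score
  expect_true(all(abs(map$quality[lab > 0] - 1) < 1e-9))
})

test_that("vectorized series matching equals voxel-wise match_signal", {
  set.seed(11)
  p <- samba_t2_protocol(matrix_size = 8)
  d <- build_dictionary(seq(20, 200, by = 5), p)
  dat <- array(abs(stats::rnorm(8 * 8 * 7)), dim = c(8, 8, 7))
  ser <- image_series(dat, p$prep_times, fov_mm = 30)
  map <- match_series(ser, d)
  for (i in 1:8) for (j in 1:8) {
    m <- match_signal(dat[i, j, ], d)
    expect_identical(map$values[i, j], m$param_value)
  }
})
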