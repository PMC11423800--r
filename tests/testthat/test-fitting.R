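tp7 <- c(12, 25, 50, 75, 100, 200, 400)

test_that("log-linear T2 fit recovers noiseless decays exactly", {
  f <- fit_t2_loglinear(2 * exp(-tp7 / 50), tp7)
  expect_true(f$converged)
  expect_equal(f$param_value, 50, tolerance = 1e-9)
  expect_equal(f$m0_estimate, 2, tolerance = 1e-9)
  # property: exact over a broad T2 span
  for (t2 in c(5, 17, 80, 333, 2000)) {
    f <- fit_t2_loglinear(1.3 * exp(-tp7 / t2), tp7)
    expect_equal(f$param_value, t2, tolerance = 1e-9)
  }
})

test_that("degenerate T2 inputs are flagged, not fit", {
  f <- fit_t2_loglinear(rep(3, 7), tp7)     # no decay: T2 beyond cap
  expect_false(f$converged)
  f2 <- fit_t2_loglinear(c(1, 0.5, -0.1, 0.2, 0.1, 0.05, 0.01), tp7)
  expect_false(f2$converged)
  expect_error(fit_t2_loglinear(1, 12), ">= 2")
})

test_that("noisy T2 estimates track an independent nonlinear oracle", {
  set.seed(101)
  n_mc <- 400
  t2 <- 100; snr <- 50
  ests_lin <- numeric(n_mc); ests_nls <- numeric(n_mc)
  for (i in seq_len(n_mc)) {
    s <- exp(-tp7 / t2) + stats::rnorm(7, sd = 1 / snr)
    s <- pmax(s, 1e-6)
    ests_lin[i] <- fit_t2_loglinear(s, tp7, weighted = TRUE)$param_value
    fit <- minpack.lm::nlsLM(s ~ m0 * exp(-tp7 / tt),
                             start = list(m0 = 1, tt = 80))
    ests_nls[i] <- coef(fit)[["tt"]]
  }
  expect_lt(abs(mean(ests_lin) - t2) / t2, 0.05)
  expect_lt(abs(mean(ests_nls) - t2) / t2, 0.05)
  expect_lt(abs(mean(ests_lin) - mean(ests_nls)) / t2, 0.03)
  expect_lt(abs(stats::sd(ests_lin) - stats::sd(ests_nls)) /
              stats::sd(ests_nls), 0.5)
})

test_that("noise-floor handling excludes sub-floor points", {
  sigma <- 0.05
  s <- exp(-tp7 / 30)
  s_floor <- sqrt(s^2 + 2 * sigma^2)   # expected Rician power
  f <- fit_t2_loglinear(s_floor, tp7, noise_sigma = sigma)
  expect_true(f$converged)
  expect_equal(f$param_value, 30, tolerance = 0.02)
  f_bad <- fit_t2_loglinear(s_floor, tp7)
  expect_gt(abs(f_bad$param_value - 30) / 30, abs(f$param_value - 30) / 30)
})

ti13 <- c(26, 79, 265, 530, 790, 1050, 1320, 1590, 1860, 2120, 3970,
          6610, 9250)

test_that("magnitude IR fit recovers T1 from the 13-point protocol", {
  for (t1 in c(300, 1000, 2400)) {
    s <- abs(1.4 * (1 - 2 * exp(-ti13 / t1)))
    f <- fit_t1_ir_magnitude(s, ti13)
    expect_true(f$converged)
    expect_equal(f$param_value, t1, tolerance = 1e-6)
    expect_equal(f$m0_estimate, 1.4, tolerance = 1e-5)
  }
})

test_that("IR fit is invariant to positive rescaling of the signal", {
  s <- abs(1 - 2 * exp(-ti13 / 700) + exp(-10000 / 700))
  f1 <- fit_t1_ir_magnitude(s, ti13, tr = 10000)
  f2 <- fit_t1_ir_magnitude(5.5 * s, ti13, tr = 10000)
  expect_equal(f1$param_value, f2$param_value, tolerance = 1e-8)
  expect_equal(f2$m0_estimate / f1$m0_estimate, 5.5, tolerance = 1e-6)
})

test_that("flat IR signals imply recovery faster than the first TI", {
  f <- fit_t1_ir_magnitude(rep(2, 13), ti13)
  expect_true(!f$converged || f$param_value < 26)
})

test_that("fit residuals equal the independently recomputed model RMS", {
  set.seed(5)
  s <- abs(1 - 2 * exp(-ti13 / 900)) + abs(stats::rnorm(13, sd = 0.02))
  f <- fit_t1_ir_magnitude(s, ti13)
  k <- f$polarity_flip_index
  y <- s; if (k > 0) y[seq_len(k)] <- -y[seq_len(k)]
  model <- f$A - f$B * exp(-ti13 / f$param_value)
  expect_equal(f$residual_rms, sqrt(mean((y - model)^2)), tolerance = 1e-10)

  f2 <- fit_t2_loglinear(2 * exp(-tp7 / 60) + 0.01, tp7)
  model2 <- f2$m0_estimate * exp(-tp7 / f2$param_value)
  expect_equal(f2$residual_rms,
               sqrt(mean((2 * exp(-tp7 / 60) + 0.01 - model2)^2)),
               tolerance = 1e-10)
})

test_that("noisy IR estimates are confirmed by a grid-search oracle", {
  set.seed(77)
  n_mc <- 60
  t1 <- 800; sd_n <- 0.02
  t1_grid <- exp(seq(log(100), log(5000), length.out = 400))
  for (i in seq_len(n_mc)) {
    s <- abs(1 - 2 * exp(-ti13 / t1) + stats::rnorm(13, sd = sd_n))
    f <- fit_t1_ir_magnitude(s, ti13)
    # independent exhaustive search over (T1, flip index), A and B solved
    # by closed-form normal equations
    best <- Inf; best_t1 <- NA
    for (k in 0:13) {
      y <- s; if (k > 0) y[seq_len(k)] <- -y[seq_len(k)]
      for (tg in t1_grid) {
        x <- exp(-ti13 / tg)
        fitk <- stats::lm.fit(cbind(1, x), y)
        rss <- sum(fitk$residuals^2)
        if (rss < best) { best <- rss; best_t1 <- tg }
      }
    }
    expect_lt(f$residual_rms^2 * 13, best + 1e-10)   # at least as good
    expect_lt(abs(f$param_value - best_t1) / best_t1, 0.02)
  }
})

test_that("Look-Locker correction recovers T1 under the published protocol", {
  p <- samba_t1_protocol()
  for (t1 in c(300, 1000, 2500)) {
    s <- abs(ll_ir_signal(tissue_params(t1, 50, 1), p))
    f <- fit_t1_looklocker(s, p)
    expect_true(f$converged)
    expect_lt(abs(f$param_value - t1) / t1, 0.03)
    expect_equal(f$m0_estimate, 1, tolerance = 1e-4)
    # the flip-angle-free amplitude-ratio variant lands close but carries
    # its documented discrete-sampling bias
    fr <- fit_t1_looklocker(s, p, correction = "ratio")
    expect_lt(abs(fr$param_value - t1) / t1, 0.05)
  }
})

test_that("amplitude-ratio correction is exact in the small-flip limit", {
  p <- samba_t1_protocol(excitation_flip_deg = 1)
  s <- abs(ll_ir_signal(tissue_params(1000, 50, 1), p))
  f <- fit_t1_looklocker(s, p, correction = "ratio")
  expect_lt(abs(f$param_value - 1000) / 1000, 0.01)
})

test_that("degenerate Look-Locker input is flagged", {
  p <- samba_t1_protocol()
  f <- fit_t1_looklocker(rep(0, 50), p)
  expect_false(f$converged)
})

test_that("noiseless residual is minimal at the true parameter", {
  # monotone identifiability on a coarse grid around the truth
  t1 <- 900
  s <- abs(1 - 2 * exp(-ti13 / t1))
  rss_at <- function(tt) {
    y <- s; y[ti13 < t1 * log(2)] <- -y[ti13 < t1 * log(2)]
    x <- exp(-ti13 / tt)
    sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
  }
  r0 <- rss_at(t1)
  for (tt in t1 * c(0.5, 0.8, 1.25, 2))
    expect_gt(rss_at(tt), r0 - 1e-12)
})

test_that("voxel-wise map fitting matches single-voxel fits", {
  set.seed(9)
  p <- se_t2_protocol(matrix_size = 8)
  dat <- array(0, dim = c(8, 8, 7))
  t2s <- matrix(runif(64, 30, 300), 8, 8)
  for (f in 1:7) dat[, , f] <- 1.5 * exp(-tp7[f] / t2s)
  ser <- image_series(dat, tp7, fov_mm = 30)
  map <- fit_series(ser, p, noise_sigma = 0)
  expect_true(all(map$valid))
  expect_equal(map$values, t2s, tolerance = 1e-9)

  pir <- se_ir_protocol(matrix_size = 8)
  t1s <- matrix(runif(64, 300, 2500), 8, 8)
  dat1 <- array(0, dim = c(8, 8, 13))
  for (f in 1:13) dat1[, , f] <- abs(1 - 2 * exp(-ti13[f] / t1s))
  ser1 <- image_series(dat1, ti13, fov_mm = 30)
  map1 <- fit_series(ser1, pir, noise_sigma = 0)
  expect_true(all(map1$valid))
  expect_equal(map1$values, t1s, tolerance = 1e-3)
})
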