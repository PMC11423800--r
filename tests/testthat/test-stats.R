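make_map <- function(values, valid = NULL) {
  parameter_map(values = values, param_name = "T1", valid = valid,
                method = "TEST")
}

test_that("ROI statistics: constants, planted values, masked means", {
  labels <- matrix(0L, 10, 10)
  labels[2:4, 2:4] <- 1L; labels[6:9, 6:9] <- 2L
  vals <- matrix(NA_real_, 10, 10)
  vals[labels == 1L] <- 700
  vals[labels == 2L] <- 1200
  tab <- roi_means(make_map(vals), labels)
  expect_equal(tab$mean, c(700, 1200))
  expect_equal(tab$sd, c(0, 0))
  expect_equal(tab$n_valid, c(9, 16))

  # 10% invalid voxels: means over the remainder match a hand computation
  set.seed(2)
  vals2 <- vals
  vals2[labels == 2L] <- seq(1000, 1150, length.out = 16)
  valid <- is.finite(vals2)
  drop <- sample(which(labels == 2L), 2)
  valid[drop] <- FALSE
  tab2 <- roi_means(make_map(vals2, valid), labels)
  keep <- setdiff(which(labels == 2L), drop)
  expect_equal(tab2$mean[2], mean(vals2[keep]))
  expect_equal(tab2$sd[2], stats::sd(vals2[keep]))

  # a fully invalid label stays as a flagged row
  valid[labels == 1L] <- FALSE
  tab3 <- roi_means(make_map(vals2, valid), labels)
  expect_equal(tab3$n_valid[1], 0)
  expect_true(is.na(tab3$mean[1]))
})

test_that("regression: identity, affine, and normal-equations oracle", {
  r1 <- linear_regression(1:10, 1:10)
  expect_equal(r1$slope, 1); expect_equal(r1$intercept, 0)
  expect_equal(r1$r_squared, 1)
  r2 <- linear_regression(1:10, 2 * (1:10) + 5)
  expect_equal(r2$slope, 2); expect_equal(r2$intercept, 5)
  expect_equal(r2$r_squared, 1)

  set.seed(8)
  x <- stats::rnorm(40, 100, 30); y <- 1.4 * x + stats::rnorm(40, 5, 10)
  r <- linear_regression(x, y)
  # textbook normal equations
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  expect_equal(r$slope, sl, tolerance = 1e-10)
  expect_equal(r$intercept, ic, tolerance = 1e-10)
  expect_error(linear_regression(rep(1, 5), 1:5), "variance")
})

test_that("Bland-Altman: analytic cases, antisymmetry, LOA identity", {
  b0 <- bland_altman(1:5, 1:5)
  expect_equal(b0$bias, 0); expect_equal(b0$loa_low, 0)
  b1 <- bland_altman(c(0, 0), c(-1, 1))
  expect_equal(b1$bias, 0)
  expect_equal(b1$sd_diff, sqrt(2), tolerance = 1e-12)
  expect_equal(b1$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)

  set.seed(3)
  x <- stats::rnorm(30, 100, 10); y <- x + stats::rnorm(30, 2, 3)
  ba <- bland_altman(x, y); ab <- bland_altman(y, x)
  expect_equal(ba$bias, -ab$bias)
  expect_equal(ba$loa_low, -ab$loa_high)
  expect_equal(ba$loa_high, ba$bias + 1.96 * ba$sd_diff, tolerance = 1e-9)
  expect_equal(ba$loa_low, ba$bias - 1.96 * ba$sd_diff, tolerance = 1e-9)
})

test_that("LOA cover about 95% of simulated Gaussian differences", {
  set.seed(123)
  d <- stats::rnorm(10000, mean = 2, sd = 3)
  ba <- bland_altman(rep(0, 10000), d)
  coverage <- mean(d >= ba$loa_low & d <= ba$loa_high) * 100
  expect_gte(coverage, 94)
  expect_lte(coverage, 96)
})

test_that("CV%: analytic value, scale invariance, guard rails", {
  expect_equal(cv_percent(c(90, 100, 110)), 10)
  expect_equal(cv_percent(rep(7, 8)), 0)
  set.seed(4)
  v <- stats::rnorm(8, 1000, 20)
  expect_equal(cv_percent(3.3 * v), cv_percent(v), tolerance = 1e-12)
  expect_error(cv_percent(5), ">= 2")
  expect_error(cv_percent(c(-1, 1)), "mean")
})

test_that("scan times reproduce the published protocol arithmetic", {
  expect_equal(scan_time(protocol_preset("samba-t1"))$seconds, 210)
  expect_equal(scan_time(protocol_preset("samba-t1"))$label, "3min30s")
  st2 <- scan_time(protocol_preset("samba-t2"))
  expect_equal(st2$seconds, 350)
  expect_equal(round(st2$seconds / 60), 6)
  # exactly linear in NSA and in the preparation count
  p <- samba_t2_protocol(nsa = 4)
  expect_equal(scan_time(p)$seconds,
               2 * scan_time(samba_t2_protocol(nsa = 2))$seconds)
  p3 <- se_t2_protocol(prep_times = c(12, 25, 50))
  expect_equal(scan_time(se_t2_protocol())$seconds / 7,
               scan_time(p3)$seconds / 3)
})

test_that("CV-per-time products and ratios behave as products", {
  expect_equal(cv_per_time(1, 0.1), 0.1)
  # with equal CVs the method ratio reduces to the scan-time ratio
  t_sa <- scan_time(protocol_preset("samba-t2"))$hours
  t_se <- scan_time(protocol_preset("se-t2prep"))$hours
  expect_equal(cv_per_time(0.8, t_se) / cv_per_time(0.8, t_sa),
               t_se / t_sa, tolerance = 1e-12)
})

test_that("method comparison: self, constant offset, tube-set guard", {
  tab <- tibble::tibble(label = rep(1:6, 2),
                        mean = rep(c(300, 500, 800, 1200, 2000, 3000), 2),
                        method = rep(c("A", "B"), each = 6),
                        repeat_index = 1L)
  cmp <- compare_methods(tab)
  row <- cmp$pairs[cmp$pairs$method_x == "A" & cmp$pairs$method_y == "B", ]
  expect_equal(row$slope, 1); expect_equal(row$intercept, 0)
  expect_equal(row$bias, 0)
  expect_true(is.na(row$p_value) || row$p_value == 1)

  tab$mean[tab$method == "B"] <- tab$mean[tab$method == "B"] + 42
  cmp2 <- compare_methods(tab)
  row2 <- cmp2$pairs[cmp2$pairs$method_y == "B", ]
  expect_equal(row2$slope, 1, tolerance = 1e-12)
  expect_equal(row2$bias, 42, tolerance = 1e-12)

  bad <- tab[!(tab$method == "B" & tab$label == 6), ]
  expect_error(compare_methods(bad), "tube set")
})

test_that("comparison against ground truth joins on tube labels", {
  tab <- tibble::tibble(label = 1:4, mean = c(310, 490, 820, 1180),
                        method = "A", repeat_index = 1L)
  truth <- tibble::tibble(label = 1:4, truth = c(300, 500, 800, 1200))
  cmp <- compare_methods(tab, ground_truth = truth)
  row <- cmp$pairs[cmp$pairs$method_x == "truth", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$n_tubes, 4L)
  expect_lt(abs(row$slope - 1), 0.05)
})
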