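#' @keywords internal
new_fit_result <- function(param_value = NA_real_, m0_estimate = NA_real_,
                           residual_rms = NA_real_, converged = FALSE,
                           polarity_flip_index = NA_integer_,
                           param_name = "T1", extra = list()) {
  structure(c(list(param_value = param_value, m0_estimate = m0_estimate,
                   residual_rms = residual_rms, converged = converged,
                   polarity_flip_index = polarity_flip_index,
                   param_name = param_name), extra),
            class = "samba_fit")
}

#' @export
print.samba_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<samba_fit> %s: not converged\n", x$param_name))
  } else {
    cat(sprintf("<samba_fit> %s = %.6g ms (M0 %.4g, residual RMS %.3g)\n",
                x$param_name, x$param_value, x$m0_estimate, x$residual_rms))
  }
  invisible(x)
}

#' @exportS3Method
tidy.samba_fit <- function(x, ...) {
  tibble::tibble(term = c(x$param_name, "M0"),
                 estimate = c(x$param_value, x$m0_estimate))
}

#' @exportS3Method
glance.samba_fit <- function(x, ...) {
  tibble::tibble(residual_rms = x$residual_rms, converged = x$converged,
                 polarity_flip_index = x$polarity_flip_index)
}

#' Log-linear T2 fit
#'
#' Ordinary least squares of `log(signal)` on preparation time: the slope
#' is \eqn{-1/T_2} and the intercept \eqn{\log M_0}. Unweighted by default;
#' `weighted = TRUE` weights each point by its squared signal, which undoes
#' the noise distortion introduced by the log transform.
#'
#' When `noise_sigma > 0`, the fit first applies the standard Rician
#' noise-floor (power) correction \eqn{\sqrt{s^2 - 2\sigma^2}} and excludes
#' points below `floor_factor * noise_sigma`: on magnitude images the late,
#' fully decayed preparation times plateau at the Rayleigh noise floor
#' instead of zero, and fitting through that plateau inflates short T2
#' estimates severely.
#'
#' @param signals Magnitude signal vector, all values must be positive.
#' @param prep_times Preparation times, ms (>= 2 points).
#' @param weighted Use signal-squared weights.
#' @param t2_cap Fits above this value (ms) are flagged not converged
#'   (near-constant data carries no decay information).
#' @param noise_sigma Per-voxel Gaussian noise component of the magnitude
#'   image (0 disables the floor handling).
#' @param floor_factor Points below `floor_factor * noise_sigma` are
#'   excluded from the fit.
#' @return A `samba_fit` result; `residual_rms` is computed in the signal
#'   (not log) domain over the points used.
#' @examples
#' tp <- c(12, 25, 50, 75, 100, 200, 400)
#' fit_t2_loglinear(2 * exp(-tp / 50), tp)
#' @export
fit_t2_loglinear <- function(signals, prep_times, weighted = FALSE,
                             t2_cap = 10000, noise_sigma = 0,
                             floor_factor = 3) {
  if (length(signals) != length(prep_times) || length(signals) < 2L)
    stop("need >= 2 matched signal/prep_time points", call. = FALSE)
  if (any(!is.finite(signals)) || any(signals <= 0))
    return(new_fit_result(param_name = "T2"))
  if (noise_sigma > 0) {
    keep <- signals > floor_factor * noise_sigma
    if (sum(keep) < 2L) return(new_fit_result(param_name = "T2"))
    signals <- sqrt(pmax(signals[keep]^2 - 2 * noise_sigma^2,
                         .Machine$double.xmin))
    prep_times <- prep_times[keep]
  }
  y <- log(signals)
  w <- if (weighted) signals^2 else rep(1, length(signals))
  fit <- stats::lm.wfit(cbind(1, prep_times), y, w)
  intercept <- fit$coefficients[[1L]]
  slope <- fit$coefficients[[2L]]
  t2 <- -1 / slope
  m0 <- exp(intercept)
  model <- m0 * exp(prep_times * slope)
  rms <- sqrt(mean((signals - model)^2))
  conv <- is.finite(t2) && t2 > 0 && t2 <= t2_cap
  new_fit_result(param_value = if (is.finite(t2) && t2 > 0) t2 else NA_real_,
                 m0_estimate = m0, residual_rms = rms, converged = conv,
                 param_name = "T2")
}

# --- polarity-restored inversion-recovery machinery -------------------------

# two-parameter linear subproblem of y ~ A + C * exp(-t / t1), vectorized
# over a matrix of voxels (rows); returns per-voxel A, C and RSS
ir_linear_sub <- function(Y, sum_y2, x) {
  n <- length(x)
  sx <- sum(x); sxx <- sum(x * x)
  det <- n * sxx - sx * sx
  sy <- rowSums(Y)
  sxy <- as.vector(Y %*% x)
  A <- (sxx * sy - sx * sxy) / det
  C <- (n * sxy - sx * sy) / det
  rss <- pmax(sum_y2 - A * sy - C * sxy, 0)
  list(A = A, C = C, rss = rss)
}

ir_rss_scalar <- function(log_t1, y, times) {
  x <- exp(-times / exp(log_t1))
  ir_linear_sub(matrix(y, nrow = 1), sum(y * y), x)$rss
}

default_flip_candidates <- function(y, full_search) {
  n <- length(y)
  if (full_search || n <= 16L) return(0:n)
  j <- which.min(y)
  sort(unique(pmin(pmax(c(0L, (j - 3L):(j + 3L)), 0L), n)))
}

# core polarity-restored fit of |A - B exp(-t/T1)| on one magnitude vector
ir_polarity_fit <- function(signals, times, t1_range, full_search = FALSE,
                            n_grid = 100L, polish = TRUE) {
  n <- length(signals)
  ord <- order(times)
  times <- times[ord]; signals <- signals[ord]
  cand <- default_flip_candidates(signals, full_search)
  lg <- seq(log(t1_range[1L]), log(t1_range[2L]), length.out = n_grid)
  best <- list(rss = Inf, k = NA_integer_, log_t1 = NA_real_,
               A = NA_real_, B = NA_real_)
  for (k in cand) {
    y <- signals
    if (k > 0L) y[seq_len(k)] <- -y[seq_len(k)]
    sum_y2 <- sum(y * y)
    Y <- matrix(y, nrow = 1L)
    rss_grid <- vapply(lg, function(l) {
      ir_linear_sub(Y, sum_y2, exp(-times / exp(l)))$rss
    }, numeric(1))
    i0 <- which.min(rss_grid)
    lo <- lg[max(i0 - 1L, 1L)]; hi <- lg[min(i0 + 1L, n_grid)]
    opt <- stats::optimize(ir_rss_scalar, c(lo, hi), y = y, times = times,
                           tol = 1e-9)
    if (opt$objective < best$rss) {
      sub <- ir_linear_sub(Y, sum_y2, exp(-times / exp(opt$minimum)))
      best <- list(rss = opt$objective, k = as.integer(k),
                   log_t1 = opt$minimum, A = sub$A, B = -sub$C)
    }
  }
  if (!is.finite(best$rss)) return(NULL)
  t1 <- exp(best$log_t1); A <- best$A; B <- best$B
  if (polish) {
    y <- signals
    if (best$k > 0L) y[seq_len(best$k)] <- -y[seq_len(best$k)]
    fit <- tryCatch(
      stats::nls(y ~ A + C * exp(-times / t1),
                 start = list(A = A, C = -B, t1 = t1),
                 control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                              minFactor = 1e-12,
                                              warnOnly = TRUE),
                 algorithm = "port", lower = c(-Inf, -Inf, 1e-3)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      rss <- sum(stats::resid(fit)^2)
      if (is.finite(rss) && rss <= best$rss + 1e-12 * (1 + best$rss)) {
        A <- cf[["A"]]; B <- -cf[["C"]]; t1 <- cf[["t1"]]
        best$rss <- rss
      }
    }
  }
  list(t1 = t1, A = A, B = B, k = best$k,
       residual_rms = sqrt(best$rss / n))
}

#' Polarity-restored magnitude inversion-recovery T1 fit
#'
#' Fits \eqn{|A - B e^{-TI/T_1}|} to a magnitude IR time-course. For each
#' candidate polarity flip index `k` the first `k` samples (in time order)
#' are negated and the signed three-parameter model is solved by least
#' squares (the `A`, `B` pair is linear for fixed T1, so T1 is found by a
#' bracketed 1-D search and polished by [stats::nls()]); the flip index
#' with minimal residual wins. With the finite-TR recovery term,
#' \eqn{A = M_0(1 + e^{-TR/T_1})} and \eqn{B = 2\epsilon M_0}; `tr` is used
#' only to convert `A` back to an M0 estimate.
#'
#' @param signals Magnitude signal vector (>= 3 points).
#' @param inversion_times Inversion times, ms.
#' @param tr Repetition time, ms (`Inf` drops the recovery term from the
#'   M0 conversion).
#' @param full_search Try every flip index instead of the window around the
#'   signal minimum (always on for <= 16 points).
#' @param t1_range Search range for T1, ms.
#' @return A `samba_fit` with `polarity_flip_index` set.
#' @export
fit_t1_ir_magnitude <- function(signals, inversion_times, tr = Inf,
                                full_search = FALSE,
                                t1_range = c(5, 30000)) {
  if (length(signals) != length(inversion_times) || length(signals) < 3L)
    stop("need >= 3 matched signal/inversion_time points", call. = FALSE)
  if (any(!is.finite(signals)) || all(signals == 0))
    return(new_fit_result(param_name = "T1"))
  res <- ir_polarity_fit(abs(signals), inversion_times, t1_range,
                         full_search = full_search)
  if (is.null(res)) return(new_fit_result(param_name = "T1"))
  m0 <- if (is.finite(tr)) res$A / (1 + exp(-tr / res$t1)) else res$A
  conv <- is.finite(res$t1) && res$t1 > 0 && res$A > 0
  new_fit_result(param_value = res$t1, m0_estimate = m0,
                 residual_rms = res$residual_rms, converged = conv,
                 polarity_flip_index = res$k, param_name = "T1",
                 extra = list(A = res$A, B = res$B))
}

# undo the excitation-driven acceleration of the apparent recovery
ll_correct <- function(t1_star, A, B, protocol,
                       correction = c("flip-angle", "ratio")) {
  correction <- match.arg(correction)
  if (correction == "ratio") return(t1_star * (B / A - 1))
  tau <- protocol$readout_spacing
  lc <- log(cos(protocol$excitation_flip_deg * pi / 180))
  rate <- 1 / t1_star + lc / tau
  if (rate <= 0) return(NA_real_)
  1 / rate
}

ll_m0 <- function(t1, t1_star, A, protocol) {
  # A = sin(a) * steady-state magnetization of the driven train
  tau <- protocol$readout_spacing
  sa <- sin(protocol$excitation_flip_deg * pi / 180)
  e <- exp(-tau / t1)
  ce <- exp(-tau / t1_star)       # cos(a) * e for the flip-angle correction
  (A / sa) * (1 - ce) / (1 - e)
}

#' Look-Locker T1 fit for the inversion-prepared spiral train
#'
#' Fits the apparent recovery \eqn{|A - B e^{-t/T_1^*}|} at the train
#' sampling times (polarity restoration as in [fit_t1_ir_magnitude()]),
#' then corrects the apparent \eqn{T_1^*} — which is shortened because
#' every excitation removes longitudinal magnetization — back to T1.
#'
#' Two corrections are available. `"flip-angle"` (default) inverts the
#' discrete recovery relation of the sampled train,
#' \eqn{1/T_1 = 1/T_1^* + \ln(\cos\alpha)/\tau}, using the nominal
#' excitation flip angle \eqn{\alpha} and readout spacing \eqn{\tau}; it is
#' exact for this signal model. `"ratio"` is the classic flip-angle-free
#' amplitude correction \eqn{T_1 = T_1^* (B/A - 1)}, useful when the true
#' flip angle is uncertain (B1 inhomogeneity); for a discretely sampled
#' train at moderate flip angles it carries a small deterministic bias
#' (about +3% under the default protocol timing).
#'
#' @param signals Magnitude signal vector, one value per readout.
#' @param protocol A [samba_t1_protocol()]; supplies the train times, flip
#'   angle and readout spacing.
#' @param correction `"flip-angle"` or `"ratio"`.
#' @param full_search Passed to the polarity search.
#' @param t1_range Search range for the apparent T1*, ms.
#' @return A `samba_fit`; `param_value` is the corrected T1.
#'   `converged = FALSE` when `A <= 0` or `B/A <= 1` (inconsistent
#'   recovery, no valid correction).
#' @export
fit_t1_looklocker <- function(signals, protocol,
                              correction = c("flip-angle", "ratio"),
                              full_search = FALSE, t1_range = c(5, 15000)) {
  stopifnot(inherits(protocol, "samba_t1_protocol"))
  correction <- match.arg(correction)
  if (length(signals) != protocol$n_readouts)
    stop("signal length does not match protocol n_readouts", call. = FALSE)
  if (any(!is.finite(signals)) || all(signals == 0))
    return(new_fit_result(param_name = "T1"))
  times <- ll_train_times(protocol)
  res <- ir_polarity_fit(abs(signals), times, t1_range)
  if (is.null(res)) return(new_fit_result(param_name = "T1"))
  if (!is.finite(res$A) || res$A <= 0 || res$B / res$A <= 1)
    return(new_fit_result(residual_rms = res$residual_rms,
                          polarity_flip_index = res$k, param_name = "T1"))
  t1 <- ll_correct(res$t1, res$A, res$B, protocol, correction)
  if (!is.finite(t1) || t1 <= 0)
    return(new_fit_result(residual_rms = res$residual_rms,
                          polarity_flip_index = res$k, param_name = "T1"))
  m0 <- ll_m0(t1, res$t1, res$A, protocol)
  new_fit_result(param_value = t1, m0_estimate = m0,
                 residual_rms = res$residual_rms, converged = TRUE,
                 polarity_flip_index = res$k, param_name = "T1",
                 extra = list(t1_star = res$t1, A = res$A, B = res$B))
}

# --- voxel-wise map fitting -------------------------------------------------

#' Estimate the magnitude-image noise level from background voxels
#'
#' Background (signal-free) magnitude voxels follow a Rayleigh
#' distribution whose median is \eqn{\sigma\sqrt{2\ln 2}}; the median over
#' all out-of-mask voxels and frames is a robust estimate of the Gaussian
#' noise component \eqn{\sigma}.
#'
#' @param series An [image_series()].
#' @param mask Logical matrix of foreground voxels; the estimate uses the
#'   complement.
#' @return Estimated sigma (0 when no background voxel exists).
#' @export
estimate_noise_sigma <- function(series, mask) {
  bg <- which(!as.vector(mask))
  if (!length(bg)) return(0)
  nt <- dim(series$data)[3L]
  v <- matrix(series$data, ncol = nt)[bg, , drop = FALSE]
  stats::median(v) / sqrt(2 * log(2))
}

# vectorized polarity-restored IR solve over many voxels; returns per-voxel
# t1 (apparent), A, B, rss, k. Refinement: 1-D optimize per voxel at its
# winning flip index.
ir_polarity_fit_voxels <- function(sig, times, t1_range, n_grid = 60L) {
  nvox <- nrow(sig); nt <- length(times)
  lg <- seq(log(t1_range[1L]), log(t1_range[2L]), length.out = n_grid)
  jmin <- max.col(-sig, ties.method = "first")
  cand <- sort(unique(pmin(pmax(c(0L, outer(jmin, -3:3, `+`)), 0L), nt)))
  best_rss <- rep(Inf, nvox)
  best_k <- integer(nvox); best_l <- numeric(nvox)
  sum_y2 <- rowSums(sig^2)
  xs <- lapply(lg, function(l) exp(-times / exp(l)))
  for (k in cand) {
    Y <- sig
    if (k > 0L) Y[, seq_len(k)] <- -Y[, seq_len(k)]
    use <- abs(jmin - k) <= 3L | k == 0L
    if (!any(use)) next
    Yu <- Y[use, , drop = FALSE]
    rss_k <- rep(Inf, sum(use)); l_k <- numeric(sum(use))
    for (ii in seq_along(lg)) {
      sub <- ir_linear_sub(Yu, sum_y2[use], xs[[ii]])
      upd <- sub$rss < rss_k
      rss_k[upd] <- sub$rss[upd]; l_k[upd] <- lg[ii]
    }
    upd_v <- which(use)[rss_k < best_rss[use]]
    sel <- rss_k < best_rss[use]
    best_rss[upd_v] <- rss_k[sel]
    best_k[upd_v] <- k
    best_l[upd_v] <- l_k[sel]
  }
  dl <- lg[2L] - lg[1L]
  t1 <- numeric(nvox); A <- numeric(nvox); B <- numeric(nvox)
  rss <- numeric(nvox)
  for (v in seq_len(nvox)) {
    y <- sig[v, ]
    if (best_k[v] > 0L) y[seq_len(best_k[v])] <- -y[seq_len(best_k[v])]
    opt <- stats::optimize(ir_rss_scalar,
                           c(best_l[v] - dl, best_l[v] + dl),
                           y = y, times = times, tol = 1e-8)
    sub <- ir_linear_sub(matrix(y, nrow = 1), sum(y * y),
                         exp(-times / exp(opt$minimum)))
    t1[v] <- exp(opt$minimum); A[v] <- sub$A; B[v] <- -sub$C
    rss[v] <- opt$objective
  }
  list(t1 = t1, A = A, B = B, rss = rss, k = best_k)
}

#' Voxel-wise least-squares parameter mapping
#'
#' Applies the protocol-appropriate least-squares fit to every in-mask
#' voxel of a magnitude series: log-linear T2 fitting for T2-prepared
#' protocols, polarity-restored IR fitting for the spin-echo IR protocol,
#' and Look-Locker-corrected fitting for the inversion-prepared spiral
#' train. Out-of-mask and degenerate voxels are flagged invalid. The fit
#' residual RMS is stored as the map's quality channel.
#'
#' When `noise_sigma` is unset it is estimated from the out-of-mask
#' (background) voxels of the series — background magnitudes are Rayleigh
#' distributed with median \eqn{\sigma\sqrt{2\ln 2}} — and the standard
#' Rician power correction \eqn{\sqrt{s^2 - 2\sigma^2}} is applied before
#' fitting; for T2 fits, points below the noise floor are excluded (see
#' [fit_t2_loglinear()]).
#'
#' @param series An [image_series()].
#' @param protocol The generating protocol (decides the model).
#' @param mask Optional logical matrix; default fits every voxel.
#' @param noise_sigma Gaussian noise component of the magnitude images;
#'   `NULL` estimates it from background voxels (0 when there are none or
#'   the mask covers everything), 0 disables floor handling.
#' @param floor_factor T2 points below `floor_factor * noise_sigma` are
#'   excluded.
#' @return A [parameter_map()] with method tag `"LSF"`.
#' @export
fit_series <- function(series, protocol, mask = NULL, noise_sigma = NULL,
                       floor_factor = 3) {
  stopifnot(inherits(series, "samba_image_series"),
            inherits(protocol, "samba_protocol"))
  nx <- dim(series$data)[1L]; ny <- dim(series$data)[2L]
  nt <- dim(series$data)[3L]
  axis <- series$frame_axis
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  if (is.null(noise_sigma)) noise_sigma <- estimate_noise_sigma(series, mask)
  idx <- which(as.vector(mask))
  sig <- matrix(series$data, nrow = nx * ny, ncol = nt)[idx, , drop = FALSE]

  values <- matrix(NA_real_, nx, ny); m0 <- matrix(NA_real_, nx, ny)
  quality <- matrix(NA_real_, nx, ny); valid <- matrix(FALSE, nx, ny)
  type <- protocol_type(protocol)
  param_name <- if (type %in% c("samba_t2_protocol", "se_t2_protocol"))
    "T2" else "T1"
  # power correction for the sparse IR samples; the densely sampled
  # Look-Locker train crosses its null between readouts, where clamping
  # corrected magnitudes to zero would distort the crossing, so the train
  # is fitted uncorrected
  if (type == "se_ir_protocol" && noise_sigma > 0)
    sig <- sqrt(pmax(sig^2 - 2 * noise_sigma^2, 0))

  if (param_name == "T2") {
    ok <- rowSums(!is.finite(sig) | sig <= 0) == 0L
    p_v <- if (noise_sigma > 0)
      rowSums(sig > floor_factor * noise_sigma) else rep(nt, nrow(sig))
    ok <- ok & p_v >= 2L
    sigc <- if (noise_sigma > 0)
      sqrt(pmax(sig^2 - 2 * noise_sigma^2, .Machine$double.xmin)) else sig
    for (p in unique(p_v[ok])) {
      sel <- ok & p_v == p
      S <- sigc[sel, seq_len(p), drop = FALSE]
      ax <- axis[seq_len(p)]
      Y <- log(S)
      sx <- sum(ax); sxx <- sum(ax^2)
      det <- p * sxx - sx^2
      sy <- rowSums(Y); sxy <- as.vector(Y %*% ax)
      slope <- (p * sxy - sx * sy) / det
      inter <- (sxx * sy - sx * sxy) / det
      t2 <- -1 / slope
      model_rms <- sqrt(rowMeans((S - exp(inter) * exp(outer(slope, ax)))^2))
      vi <- idx[sel]
      good <- is.finite(t2) & t2 > 0 & t2 <= 10000
      good[is.na(good)] <- FALSE
      values[vi[good]] <- t2[good]
      m0[vi] <- exp(inter)
      quality[vi] <- model_rms
      valid[vi] <- good
    }
  } else if (type == "se_ir_protocol") {
    ok <- rowSums(!is.finite(sig)) == 0L & rowSums(sig^2) > 0
    if (any(ok)) {
      res <- ir_polarity_fit_voxels(abs(sig[ok, , drop = FALSE]), axis,
                                    t1_range = c(5, 30000))
      vi <- idx[ok]
      good <- is.finite(res$t1) & res$t1 > 0 & res$A > 0
      good[is.na(good)] <- FALSE
      values[vi[good]] <- res$t1[good]
      rec <- 1 + exp(-protocol$tr / res$t1)
      m0[vi] <- res$A / rec
      quality[vi] <- sqrt(res$rss / nt)
      valid[vi] <- good
    }
  } else if (type == "samba_t1_protocol") {
    ok <- rowSums(!is.finite(sig)) == 0L & rowSums(sig^2) > 0
    if (any(ok)) {
      res <- ir_polarity_fit_voxels(abs(sig[ok, , drop = FALSE]), axis,
                                    t1_range = c(5, 15000))
      vi <- idx[ok]
      t1c <- vapply(seq_along(res$t1), function(v)
        ll_correct(res$t1[v], res$A[v], res$B[v], protocol), numeric(1))
      good <- is.finite(res$t1) & res$A > 0 & res$B / res$A > 1 &
        is.finite(t1c) & t1c > 0
      good[is.na(good)] <- FALSE
      values[vi[good]] <- t1c[good]
      m0[vi[good]] <- ll_m0(t1c, res$t1, res$A, protocol)[good]
      quality[vi] <- sqrt(res$rss / nt)
      valid[vi] <- good
    }
  } else {
    stop("no least-squares model for protocol type ", type, call. = FALSE)
  }
  parameter_map(values = values, param_name = param_name, m0 = m0,
                quality = quality, valid = valid, fov_mm = series$fov_mm,
                method = "LSF")
}
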