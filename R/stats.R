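#' Per-tube ROI statistics of a parameter map
#'
#' Mean and standard deviation of the valid voxels of each nonzero label.
#' Labels with no valid voxel are kept as flagged rows (`n_valid = 0`,
#' `NA` mean) rather than dropped.
#'
#' @param map A [parameter_map()].
#' @param labels Integer label matrix (0 = background), same geometry as
#'   the map.
#' @param method Method tag column; defaults to the map's tag.
#' @param repeat_index Repeat index column (for repeatability tables).
#' @return A tibble with columns `label`, `n_voxels`, `n_valid`, `mean`,
#'   `sd`, `method`, `repeat_index`.
#' @export
roi_means <- function(map, labels, method = map$method,
                      repeat_index = NA_integer_) {
  stopifnot(inherits(map, "samba_parameter_map"),
            identical(dim(map$values), dim(labels)))
  labs <- sort(unique(labels[labels > 0]))
  rows <- lapply(labs, function(l) {
    in_lab <- labels == l
    ok <- in_lab & map$valid
    v <- map$values[ok]
    tibble::tibble(label = as.integer(l),
                   n_voxels = sum(in_lab), n_valid = sum(ok),
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) > 1L) stats::sd(v) else
                     if (length(v) == 1L) 0 else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  out$method <- method
  out$repeat_index <- repeat_index
  out
}

#' Ordinary least-squares regression between two methods
#'
#' OLS of `y` on `x` with \eqn{R^2 = 1 - SS_{res}/SS_{tot}} — the
#' method-agreement regression reported for each pair of mapping methods.
#'
#' @param x,y Paired estimates, ms (length >= 3).
#' @return A `samba_regression`: `slope`, `intercept` (ms), `r_squared`,
#'   `n`.
#' @examples
#' linear_regression(1:5, 2 * (1:5) + 5)
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 paired points", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in x: regression undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 n = length(x)),
            class = "samba_regression")
}

#' @export
print.samba_regression <- function(x, ...) {
  cat(sprintf(
    "<samba_regression> slope %.4f, intercept %.4g ms, R^2 = %.4f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @exportS3Method
tidy.samba_regression <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method
glance.samba_regression <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = y - x`: `bias = mean(d)`, `sd_diff` the sample (n-1)
#' standard deviation of `d`, and 95% limits of agreement
#' `bias +/- 1.96 * sd_diff`.
#'
#' @param x,y Paired measurements, ms (length >= 2).
#' @return A `samba_bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, plus the per-pair `means` and `diffs` for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("need >= 2 paired points", call. = FALSE)
  d <- y - x
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 n = length(d), means = (x + y) / 2, diffs = d),
            class = "samba_bland_altman")
}

#' @export
print.samba_bland_altman <- function(x, ...) {
  cat(sprintf(
    "<samba_bland_altman> bias %.4g ms, 95%% LOA [%.4g, %.4g] ms (n = %d)\n",
    x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @exportS3Method
tidy.samba_bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff, loa_low = x$loa_low,
                 loa_high = x$loa_high, n = x$n)
}

#' Coefficient of variation over repeated measurements
#'
#' `CV% = sample SD / mean * 100` over the repeat dimension — the
#' repeatability metric computed per tube across the consecutive scans.
#'
#' @param values Estimates over repeats (length >= 2, nonzero mean).
#' @return CV in percent.
#' @examples
#' cv_percent(c(90, 100, 110))
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L)
    stop("need >= 2 repeated values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean is zero: CV%% undefined", call. = FALSE)
  stats::sd(values) / m * 100
}

format_hms <- function(seconds) {
  s <- round(seconds)
  h <- s %/% 3600; m <- (s %% 3600) %/% 60; sec <- s %% 60
  out <- ""
  if (h > 0) out <- paste0(out, h, "h")
  if (m > 0 || (h > 0 && sec > 0)) out <- paste0(out, m, "min")
  if (sec > 0 || out == "") out <- paste0(out, sec, "s")
  out
}

#' Nominal scan time of a protocol
#'
#' Acquisition time from the sequence parameters: the spiral T1 protocol
#' needs one TR per interleaf per average (all readouts of the train fall
#' inside one TR); the spiral T2 protocol one TR per interleaf per
#' preparation time per average; Cartesian spin-echo protocols one TR per
#' phase-encode line per frame per average.
#'
#' @param protocol Any protocol object.
#' @return A `samba_scan_time`: `seconds`, `hours` and a formatted `label`
#'   (e.g. `"3min30s"`).
#' @examples
#' scan_time(protocol_preset("samba-t1"))
#' @export
scan_time <- function(protocol) {
  stopifnot(inherits(protocol, "samba_protocol"))
  tr_s <- protocol$tr / 1000
  seconds <- switch(protocol_type(protocol),
    samba_t1_protocol = protocol$n_interleaves * protocol$nsa * tr_s,
    samba_t2_protocol = protocol$n_interleaves *
      length(protocol$prep_times) * protocol$nsa * tr_s,
    se_ir_protocol = protocol$n_phase_encodes *
      length(protocol$inversion_times) * protocol$nsa * tr_s,
    se_t2_protocol = protocol$n_phase_encodes *
      length(protocol$prep_times) * protocol$nsa * tr_s)
  structure(list(seconds = seconds, hours = seconds / 3600,
                 label = format_hms(seconds)),
            class = "samba_scan_time")
}

#' @export
print.samba_scan_time <- function(x, ...) {
  cat(sprintf("<samba_scan_time> %g s (%s)\n", x$seconds, x$label))
  invisible(x)
}

#' Time-normalized repeatability
#'
#' `CV% * scan time in hours` — the efficiency metric that accounts for
#' the very different acquisition times when comparing repeatability
#' between methods. Method ratios of this product reduce to scan-time
#' ratios when the CVs are equal.
#'
#' @param cv CV in percent (>= 0).
#' @param scan_time_hours Scan duration, hours (>= 0).
#' @return The product, in percent-hours.
#' @export
cv_per_time <- function(cv, scan_time_hours) {
  stopifnot(all(cv >= 0), all(scan_time_hours >= 0))
  cv * scan_time_hours
}

#' Pairwise method comparison report
#'
#' Runs the evaluation battery across every pair of mapping methods: OLS
#' regression and Bland-Altman agreement on per-tube means (averaged over
#' repeats), and a paired two-tailed t-test across tubes. When a
#' ground-truth table is supplied, each method is also compared against
#' the truth.
#'
#' @param roi_table Combined ROI table (rows from [roi_means()], one per
#'   tube x method x repeat) with columns `label`, `mean`, `method`,
#'   `repeat_index`.
#' @param ground_truth Optional tibble with columns `label` and `truth`
#'   (ms).
#' @return A `samba_comparison` whose `pairs` tibble has one row per
#'   ordered comparison (`method_x` is the reference axis) with columns
#'   `slope`, `intercept`, `r_squared`, `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `p_value`, `n_tubes`.
#' @export
compare_methods <- function(roi_table, ground_truth = NULL) {
  stopifnot(all(c("label", "mean", "method") %in% names(roi_table)))
  per_tube <- roi_table |>
    dplyr::group_by(.data$method, .data$label) |>
    dplyr::summarise(mean = mean(.data$mean), .groups = "drop")
  wide <- tidyr::pivot_wider(per_tube, names_from = "method",
                             values_from = "mean") |>
    dplyr::arrange(.data$label)
  methods <- setdiff(names(wide), "label")
  for (m in methods) {
    tube_sets <- per_tube$label[per_tube$method == m]
    if (!setequal(tube_sets, wide$label))
      stop("method ", m, " does not cover the same tube set", call. = FALSE)
  }
  if (!is.null(ground_truth)) {
    stopifnot(all(c("label", "truth") %in% names(ground_truth)))
    wide <- dplyr::left_join(wide, ground_truth[, c("label", "truth")],
                             by = "label")
    methods <- c("truth", methods)
  }
  combos <- utils::combn(methods, 2L)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    mx <- combos[1L, i]; my <- combos[2L, i]
    x <- wide[[mx]]; y <- wide[[my]]
    reg <- linear_regression(x, y)
    ba <- bland_altman(x, y)
    p <- tryCatch(stats::t.test(y, x, paired = TRUE)$p.value,
                  error = function(e) NA_real_)
    tibble::tibble(method_x = mx, method_y = my,
                   slope = reg$slope, intercept = reg$intercept,
                   r_squared = reg$r_squared,
                   bias = ba$bias, loa_low = ba$loa_low,
                   loa_high = ba$loa_high, sd_diff = ba$sd_diff,
                   p_value = p, n_tubes = length(x))
  })
  structure(list(pairs = dplyr::bind_rows(rows), per_tube = wide),
            class = "samba_comparison")
}

#' @export
print.samba_comparison <- function(x, ...) {
  cat("<samba_comparison>\n")
  print(as.data.frame(x$pairs), digits = 4)
  invisible(x)
}

#' @exportS3Method
tidy.samba_comparison <- function(x, ...) x$pairs

#' Per-tube repeatability table
#'
#' CV% across repeats for every tube of one method's ROI table, with the
#' scan-time-normalized product attached.
#'
#' @param roi_table ROI rows of a single method across repeats.
#' @param scan_time_hours That method's nominal scan time, hours.
#' @return Tibble with `label`, `cv_percent`, `scan_time_hours`,
#'   `cv_times_time`.
#' @export
cv_table <- function(roi_table, scan_time_hours) {
  roi_table |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(cv_percent = cv_percent(.data$mean),
                     .groups = "drop") |>
    dplyr::mutate(scan_time_hours = scan_time_hours,
                  cv_times_time = cv_per_time(.data$cv_percent,
                                              scan_time_hours))
}
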