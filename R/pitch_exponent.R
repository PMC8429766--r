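#' Fit the pitch-exponent k from frequency shift ratios
#'
#' The metamer model predicts that the PSE shift ratio `mu / mu_ref` measured
#' at an amplitude change factor `acf = A / A_ref` obeys the power law
#' `mu / mu_ref = (A_ref / A)^k = acf^(-k)`. Taking logs turns this into a
#' straight line through the origin, `log(shift_ratio) = k * (-log(acf))`, so
#' the primary estimator is a no-intercept linear regression of
#' `log(shift_ratio)` on `-log(acf)` (the only reading under which a linear
#' least-squares routine fits this power law). A nonlinear least-squares
#' estimate on the linear scale is computed as a cross-check and reported
#' alongside.
#'
#' The 95% confidence interval for k comes from the t distribution on the
#' regression standard error. Following the significance rule used for these
#' fits, `k_effective` equals k when the CI excludes zero and 0 otherwise.
#' Rows with `acf == 1` carry a zero regressor and are dropped from the
#' regression.
#'
#' @param data A tibble with columns `acf` (> 0) and `shift_ratio` (> 0);
#'   optional columns such as `subject` are carried along.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `pitch_exponent_fit` with elements `k`, `k_se`,
#'   `k_ci`, `significant`, `k_effective`, `k_nls` (cross-check), `n_points`,
#'   `residual_ss` (linear scale) and the input data.
#' @examples
#' acf <- c(0.196, 0.464, 0.732, 1.268, 1.536)
#' d <- tibble::tibble(acf = acf, shift_ratio = acf^-0.32)
#' fit_pitch_exponent(d)$k
#' @export
fit_pitch_exponent <- function(data, conf = 0.95) {
  req <- c("acf", "shift_ratio")
  if (!all(req %in% names(data))) {
    abort("`data` must have columns `acf` and `shift_ratio`.",
          class = "vibropitch_schema_error")
  }
  check_positive(data$acf, "acf")
  check_positive(data$shift_ratio, "shift_ratio")
  d <- data[data$acf != 1, , drop = FALSE]
  if (nrow(d) < 2L) {
    abort("Need at least 2 data points with acf != 1; k is unidentifiable otherwise.",
          class = "vibropitch_fit_error")
  }
  xx <- -log(d$acf)
  yy <- log(d$shift_ratio)
  k <- sum(xx * yy) / sum(xx^2)
  res <- yy - k * xx
  df <- nrow(d) - 1L
  k_se <- sqrt(sum(res^2) / df / sum(xx^2))
  tq <- qt(1 - (1 - conf) / 2, df)
  k_ci <- c(k - tq * k_se, k + tq * k_se)
  significant <- k_ci[1] > 0 || k_ci[2] < 0

  # nonlinear cross-check: least squares on the linear (ratio) scale
  sse_lin <- function(kk) sum((d$shift_ratio - d$acf^(-kk))^2)
  k_nls <- optimize(sse_lin, interval = k + c(-2, 2), tol = 1e-9)$minimum

  structure(
    list(
      k = k, k_se = k_se, k_ci = k_ci, conf = conf,
      significant = significant,
      k_effective = if (significant) k else 0,
      k_nls = k_nls,
      n_points = nrow(d),
      residual_ss = sse_lin(k),
      data = data
    ),
    class = "pitch_exponent_fit"
  )
}

#' @export
print.pitch_exponent_fit <- function(x, ...) {
  cat(sprintf(
    "Pitch exponent fit (A^k x f metamer model)\n  k = %.4g  [%.4g, %.4g] %d%% CI  (%ssignificant; k_effective = %.4g)\n  nonlinear cross-check k = %.4g; n = %d points\n",
    x$k, x$k_ci[1], x$k_ci[2], round(100 * x$conf),
    if (x$significant) "" else "not ", x$k_effective, x$k_nls, x$n_points
  ))
  invisible(x)
}

#' @export
tidy.pitch_exponent_fit <- function(x, ...) {
  tibble(
    term = "k",
    estimate = x$k,
    std.error = x$k_se,
    conf.low = x$k_ci[1],
    conf.high = x$k_ci[2]
  )
}

#' @export
glance.pitch_exponent_fit <- function(x, ...) {
  tibble(
    k = x$k, k_effective = x$k_effective, significant = x$significant,
    k_nls = x$k_nls, n_points = x$n_points, residual_ss = x$residual_ss
  )
}

#' Map shift-ratio data and a fitted exponent back to stimulus space
#'
#' Rescales the dimensionless shift data into physical units (amplitudes by
#' the reference amplitude, frequencies by the reference frequency) and
#' overlays the fitted equal-pitch curve evaluated with `k_effective`. The
#' point at `acf = 1`, `shift_ratio = 1` maps to the reference stimulus.
#'
#' @param fit A [fit_pitch_exponent()] object.
#' @param ref_frequency,ref_amplitude Reference stimulus (Hz, micrometres).
#' @param data Shift data to map (default: the fit's own data).
#' @param n_curve Number of curve points for the overlay (default 50).
#' @return A list of class `equal_pitch_overlay` with `points` (tibble
#'   `amplitude_um`, `frequency_hz`) and `curve` (an [equal_pitch_curve()]).
#' @export
equal_pitch_points <- function(fit, ref_frequency, ref_amplitude,
                               data = fit$data, n_curve = 50L) {
  stopifnot(inherits(fit, "pitch_exponent_fit"))
  check_positive(ref_frequency, "ref_frequency", scalar = TRUE)
  check_positive(ref_amplitude, "ref_amplitude", scalar = TRUE)
  pts <- tibble(
    amplitude_um = data$acf * ref_amplitude,
    frequency_hz = data$shift_ratio * ref_frequency
  )
  amps <- exp(seq(log(min(pts$amplitude_um)), log(max(pts$amplitude_um)),
                  length.out = n_curve))
  structure(
    list(
      points = pts,
      curve = equal_pitch_curve(ref_frequency, ref_amplitude, fit$k_effective, amps)
    ),
    class = "equal_pitch_overlay"
  )
}
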