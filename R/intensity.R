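#' Fit a descriptive sum-of-exponentials equal-intensity curve
#'
#' Equal-intensity data (amplitude as a function of frequency at matched
#' perceived intensity) are fit with `A = a * exp(b * f) + c * exp(d * f)`.
#' The sum-of-exponentials family is notoriously ill-conditioned, so the fit
#' uses variable projection: for each candidate rate pair `(b, d)` the linear
#' coefficients `(a, c)` are solved exactly by least squares, and the profiled
#' objective is minimised over `(b, d)` by Nelder-Mead from a grid of starts
#' covering all sign patterns. The individual parameters are reported with the
#' explicit caveat that they are descriptive and not separately identifiable;
#' the fitted curve, not its parameters, is the meaningful output.
#'
#' @param data A tibble with columns `frequency` (Hz) and `amplitude`
#'   (micrometres); an optional `subject` column enables subject-level
#'   bootstrap.
#' @param n_boot Bootstrap resamples for parameter SDs (default 200; 0 skips).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `intensity_curve_fit` with elements `a`, `b`,
#'   `c`, `d`, `param_sd`, `fit_range`, `rss` and the data. Use
#'   [predict.intensity_curve_fit()] to evaluate the curve.
#' @export
fit_intensity_curve <- function(data, n_boot = 200L, seed = 1L) {
  req <- c("frequency", "amplitude")
  if (!all(req %in% names(data))) {
    abort("`data` must have columns `frequency` and `amplitude`.",
          class = "vibropitch_schema_error")
  }
  if (nrow(data) < 5L || dplyr::n_distinct(data$frequency) < 3L) {
    abort("Need >= 5 points spanning >= 3 distinct frequencies.",
          class = "vibropitch_fit_error")
  }
  check_positive(data$frequency, "frequency")
  check_positive(data$amplitude, "amplitude")

  core <- sumexp_core_fit(data$frequency, data$amplitude)
  if (is.null(core)) {
    abort("Sum-of-exponentials fit failed to converge from every start.",
          class = "vibropitch_fit_error")
  }

  param_sd <- c(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_)
  if (n_boot > 0L) {
    boots <- withr::with_seed(as.integer(seed), {
      purrr::map(seq_len(n_boot), function(i) {
        db <- if ("subject" %in% names(data)) {
          subs <- unique(data$subject)
          picked <- sample(subs, length(subs), replace = TRUE)
          purrr::map_dfr(picked, function(s) data[data$subject == s, , drop = FALSE])
        } else {
          data[sample.int(nrow(data), replace = TRUE), , drop = FALSE]
        }
        if (dplyr::n_distinct(db$frequency) < 3L) return(NULL)
        sumexp_core_fit(db$frequency, db$amplitude, starts = list(c(core$b, core$d)))
      })
    })
    boots <- purrr::compact(boots)
    if (length(boots) >= 10L) {
      pm <- do.call(rbind, purrr::map(boots, ~ c(.x$a, .x$b, .x$c, .x$d)))
      param_sd <- setNames(apply(pm, 2, sd), c("a", "b", "c", "d"))
    }
  }

  structure(
    list(
      a = core$a, b = core$b, c = core$c, d = core$d,
      param_sd = param_sd, rss = core$rss,
      fit_range = range(data$frequency), data = data
    ),
    class = "intensity_curve_fit"
  )
}

# variable-projection core: minimise over (b, d), solve (a, c) linearly
sumexp_core_fit <- function(f, A, starts = NULL) {
  fscale <- max(abs(f))
  rate_cap <- 50 / fscale   # keep exp arguments bounded
  proj <- function(bd) {
    b <- bd[1]; d <- bd[2]
    if (abs(b) > rate_cap || abs(d) > rate_cap) return(list(rss = Inf))
    X <- if (abs(b - d) < 1e-10) cbind(exp(b * f)) else cbind(exp(b * f), exp(d * f))
    fit <- tryCatch(stats::lm.fit(X, A), error = function(e) NULL)
    if (is.null(fit)) return(list(rss = Inf))
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    rss <- sum(fit$residuals^2)
    if (length(cf) == 1L) cf <- c(cf, 0)
    list(rss = rss, coef = cf)
  }
  obj <- function(bd) proj(bd)$rss
  if (is.null(starts)) {
    mags <- c(0.02, 0.005, 0.001) / (fscale / 534)
    starts <- list()
    for (m1 in mags) for (m2 in mags) {
      starts <- c(starts, list(c(-m1, m2), c(-m1, -m2), c(m1, m2)))
    }
  }
  best <- NULL
  n_fail <- 0L
  for (st in starts) {
    res <- tryCatch(
      optim(st, obj, method = "Nelder-Mead",
            control = list(maxit = 800, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) { n_fail <- n_fail + 1L; next }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || n_fail > length(starts) / 2) return(NULL)
  pr <- proj(best$par)
  list(a = pr$coef[1], b = best$par[1], c = pr$coef[2], d = best$par[2],
       rss = pr$rss)
}

#' Evaluate a fitted equal-intensity curve
#'
#' @param object An `intensity_curve_fit`.
#' @param frequency Frequencies at which to evaluate the curve (Hz).
#' @param ... Unused.
#' @return Amplitudes in micrometres. Queries outside the fitted frequency
#'   range are returned but flagged with a warning (the fit is descriptive and
#'   not meant to extrapolate).
#' @export
predict.intensity_curve_fit <- function(object, frequency, ...) {
  if (any(frequency < object$fit_range[1] | frequency > object$fit_range[2])) {
    warn("Evaluating the equal-intensity fit outside its fitted frequency range; the fit is descriptive only.")
  }
  object$a * exp(object$b * frequency) + object$c * exp(object$d * frequency)
}

#' @export
print.intensity_curve_fit <- function(x, ...) {
  cat(sprintf(
    "Equal-intensity fit A = a e^(b f) + c e^(d f) (descriptive; parameters not separately identifiable)\n  a = %.4g, b = %.4g, c = %.4g, d = %.4g, rss = %.3g, range [%.4g, %.4g] Hz\n",
    x$a, x$b, x$c, x$d, x$rss, x$fit_range[1], x$fit_range[2]
  ))
  invisible(x)
}

#' @export
tidy.intensity_curve_fit <- function(x, ...) {
  tibble(
    term = c("a", "b", "c", "d"),
    estimate = c(x$a, x$b, x$c, x$d),
    std.error = unname(x$param_sd)
  )
}

#' @export
glance.intensity_curve_fit <- function(x, ...) {
  tibble(rss = x$rss, n = nrow(x$data),
         f_lo = x$fit_range[1], f_hi = x$fit_range[2])
}

#' Natural cubic-spline interpolation of equal-intensity data
#'
#' Interpolates (frequency, amplitude) equal-intensity points with a natural
#' cubic spline, exact at the knots. Extrapolation outside the knot range is
#' an error: the equal-intensity data are only valid inside the measured
#' range.
#'
#' @param points A tibble with columns `frequency`, `amplitude`.
#' @param query_f Frequencies at which to interpolate (Hz).
#' @return Interpolated amplitudes in micrometres.
#' @export
interpolate_equal_intensity <- function(points, query_f) {
  req <- c("frequency", "amplitude")
  if (!all(req %in% names(points))) {
    abort("`points` must have columns `frequency` and `amplitude`.",
          class = "vibropitch_schema_error")
  }
  rng <- range(points$frequency)
  if (any(query_f < rng[1] | query_f > rng[2])) {
    abort("`query_f` outside the interpolation range; extrapolation is not supported.",
          class = "vibropitch_domain_error")
  }
  spline(points$frequency, points$amplitude, method = "natural", xout = query_f)$y
}

#' Aggregate per-subject detection thresholds into a sensitivity curve
#'
#' Computes the mean (and SEM) detection threshold per frequency across
#' subjects, with available-case handling of missing thresholds (counts are
#' recorded per frequency). Reports both the grid argmin of the mean curve
#' (`best_frequency`) and a continuous estimate from the vertex of a quadratic
#' fit of log threshold on log frequency (`best_frequency_interp`), which can
#' resolve a sensitivity peak lying between tested frequencies.
#'
#' @param data A tibble with columns `subject`, `frequency`, `threshold`
#'   (micrometres; `NA` allowed for sessions without a measurable threshold).
#' @return A tibble of class `sensitivity_estimate` with columns `frequency`,
#'   `mean_threshold`, `sem`, `n`, and attributes `best_frequency` and
#'   `best_frequency_interp`.
#' @export
aggregate_sensitivity <- function(data) {
  req <- c("subject", "frequency", "threshold")
  if (!all(req %in% names(data))) {
    abort("`data` must have columns `subject`, `frequency`, `threshold`.",
          class = "vibropitch_schema_error")
  }
  if (dplyr::n_distinct(data$frequency) < 2L) {
    abort("Need thresholds at >= 2 frequencies.", class = "vibropitch_fit_error")
  }
  agg <- data |>
    dplyr::filter(!is.na(.data$threshold)) |>
    dplyr::group_by(.data$frequency) |>
    dplyr::summarise(
      mean_threshold = mean(.data$threshold),
      sem = sd(.data$threshold) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$frequency)
  best <- agg$frequency[which.min(agg$mean_threshold)]
  lx <- log(agg$frequency); ly <- log(agg$mean_threshold)
  qf <- lm(ly ~ lx + I(lx^2))
  b <- coef(qf)
  best_interp <- if (length(b) == 3 && is.finite(b[3]) && b[3] > 0) {
    unname(exp(-b[2] / (2 * b[3])))
  } else NA_real_
  structure(agg,
    best_frequency = best,
    best_frequency_interp = best_interp,
    class = c("sensitivity_estimate", class(agg))
  )
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat(sprintf(
    "V-shaped sensitivity curve: best frequency %.4g Hz (grid), %.4g Hz (interpolated)\n",
    attr(x, "best_frequency"), attr(x, "best_frequency_interp")
  ))
  NextMethod()
}
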