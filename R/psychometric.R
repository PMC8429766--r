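#' Bin trial-level responses by stimulus level
#'
#' Aggregates a trial table into the binned-response format consumed by
#' [fit_psychometric()]: one row per stimulus level with the number of trials
#' and the number of "chosen" responses (go responses, or "test higher"
#' judgements).
#'
#' @param data A trial table (one row per trial).
#' @param level Column holding the stimulus value (tidy-eval).
#' @param chosen Logical column holding the response of interest (tidy-eval).
#' @return A tibble with columns `level`, `n_chosen`, `n_total`, sorted by level.
#' @examples
#' trials <- tibble::tibble(f = rep(c(400, 500), each = 5),
#'                          lick = c(rep(FALSE, 4), TRUE, rep(TRUE, 4), FALSE))
#' bin_responses(trials, f, lick)
#' @export
bin_responses <- function(data, level, chosen) {
  data |>
    dplyr::group_by(level = {{ level }}) |>
    dplyr::summarise(n_chosen = sum({{ chosen }}), n_total = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$level)
}

psi_fun <- function(x, mu, sigma, lapse, guess) {
  guess + (1 - guess - lapse) * pnorm((x - mu) / sigma)
}

# negative binomial log-likelihood of the cumulative-Gaussian psychometric
psycho_nll <- function(par, level, n_chosen, n_total, equal_asymptotes) {
  mu <- par[1]
  sigma <- exp(par[2])
  lapse <- par[3]
  guess <- if (equal_asymptotes) par[3] else par[4]
  p <- psi_fun(level, mu, sigma, lapse, guess)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(n_chosen * log(p) + (n_total - n_chosen) * log1p(-p))
}

#' Fit a cumulative-Gaussian psychometric function by maximum likelihood
#'
#' Fits `psi(x) = guess + (1 - guess - lapse) * Phi((x - mu) / sigma)` to
#' binned binomial responses by direct maximisation of the binomial
#' log-likelihood, with multi-start box-constrained optimisation. With
#' `equal_asymptotes = TRUE` (the default, matching the usual
#' equal-asymptote mode of psychometric toolboxes) the guess rate is
#' constrained equal to the lapse rate; otherwise both are free. Lapse and
#' guess are bounded to `[0, lapse_max]` during optimisation to prevent
#' asymptote/slope trade-off degeneracy.
#'
#' The fitted `mu` is the point of subjective equality (PSE). The response
#' probability is assumed to increase with `level`.
#'
#' @param data A tibble with columns `level`, `n_chosen`, `n_total`
#'   (see [bin_responses()]). Duplicate levels are pooled.
#' @param equal_asymptotes Constrain guess = lapse (default `TRUE`).
#' @param lapse_max Upper bound for lapse and guess rates (default 0.25).
#' @param n_starts Number of optimisation starts (deterministic heuristics;
#'   default 5).
#' @return An object of class `psychometric_fit` with elements `mu`, `sigma`,
#'   `lapse`, `guess`, `loglik`, `mu_ci` (filled by [bootstrap_mu()]),
#'   `convergence` (per-start report) and the input data.
#' @examples
#' d <- tibble::tibble(level = c(310, 345, 380, 415, 485, 520, 555, 590),
#'                     n_total = 50)
#' d$n_chosen <- round(d$n_total * pnorm((d$level - 450) / 60))
#' fit <- fit_psychometric(d)
#' fit$mu
#' @export
fit_psychometric <- function(data, equal_asymptotes = TRUE, lapse_max = 0.25,
                             n_starts = 5L) {
  req <- c("level", "n_chosen", "n_total")
  if (!all(req %in% names(data))) {
    abort(paste0("`data` must have columns: ", paste(req, collapse = ", ")),
          class = "vibropitch_schema_error")
  }
  d <- data |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(n_chosen = sum(.data$n_chosen), n_total = sum(.data$n_total),
                     .groups = "drop") |>
    dplyr::filter(.data$n_total > 0) |>
    dplyr::arrange(.data$level)
  if (nrow(d) < 4L) {
    abort("Need at least 4 stimulus levels with trials to fit a psychometric function.",
          class = "vibropitch_fit_error")
  }
  if (any(d$n_chosen < 0) || any(d$n_chosen > d$n_total)) {
    abort("`n_chosen` must lie in [0, n_total].", class = "vibropitch_schema_error")
  }
  if (all(d$n_chosen == 0) || all(d$n_chosen == d$n_total)) {
    abort("Degenerate data: responses are constant across levels (all 0 or all maximal).",
          class = "vibropitch_fit_error")
  }

  x <- d$level; k <- d$n_chosen; n <- d$n_total
  rng <- range(x); r <- diff(rng)
  mu_lo <- rng[1] - 2 * r; mu_hi <- rng[2] + 2 * r
  ls_lo <- log(r / 100); ls_hi <- log(5 * r)

  # probit-regression start, with quantile fallback
  p_emp <- (k + 0.5) / (n + 1)
  init <- tryCatch({
    g <- suppressWarnings(stats::glm(cbind(k, n - k) ~ x, family = stats::binomial("probit")))
    b <- coef(g)
    if (is.finite(b[2]) && b[2] > 1e-8) c(-b[1] / b[2], 1 / b[2]) else NULL
  }, error = function(e) NULL)
  if (is.null(init)) {
    mu0 <- stats::approx(p_emp, x, xout = 0.5, ties = mean, rule = 2)$y
    init <- c(mu0, r / 4)
  }
  mu0 <- min(max(init[1], mu_lo), mu_hi)
  s0 <- min(max(init[2], exp(ls_lo)), exp(ls_hi))

  start_grid <- list(
    c(mu0, s0), c(mu0, 2 * s0), c(mu0 + 0.2 * r, s0),
    c(mu0 - 0.2 * r, s0), c(mean(rng), r / 3)
  )[seq_len(max(1L, min(n_starts, 5L)))]

  npar <- if (equal_asymptotes) 3L else 4L
  lower <- c(mu_lo, ls_lo, 0, 0)[seq_len(npar)]
  upper <- c(mu_hi, ls_hi, lapse_max, lapse_max)[seq_len(npar)]

  runs <- purrr::map(start_grid, function(st) {
    par0 <- c(min(max(st[1], mu_lo), mu_hi), log(min(max(st[2], exp(ls_lo)), exp(ls_hi))),
              0.02, 0.02)[seq_len(npar)]
    tryCatch(
      optim(par0, psycho_nll, level = x, n_chosen = k, n_total = n,
            equal_asymptotes = equal_asymptotes, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 400)),
      error = function(e) NULL
    )
  })
  runs <- purrr::compact(runs)
  if (length(runs) == 0L) {
    abort("Psychometric fit failed to converge from every start.",
          class = "vibropitch_fit_error")
  }
  report <- tibble(
    start = seq_along(runs),
    nll = purrr::map_dbl(runs, "value"),
    converged = purrr::map_int(runs, "convergence") == 0L
  )
  best <- runs[[which.min(report$nll)]]
  par <- best$par
  # a PSE pinned to the search boundary means the likelihood is monotone in
  # mu over the admissible range: the PSE is not identifiable from these data
  mu_at_bound <- par[1] <= mu_lo + 1e-6 * r || par[1] >= mu_hi - 1e-6 * r
  fit <- structure(
    list(
      mu = par[1], sigma = exp(par[2]),
      lapse = par[3], guess = if (equal_asymptotes) par[3] else par[4],
      equal_asymptotes = equal_asymptotes,
      loglik = -best$value, mu_ci = NULL, mu_at_bound = mu_at_bound,
      lapse_max = lapse_max, data = d, convergence = report
    ),
    class = "psychometric_fit"
  )
  fit
}

#' Evaluate a fitted psychometric function
#'
#' @param object A `psychometric_fit`.
#' @param x Stimulus values at which to evaluate the fitted function.
#' @param ... Unused.
#' @return Predicted response probabilities.
#' @export
predict.psychometric_fit <- function(object, x, ...) {
  psi_fun(x, object$mu, object$sigma, object$lapse, object$guess)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Cumulative-Gaussian psychometric fit (%s asymptotes)\n  mu = %.4g, sigma = %.4g, lapse = %.3g, guess = %.3g, loglik = %.2f\n",
    if (x$equal_asymptotes) "equal" else "free",
    x$mu, x$sigma, x$lapse, x$guess, x$loglik
  ))
  if (!is.null(x$mu_ci)) cat(sprintf("  mu 95%% CI: [%.4g, %.4g]\n", x$mu_ci[1], x$mu_ci[2]))
  invisible(x)
}

#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble(
    term = c("mu", "sigma", "lapse", "guess"),
    estimate = c(x$mu, x$sigma, x$lapse, x$guess)
  )
}

#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik,
    n_levels = nrow(x$data),
    n_trials = sum(x$data$n_total),
    equal_asymptotes = x$equal_asymptotes,
    converged = any(x$convergence$converged)
  )
}

#' Bootstrap confidence interval for the PSE
#'
#' Nonparametric bootstrap of the fitted `mu`: per level, responses are
#' resampled binomially at the observed response rate, the psychometric
#' function is refit, and the percentile interval of the resampled `mu` values
#' is returned. Deterministic given `seed`.
#'
#' @inheritParams fit_psychometric
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A list with `ci` (length-2 vector), `mu_boot` (successful resample
#'   estimates) and `n_failed`. Errors if more than 20% of resample fits fail.
#' @export
bootstrap_mu <- function(data, equal_asymptotes = TRUE, n_boot = 500L, seed = 1L,
                         conf = 0.95) {
  base_fit <- fit_psychometric(data, equal_asymptotes = equal_asymptotes)
  d <- base_fit$data
  p_hat <- d$n_chosen / d$n_total
  mu_boot <- withr::with_seed(as.integer(seed), {
    purrr::map_dbl(seq_len(n_boot), function(b) {
      db <- d
      db$n_chosen <- rbinom(nrow(d), d$n_total, p_hat)
      tryCatch(
        fit_psychometric(db, equal_asymptotes = equal_asymptotes, n_starts = 2L)$mu,
        error = function(e) NA_real_
      )
    })
  })
  n_failed <- sum(is.na(mu_boot))
  if (n_failed > 0.2 * n_boot) {
    abort(sprintf("Bootstrap failed on %d of %d resamples.", n_failed, n_boot),
          class = "vibropitch_fit_error")
  }
  a <- (1 - conf) / 2
  ci <- unname(quantile(mu_boot, c(a, 1 - a), na.rm = TRUE))
  list(ci = ci, mu_boot = mu_boot[!is.na(mu_boot)], n_failed = n_failed)
}
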