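test_that("the pitch-exponent fit inverts noiseless power-law data exactly", {
  for (k_true in c(0.32, -0.24, -0.044, 0)) {
    fit <- fit_pitch_exponent(noiseless_shift(k_true))
    expect_equal(fit$k, k_true, tolerance = 1e-10)
    expect_equal(fit$k_nls, k_true, tolerance = 1e-4)
  }
})

test_that("flat shift ratios give k = 0 with a CI spanning zero", {
  d <- tibble::tibble(acf = c(0.5, 0.7, 1.3, 1.6),
                      shift_ratio = rep(1, 4))
  fit <- fit_pitch_exponent(d)
  expect_equal(fit$k, 0)
  expect_false(fit$significant)
  expect_equal(fit$k_effective, 0)
})

test_that("acf = 1 points do not influence the fitted exponent", {
  d <- noiseless_shift(0.32)
  d$shift_ratio <- d$shift_ratio * exp(c(0.02, -0.01, 0.015, -0.02, 0.005))
  fit1 <- fit_pitch_exponent(d)
  fit2 <- fit_pitch_exponent(dplyr::bind_rows(
    d, tibble::tibble(acf = 1, shift_ratio = 1)))
  expect_equal(fit1$k, fit2$k, tolerance = 1e-12)
  expect_error(fit_pitch_exponent(tibble::tibble(acf = c(1, 1),
                                                 shift_ratio = c(1, 1))),
               class = "vibropitch_fit_error")
})

test_that("log-space and nonlinear estimators agree on clean data", {
  d <- noiseless_shift(-0.24)
  fit <- fit_pitch_exponent(d)
  expect_lt(abs(fit$k - fit$k_nls), 0.01)
})

test_that("the estimator is unbiased at realistic noise over many replicates", {
  # shift ratios with lognormal measurement error of the magnitude the
  # psychometric stage delivers (sd ~ 0.04 on the log scale)
  acf <- rep(c(0.196, 0.464, 0.732, 1.268, 1.536), 4)
  for (k_true in c(-0.3, 0, 0.3)) {
    khat <- withr::with_seed(round(100 + k_true * 10), {
      vapply(seq_len(200), function(i) {
        d <- tibble::tibble(
          acf = acf,
          shift_ratio = acf^(-k_true) * exp(rnorm(length(acf), 0, 0.04))
        )
        fit_pitch_exponent(d)$k
      }, numeric(1))
    })
    expect_lt(abs(mean(khat) - k_true), 0.02)
  }
})

test_that("the significance gate fires at about its nominal rate when k = 0", {
  acf <- rep(c(0.196, 0.464, 0.732, 1.268, 1.536), 4)
  sig <- withr::with_seed(77, {
    vapply(seq_len(200), function(i) {
      d <- tibble::tibble(acf = acf,
                          shift_ratio = exp(rnorm(length(acf), 0, 0.04)))
      fit_pitch_exponent(d)$significant
    }, logical(1))
  })
  expect_lte(mean(sig), 0.10)   # nominal 5%, binomial slack at 200 replicates
})

test_that("shift data map back to stimulus space around the reference", {
  fit <- fit_pitch_exponent(noiseless_shift(-0.24, acf = c(0.624, 0.831, 1.2)))
  ov <- equal_pitch_points(fit, ref_frequency = 440, ref_amplitude = 11.8,
                           data = tibble::tibble(acf = c(1, 0.624),
                                                 shift_ratio = c(1, 0.624^0.24)))
  expect_equal(ov$points$amplitude_um, c(11.8, 0.624 * 11.8))
  expect_equal(ov$points$frequency_hz[1], 440)
  expect_equal(ov$points$frequency_hz[2], 440 * exp(0.24 * log(0.624)),
               tolerance = 1e-12)
  # non-significant fit: flat overlay at the reference frequency
  flat <- fit_pitch_exponent(tibble::tibble(acf = c(0.6, 0.8, 1.3, 1.7),
                                            shift_ratio = rep(1, 4)))
  ov2 <- equal_pitch_points(flat, 440, 11.8)
  expect_equal(ov2$curve$frequency_hz, rep(440, nrow(ov2$curve)))
})

test_that("the sum-of-exponentials fit reproduces noiseless curves at the knots", {
  f <- c(75, 100, 150, 200, 266, 300, 350, 400, 466, 534)
  A <- 2 * exp(-0.01 * f) + 0.001 * exp(0.01 * f)
  fit <- fit_intensity_curve(tibble::tibble(frequency = f, amplitude = A),
                             n_boot = 0)
  expect_equal(predict(fit, f), A, tolerance = 1e-6)
  # collapsed family b = d: the fit recovers the single-exponential curve
  A2 <- 2.5 * exp(-0.004 * f)
  fit2 <- fit_intensity_curve(tibble::tibble(frequency = f, amplitude = A2),
                              n_boot = 0)
  expect_equal(predict(fit2, f), A2, tolerance = 1e-6)
})

test_that("V-shaped data produce a fitted minimum inside the data range", {
  v <- sensitivity_curve_params(240, 0.2, 0.4)
  f <- c(75, 100, 150, 200, 266, 400, 534)
  A <- 10 * detection_threshold(f, v) / detection_threshold(200, v)
  fit <- fit_intensity_curve(tibble::tibble(frequency = f, amplitude = A),
                             n_boot = 0)
  grid <- seq(75, 534, by = 1)
  fmin <- grid[which.min(predict(fit, grid))]
  expect_gt(fmin, 75)
  expect_lt(fmin, 534)
  expect_error(fit_intensity_curve(tibble::tibble(frequency = c(1, 2),
                                                  amplitude = c(1, 2))),
               class = "vibropitch_fit_error")
})

test_that("sum-of-exponentials bootstrap SDs are deterministic given the seed", {
  f <- c(75, 100, 150, 200, 266, 400, 534)
  A <- 2 * exp(-0.005 * f) + 0.02 * exp(0.006 * f)
  d <- tibble::tibble(frequency = rep(f, 3), subject = rep(1:3, each = 7),
                      amplitude = rep(A, 3) * exp(rnorm(21, 0, 0.02)))
  fit1 <- fit_intensity_curve(d, n_boot = 30L, seed = 5L)
  fit2 <- fit_intensity_curve(d, n_boot = 30L, seed = 5L)
  expect_identical(fit1$param_sd, fit2$param_sd)
})

test_that("equal-intensity interpolation is exact at knots and errors outside", {
  pts <- tibble::tibble(frequency = c(75, 100, 150, 200, 266, 400, 534),
                        amplitude = c(17, 13.4, 10.8, 10, 9.9, 11, 12.7))
  expect_equal(interpolate_equal_intensity(pts, pts$frequency), pts$amplitude)
  expect_error(interpolate_equal_intensity(pts, 600),
               class = "vibropitch_domain_error")
  # collinear points reduce the natural spline to a straight line
  lin <- tibble::tibble(frequency = c(100, 200, 300), amplitude = c(1, 2, 3))
  expect_equal(interpolate_equal_intensity(lin, 150), 1.5, tolerance = 1e-9)
  # samples of a smooth V-curve interpolate to within 5%
  v <- sensitivity_curve_params(240, 0.2, 0.4)
  vc <- tibble::tibble(frequency = pts$frequency,
                       amplitude = 10 * detection_threshold(pts$frequency, v) /
                         detection_threshold(200, v))
  est <- interpolate_equal_intensity(vc, 352)
  truth <- 10 * detection_threshold(352, v) / detection_threshold(200, v)
  expect_equal(est, truth, tolerance = 0.05)
})

test_that("sensitivity aggregation averages subjects and finds the V minimum", {
  one <- tibble::tibble(subject = 1, frequency = c(100, 200, 400),
                        threshold = c(3, 1, 2))
  agg1 <- aggregate_sensitivity(one)
  expect_equal(agg1$mean_threshold, c(3, 1, 2))
  expect_equal(attr(agg1, "best_frequency"), 200)
  two <- tibble::tibble(subject = rep(1:2, each = 2),
                        frequency = rep(c(100, 200), 2),
                        threshold = c(2, 1, 4, 1.5))
  agg2 <- aggregate_sensitivity(two)
  expect_equal(agg2$mean_threshold[agg2$frequency == 100], 3)
  expect_equal(agg2$sem[agg2$frequency == 100], 1)
  # available-case handling of missing cells
  nas <- tibble::tibble(subject = c(1, 2, 1, 2), frequency = c(100, 100, 200, 200),
                        threshold = c(2, NA, 1, 1))
  agg3 <- aggregate_sensitivity(nas)
  expect_equal(agg3$n, c(1L, 2L))
})

test_that("equal-pitch and equal-intensity curves are geometrically distinct", {
  # with k_effective != 0 the two constancy rules must disagree at most points
  v <- sensitivity_curve_params(240, 0.2, 0.4)
  f <- seq(352, 528, by = 8)
  a_ei <- 10 * detection_threshold(f, v) / detection_threshold(200, v)
  a_ep <- attr_amp <- NULL
  k <- -0.24
  a440 <- 10 * detection_threshold(440, v) / detection_threshold(200, v)
  # equal-pitch amplitudes through the same (440 Hz) anchor point
  a_ep <- a440 * (440 / f)^(1 / k)
  rel_diff <- abs(a_ep - a_ei) / a_ei
  expect_gt(mean(rel_diff > 0.05), 0.5)
})
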