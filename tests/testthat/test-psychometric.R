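test_that("the MLE recovers generating parameters at large n", {
  d <- make_binned(mouse_levels, mu = 450, sigma = 60, n_per_level = 10000L,
                   seed = 7)
  fit <- fit_psychometric(d)
  expect_equal(fit$mu, 450, tolerance = 2 / 450)       # within +/- 2 Hz
  expect_equal(fit$sigma, 60, tolerance = 0.05)        # within 5%
})

test_that("free-asymptote fits recover guess and lapse rates", {
  d <- make_binned(mouse_levels, mu = 1000 - 550, sigma = 60, lapse = 0.05,
                   guess = 0.10, n_per_level = 10000L, seed = 11)
  fit <- fit_psychometric(d, equal_asymptotes = FALSE)
  expect_equal(fit$guess, 0.10, tolerance = 0.03 / 0.10)
  expect_equal(fit$lapse, 0.05, tolerance = 0.03 / 0.05)
  expect_equal(fit$mu, 450, tolerance = 0.02)
})

test_that("mirrored counts give a PSE at the centre of symmetry", {
  lv <- c(-3, -2, -1, 1, 2, 3) * 50 + 400
  counts <- c(2, 10, 30, 70, 90, 98)
  d <- tibble::tibble(level = lv, n_chosen = counts, n_total = 100L)
  fit <- fit_psychometric(d)
  expect_equal(fit$mu, 400, tolerance = 1e-3)
})

test_that("predictions hit the defining points of the fitted function", {
  d <- make_binned(mouse_levels, mu = 450, sigma = 60, n_per_level = 5000L)
  fit <- fit_psychometric(d)
  expect_equal(predict(fit, fit$mu), (1 + fit$guess - fit$lapse) / 2,
               tolerance = 1e-9)
  expect_equal(predict(fit, -1e9), fit$guess, tolerance = 1e-9)
  expect_equal(predict(fit, 1e9), 1 - fit$lapse, tolerance = 1e-9)
  expect_equal(predict(fit, fit$mu + fit$sigma),
               fit$guess + (1 - fit$guess - fit$lapse) * pnorm(1),
               tolerance = 1e-9)
})

test_that("fits are equivariant under shift and scale of the level axis", {
  d <- make_binned(mouse_levels, mu = 450, sigma = 60, n_per_level = 300L,
                   seed = 3)
  fit <- fit_psychometric(d)
  d_shift <- dplyr::mutate(d, level = level + 123)
  fit_s <- fit_psychometric(d_shift)
  expect_equal(fit_s$mu, fit$mu + 123, tolerance = 1e-6)
  d_scale <- dplyr::mutate(d, level = level * 2.5)
  fit_m <- fit_psychometric(d_scale)
  expect_equal(fit_m$mu, fit$mu * 2.5, tolerance = 1e-6)
  expect_equal(fit_m$sigma, fit$sigma * 2.5, tolerance = 1e-6)
})

test_that("the equal-asymptote fit never beats the free fit in likelihood", {
  for (seed in 1:4) {
    d <- make_binned(mouse_levels, mu = 430, sigma = 70, lapse = 0.06,
                     guess = 0.03, n_per_level = 200L, seed = seed)
    f_eq <- fit_psychometric(d, equal_asymptotes = TRUE)
    f_fr <- fit_psychometric(d, equal_asymptotes = FALSE)
    expect_gte(f_fr$loglik, f_eq$loglik - 1e-6)
  }
})

test_that("the returned optimum is at least as good as every start's result", {
  d <- make_binned(mouse_levels, mu = 480, sigma = 90, n_per_level = 100L,
                   seed = 9)
  fit <- fit_psychometric(d)
  expect_true(all(-fit$loglik <= fit$convergence$nll + 1e-9))
})

test_that("degenerate and malformed inputs raise informative errors", {
  d <- tibble::tibble(level = mouse_levels, n_chosen = 0L, n_total = 10L)
  expect_error(fit_psychometric(d), class = "vibropitch_fit_error")
  d2 <- tibble::tibble(level = c(1, 2, 3), n_chosen = c(0, 5, 9), n_total = 10L)
  expect_error(fit_psychometric(d2), class = "vibropitch_fit_error")
  expect_error(fit_psychometric(tibble::tibble(x = 1)),
               class = "vibropitch_schema_error")
})

test_that("bootstrap CIs are deterministic, contain mu, and shrink with n", {
  d_small <- make_binned(mouse_levels, mu = 450, sigma = 60,
                         n_per_level = 50L, seed = 2)
  d_large <- make_binned(mouse_levels, mu = 450, sigma = 60,
                         n_per_level = 5000L, seed = 2)
  b1 <- bootstrap_mu(d_small, n_boot = 120L, seed = 42L)
  b2 <- bootstrap_mu(d_small, n_boot = 120L, seed = 42L)
  expect_identical(b1$ci, b2$ci)
  fit <- fit_psychometric(d_small)
  expect_true(b1$ci[1] <= fit$mu && fit$mu <= b1$ci[2])
  b_large <- bootstrap_mu(d_large, n_boot = 120L, seed = 42L)
  expect_lt(diff(b_large$ci), diff(b1$ci))
})

test_that("bootstrap CI coverage of the generating PSE is near nominal", {
  n_rep <- 60L
  covered <- vapply(seq_len(n_rep), function(i) {
    d <- make_binned(mouse_levels, mu = 450, sigma = 60, n_per_level = 120L,
                     seed = 1000L + i)
    ci <- bootstrap_mu(d, n_boot = 99L, seed = i)$ci
    ci[1] <= 450 && 450 <= ci[2]
  }, logical(1))
  # nominal 95%; binomial spread at 60 replicates
  expect_gte(mean(covered), 0.85)
})

test_that("tidy and glance return the standard one-row summaries", {
  d <- make_binned(mouse_levels, mu = 450, sigma = 60, n_per_level = 100L)
  fit <- fit_psychometric(d)
  td <- tidy(fit)
  expect_equal(td$term, c("mu", "sigma", "lapse", "guess"))
  gl <- glance(fit)
  expect_equal(gl$n_trials, 800L)
  expect_true(gl$converged)
})
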