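test_that("the frequency staircase follows the doubling/halving rules by hand", {
  # 440 Hz track: delta_max 256, step bounds [32, 64]; start step forced to 32
  s <- freq_staircase(256, 32, 64, delta = 256, step = 32)
  s <- freq_staircase_update(s, TRUE);  expect_equal(s$delta, 224)
  s <- freq_staircase_update(s, TRUE);  expect_equal(s$delta, 192)
  s <- freq_staircase_update(s, TRUE)
  expect_equal(s$delta, 160)
  expect_equal(s$step, 64)            # doubled after the 3rd same-direction change
  s <- freq_staircase_update(s, TRUE);  expect_equal(s$delta, 96)
  s <- freq_staircase_update(s, FALSE)
  expect_equal(s$delta, 160)          # step applied before the reversal halving
  expect_equal(s$step, 32)            # halved at the reversal
})

test_that("staircase steps clip at their bounds", {
  s <- freq_staircase(256, 32, 64, step = 64)
  for (i in 1:6) s <- freq_staircase_update(s, TRUE)
  expect_equal(s$step, 64)            # doubling clipped at step_max
  s2 <- freq_staircase(256, 32, 64, step = 32)
  s2 <- freq_staircase_update(s2, TRUE)
  s2 <- freq_staircase_update(s2, FALSE)
  s2 <- freq_staircase_update(s2, TRUE)
  expect_gte(s2$step, 32)             # halving floored at step_min
})

test_that("delta and step stay in range over random response sequences", {
  for (seed in 1:10) {
    resp <- withr::with_seed(seed, runif(300) < 0.6)
    s <- freq_staircase(256, 32, 64)
    for (r in resp) {
      s <- freq_staircase_update(s, r)
      expect_true(s$step >= 32 && s$step <= 64)
      expect_true(s$delta > 0 && s$delta <= 256)
    }
  }
})

test_that("the 3-down/1-up staircase applies dB steps and reversal halving", {
  s <- updown_staircase(10, step_db = 12)
  s <- updown_update(s, TRUE); s <- updown_update(s, TRUE)
  expect_equal(s$amplitude, 10)                     # no move before the 3rd correct
  s <- updown_update(s, TRUE)
  expect_equal(s$amplitude, 10 * 10^(-12 / 20), tolerance = 1e-12)
  expect_equal(s$consecutive_correct, 0L)
  s <- updown_update(s, TRUE); s <- updown_update(s, TRUE)
  s <- updown_update(s, FALSE)                      # reversal: up, then halve
  expect_equal(s$reversals, 1L)
  expect_equal(s$step_db, 6)
  # step floor at 3 dB
  s$step_db <- 3; s$last_direction <- "up"
  s <- updown_update(s, TRUE); s <- updown_update(s, TRUE); s <- updown_update(s, TRUE)
  expect_equal(s$step_db, 3)
})

test_that("updown_threshold averages the last 10 trial amplitudes", {
  s <- updown_staircase(2)
  s$reversals <- 5L; s$reversal_limit <- 5L
  s$amplitude_history <- rep(2, 12)
  expect_equal(updown_threshold(s), 2)
  s$amplitude_history <- c(rep(9, 5), rep(c(1, 2), 5))
  expect_equal(updown_threshold(s), 1.5)
  s$amplitude_history <- rep(2, 5)
  expect_error(updown_threshold(s), class = "vibropitch_state_error")
  s2 <- updown_staircase(2)
  expect_error(updown_threshold(s2), class = "vibropitch_state_error")
  s2$finished <- TRUE
  expect_error(updown_update(s2, TRUE), class = "vibropitch_state_error")
})

test_that("binomial_onesided_p equals exhaustive outcome enumeration for n <= 12", {
  # oracle: enumerate all 2^n response sequences and count tail mass
  for (n in 1:12) {
    outcomes <- rowSums(as.matrix(expand.grid(rep(list(0:1), n))))
    for (x in 0:n) {
      expect_equal(binomial_onesided_p(x, n), mean(outcomes >= x),
                   tolerance = 1e-12)
    }
  }
  expect_equal(binomial_onesided_p(12, 12), 1 / 4096)
  expect_equal(binomial_onesided_p(10, 12), 79 / 4096)
  expect_equal(binomial_onesided_p(7, 12), 1586 / 4096)
  expect_error(binomial_onesided_p(13, 12), class = "vibropitch_domain_error")
})

test_that("bouts complete at >=6 present / >=12 total and apply the 70/60 rules", {
  feed <- function(st, n_present, n_absent, n_correct) {
    pres <- c(rep(TRUE, n_present), rep(FALSE, n_absent))
    corr <- c(rep(TRUE, n_correct), rep(FALSE, length(pres) - n_correct))
    for (i in seq_along(pres)) st <- bout_update(st, pres[i], corr[i])
    st
  }
  # 10/12 correct (> 70%): attenuate 4 dB
  st <- feed(bout_state(1), 6, 6, 10)
  expect_equal(nrow(st$bouts), 1L)
  expect_equal(st$amplitude, 10^(-4 / 20), tolerance = 1e-12)
  # 7/12 (< 60%): increase 4 dB (here capped at the session maximum of 1)
  st <- feed(bout_state(1, max_amplitude = 2), 6, 6, 7)
  expect_equal(st$amplitude, 10^(4 / 20), tolerance = 1e-12)
  # 8/12 (dead zone): unchanged
  st <- feed(bout_state(1), 6, 6, 8)
  expect_equal(st$amplitude, 1)
  # a bout with 12 trials but only 5 present is not complete
  st <- feed(bout_state(1), 5, 7, 12)
  expect_equal(nrow(st$bouts), 0L)
})

test_that("mouse session thresholds follow the binomial significance rule", {
  st <- bout_state(1)
  st$bouts <- tibble::tibble(amplitude_um = 1, n_correct = 12L,
                             n_present = 6L, n_total = 12L)
  expect_equal(mouse_session_threshold(st), 1)
  st$bouts <- tibble::tibble(amplitude_um = c(1, 0.63),
                             n_correct = c(11L, 7L),
                             n_present = c(6L, 6L), n_total = c(12L, 12L))
  expect_equal(mouse_session_threshold(st), 1)   # lower bout not significant
  st$bouts <- tibble::tibble(amplitude_um = 1, n_correct = 7L,
                             n_present = 6L, n_total = 12L)
  expect_warning(thr <- mouse_session_threshold(st))
  expect_true(is.na(thr))
  st$bouts <- st$bouts[0, ]
  expect_error(mouse_session_threshold(st), class = "vibropitch_state_error")
})

test_that("the session threshold is non-increasing in added correct responses", {
  base <- tibble::tibble(amplitude_um = c(2, 1, 0.5),
                         n_correct = c(11L, 9L, 8L),
                         n_present = c(6L, 6L, 6L), n_total = c(12L, 12L, 12L))
  thr_of <- function(b) {
    st <- bout_state(2); st$bouts <- b
    suppressWarnings(mouse_session_threshold(st))
  }
  t0 <- thr_of(base)
  for (i in 1:3) {
    b2 <- base
    b2$n_correct[i] <- pmin(b2$n_correct[i] + 2L, b2$n_total[i])
    t2 <- thr_of(b2)
    expect_true(is.na(t0) || (!is.na(t2) && t2 <= t0))
  }
})
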