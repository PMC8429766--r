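#' Custom frequency-discrimination staircase
#'
#' Adaptive procedure for the human 2AFC frequency task. The frequency
#' difference between test and standard starts at `delta_max` and is lowered by
#' the current rate of change `step` after each correct answer and raised by
#' `step` after each incorrect answer. After three successive changes in the
#' same direction `step` is doubled (capped at `step_max`); after each change
#' of direction it is halved (floored at `step_min`). Independent states are
#' kept for the tracks above (`f_test > f_ref`) and below the standard.
#'
#' The starting rate of change is `step_min` (so the doubling rule is active
#' from the start); the run counter resets after a doubling event and on any
#' reversal. `delta` is floored at `step_min` so the test never equals the
#' standard.
#'
#' @param delta_max Maximal (and starting) frequency difference, Hz.
#' @param step_min,step_max Bounds on the rate of change, Hz.
#' @param side `"above"` or `"below"` (bookkeeping only).
#' @param delta,step Optional starting values (default `delta_max`, `step_min`).
#' @return A list of class `freq_staircase`.
#' @examples
#' s <- freq_staircase(delta_max = 256, step_min = 32, step_max = 64)
#' s <- freq_staircase_update(s, correct = TRUE)
#' s$delta
#' @export
freq_staircase <- function(delta_max, step_min, step_max, side = "above",
                           delta = delta_max, step = step_min) {
  check_positive(delta_max, "delta_max", scalar = TRUE)
  check_positive(step_min, "step_min", scalar = TRUE)
  check_positive(step_max, "step_max", scalar = TRUE)
  if (step_min > step_max) abort("`step_min` must be <= `step_max`.", class = "vibropitch_domain_error")
  if (delta <= 0 || delta > delta_max) abort("`delta` must lie in (0, delta_max].", class = "vibropitch_domain_error")
  structure(
    list(side = side, delta = delta, step = min(max(step, step_min), step_max),
         delta_max = delta_max, step_min = step_min, step_max = step_max,
         run_length = 0L, last_direction = "none"),
    class = "freq_staircase"
  )
}

#' @rdname freq_staircase
#' @param state A `freq_staircase` state.
#' @param correct Logical: was the response correct?
#' @export
freq_staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "freq_staircase"))
  dir <- if (correct) "down" else "up"
  state$delta <- if (correct) {
    max(state$step_min, state$delta - state$step)
  } else {
    min(state$delta_max, state$delta + state$step)
  }
  if (state$last_direction == "none" || dir == state$last_direction) {
    state$run_length <- state$run_length + 1L
  } else {
    state$step <- max(state$step_min, state$step / 2)
    state$run_length <- 1L
  }
  if (state$run_length >= 3L) {
    state$step <- min(state$step_max, state$step * 2)
    state$run_length <- 0L
  }
  state$last_direction <- dir
  state
}

#' 3-down/1-up detection staircase
#'
#' Transformed up-down procedure for the human 2AFC detection task. The
#' amplitude is decreased by `step_db` dB after three successive correct
#' answers and increased by `step_db` dB after any incorrect answer. `step_db`
#' starts at 12 dB, is halved after each direction reversal, and never falls
#' below 3 dB. Testing stops after `reversal_limit` reversals; the threshold is
#' the mean amplitude of the last 10 trials. This rule converges near the
#' 79.4%-correct point (`0.5^(1/3)`).
#'
#' @param amplitude Starting amplitude, micrometres.
#' @param max_amplitude Actuator ceiling at this frequency, micrometres.
#' @param step_db Starting step, dB (amplitude dB, `20 log10`).
#' @param step_db_min Step floor, dB.
#' @param reversal_limit Number of reversals at which testing stops.
#' @return A list of class `updown_staircase`; `$finished` becomes `TRUE` once
#'   the reversal limit is reached.
#' @export
updown_staircase <- function(amplitude, max_amplitude = Inf, step_db = 12,
                             step_db_min = 3, reversal_limit = 5L) {
  check_positive(amplitude, "amplitude", scalar = TRUE)
  if (amplitude > max_amplitude) abort("`amplitude` exceeds `max_amplitude`.", class = "vibropitch_domain_error")
  structure(
    list(amplitude = amplitude, max_amplitude = max_amplitude,
         step_db = step_db, step_db_min = step_db_min,
         consecutive_correct = 0L, reversals = 0L,
         reversal_limit = as.integer(reversal_limit),
         amplitude_history = numeric(0), last_direction = "none",
         finished = FALSE),
    class = "updown_staircase"
  )
}

#' @rdname updown_staircase
#' @param state An `updown_staircase` state.
#' @param correct Logical: was the response correct?
#' @export
updown_update <- function(state, correct) {
  stopifnot(inherits(state, "updown_staircase"))
  if (state$finished) {
    abort("Staircase already finished (reversal limit reached).",
          class = "vibropitch_state_error")
  }
  state$amplitude_history <- c(state$amplitude_history, state$amplitude)
  dir <- NULL
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 3L) {
      state$amplitude <- state$amplitude * 10^(-state$step_db / 20)
      state$consecutive_correct <- 0L
      dir <- "down"
    }
  } else {
    state$amplitude <- min(state$max_amplitude, state$amplitude * 10^(state$step_db / 20))
    state$consecutive_correct <- 0L
    dir <- "up"
  }
  if (!is.null(dir)) {
    if (state$last_direction != "none" && dir != state$last_direction) {
      state$reversals <- state$reversals + 1L
      state$step_db <- max(state$step_db_min, state$step_db / 2)
      if (state$reversals >= state$reversal_limit) state$finished <- TRUE
    }
    state$last_direction <- dir
  }
  state
}

#' @rdname updown_staircase
#' @export
updown_threshold <- function(state) {
  stopifnot(inherits(state, "updown_staircase"))
  if (state$reversals < state$reversal_limit) {
    abort("Staircase has not reached its reversal limit.", class = "vibropitch_state_error")
  }
  if (length(state$amplitude_history) < 10L) {
    abort("Fewer than 10 trials in the staircase history.", class = "vibropitch_state_error")
  }
  mean(tail(state$amplitude_history, 10L))
}

#' Exact one-sided binomial test against chance
#'
#' Upper-tail probability of observing at least `n_correct` correct responses
#' in `n_trials` fair coin flips: `sum_{i >= n_correct} C(n, i) 0.5^n`.
#'
#' @param n_correct Number of correct responses (0..`n_trials`).
#' @param n_trials Number of trials.
#' @return The exact one-sided p-value.
#' @examples
#' binomial_onesided_p(10, 12)  # 79/4096
#' @export
binomial_onesided_p <- function(n_correct, n_trials) {
  if (any(n_correct < 0) || any(n_correct > n_trials)) {
    abort("`n_correct` must lie in [0, n_trials].", class = "vibropitch_domain_error")
  }
  pbinom(n_correct - 1, n_trials, 0.5, lower.tail = FALSE)
}

#' Bout-based mouse detection procedure
#'
#' The mouse 2AFC detection task proceeds in bouts at a fixed amplitude. A bout
#' completes once it holds at least 6 stimulus-present trials and at least 12
#' trials in total. On completion, the fraction of correct responses over all
#' the bout's trials determines the next amplitude: above 70% the amplitude is
#' attenuated by 4 dB; below 60% it is increased by 4 dB (capped at the session
#' maximum); otherwise it is left unchanged. Completed bouts are archived under
#' their amplitude and a fresh bout begins.
#'
#' @param amplitude Starting amplitude, micrometres.
#' @param max_amplitude Largest amplitude the actuator can produce, micrometres.
#' @param step_db Attenuation step, dB (default 4).
#' @param min_present,min_total Bout completion requirements (defaults 6 and 12).
#' @return A list of class `bout_state`; `$bouts` is a tibble of completed
#'   bouts with columns `amplitude_um`, `n_correct`, `n_present`, `n_total`.
#' @export
bout_state <- function(amplitude, max_amplitude = amplitude, step_db = 4,
                       min_present = 6L, min_total = 12L) {
  check_positive(amplitude, "amplitude", scalar = TRUE)
  structure(
    list(amplitude = min(amplitude, max_amplitude), max_amplitude = max_amplitude,
         step_db = step_db, min_present = as.integer(min_present),
         min_total = as.integer(min_total),
         cur_present = 0L, cur_total = 0L, cur_correct = 0L,
         bouts = tibble(amplitude_um = numeric(0), n_correct = integer(0),
                        n_present = integer(0), n_total = integer(0))),
    class = "bout_state"
  )
}

#' @rdname bout_state
#' @param state A `bout_state`.
#' @param stimulus_present Logical: did this trial contain a vibration?
#' @param correct Logical: was the response correct?
#' @export
bout_update <- function(state, stimulus_present, correct) {
  stopifnot(inherits(state, "bout_state"))
  state$cur_total <- state$cur_total + 1L
  state$cur_present <- state$cur_present + as.integer(stimulus_present)
  state$cur_correct <- state$cur_correct + as.integer(correct)
  if (state$cur_present >= state$min_present && state$cur_total >= state$min_total) {
    state$bouts <- dplyr::bind_rows(state$bouts, tibble(
      amplitude_um = state$amplitude, n_correct = state$cur_correct,
      n_present = state$cur_present, n_total = state$cur_total
    ))
    frac <- state$cur_correct / state$cur_total
    if (frac > 0.7) {
      state$amplitude <- state$amplitude * 10^(-state$step_db / 20)
    } else if (frac < 0.6) {
      state$amplitude <- min(state$max_amplitude, state$amplitude * 10^(state$step_db / 20))
    }
    state$cur_present <- state$cur_total <- state$cur_correct <- 0L
  }
  state
}

#' @rdname bout_state
#' @param alpha Significance level for the one-sided binomial test (default 0.05).
#' @return `mouse_session_threshold()` returns the lowest amplitude of the
#'   session for which at least one completed bout beats chance at level
#'   `alpha`, or `NA` (with a warning) when no bout does.
#' @export
mouse_session_threshold <- function(state, alpha = 0.05) {
  stopifnot(inherits(state, "bout_state"))
  b <- state$bouts
  if (nrow(b) == 0L) {
    abort("No completed bouts in this session.", class = "vibropitch_state_error")
  }
  p <- binomial_onesided_p(b$n_correct, b$n_total)
  sig <- b$amplitude_um[p < alpha]
  if (length(sig) == 0L) {
    warn("No bout was significantly above chance; threshold undefined for this session.")
    return(NA_real_)
  }
  min(sig)
}
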