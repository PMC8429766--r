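#' Stimulus plans for the five behavioural experiments
#'
#' Returns the frequency sets, amplitude sets and staircase parameter tables
#' that define each experiment: the three mouse go/no-go frequency ranges, the
#' human 2AFC frequency-comparison plan (per reference frequency), the human
#' 2AFC amplitude-comparison plan (per reference amplitude), and the mouse and
#' human detection plans. These numbers are the package's canonical defaults;
#' a copy is stored at `inst/extdata/stimulus_plans.json` and the test suite
#' asserts the two stay identical.
#'
#' @return A nested list with components `mouse_freq`, `human_freq`,
#'   `human_amp`, `mouse_detection`, `human_detection`.
#' @export
stimulus_plans <- function() {
  list(
    mouse_freq = list(
      low = list(
        center_hz = 450,
        no_go_hz = c(310, 345, 380, 415),
        go_hz = c(485, 520, 555, 590),
        a_ref_um = 5.6,
        probe_amps_um = c(8.6, 7.1, 4.1, 2.6, 1.1),
        n_mice = 4,
        min_repeats = 10,
        probe_fraction = 0.3
      ),
      middle = list(
        center_hz = 1000,
        no_go_hz = c(900, 925, 950, 975),
        go_hz = c(1025, 1050, 1075, 1100),
        a_ref_um = 3.8,
        probe_amps_um = c(6.9, 5.4, 4.8, 2.7, 2.1, 1.8),
        n_mice = 4,
        min_repeats = 10,
        probe_fraction = 0.3
      ),
      high = list(
        center_hz = 1600,
        no_go_hz = c(1500, 1525, 1550, 1575),
        go_hz = c(1625, 1650, 1675, 1700),
        a_ref_um = 3.8,
        probe_amps_um = c(6.9, 5.4, 4.8, 2.7, 2.1, 1.8),
        n_mice = 6,
        min_repeats = 10,
        probe_fraction = 0.3
      )
    ),
    human_freq = list(
      f_ref_hz = c(160, 200, 280, 440, 480),
      delta_max_hz = c(64, 128, 128, 256, 256),
      step_min_hz = c(8, 8, 16, 32, 32),
      step_max_hz = c(16, 32, 32, 64, 64),
      a_test_um = 11.8,
      a_ref_um = c(7.4, 8.4, 9.8, 11.8, 14.2, 16.5, 18.9),
      min_trials_per_a_ref = 70,
      n_subjects = 9
    ),
    human_amp = list(
      a_ref_um = c(6, 8, 10, 12),
      delta_max_up_um = c(12, 10, 8, 6),
      delta_max_down_um = c(5, 7, 9, 11),
      step_min_um = 1,
      step_max_um = 3,
      f_test_hz = 200,
      f_ref_hz = c(75, 100, 150, 200, 266, 400, 534),
      n_subjects = 10
    ),
    mouse_detection = list(
      frequencies_hz = c(200, 450, 700, 1000, 1300, 1600, 2000),
      n_mice = 7,
      n_sessions = 5,
      step_db = 4,
      bout_min_present = 6,
      bout_min_total = 12,
      alpha = 0.05
    ),
    human_detection = list(
      frequencies_hz = c(10, 25, 50, 75, 100, 200, 300, 400, 500,
                         600, 700, 800, 900, 1000),
      n_subjects = 19,
      start_step_db = 12,
      step_db_min = 3,
      reversal_limit = 5
    )
  )
}

# actuator ceilings (um): documented modelling assumptions, anchored to the
# reported extremes (mouse: 10 um at 200 Hz down to 1 um at 2000 Hz)
mouse_max_amplitude <- function(frequency) pmin(10, 2000 / frequency)
human_max_amplitude <- function(frequency) pmin(40, 4000 / frequency)

#' Default generative observers for each experiment
#'
#' Returns the [observer_params()] used by the synthetic-data generator for a
#' given experiment and spectral location. Pitch exponents are set to the
#' fitted behavioural values at each location (mouse: 0.32 at 450 Hz, 0 at
#' 1000 Hz where the fit is non-significant, -0.044 at 1600 Hz; human: -0.24
#' at 440 Hz; other human locations get sign-consistent synthetic values since
#' only the sign is established). Noise magnitudes are fixed package-level
#' modelling choices (see the methods vignette).
#'
#' @param experiment One of `"mouse_freq_gonogo"`, `"human_freq_2afc"`,
#'   `"human_amp_2afc"`, `"mouse_detection"`, `"human_detection"`,
#'   `"equal_intensity_control"`.
#' @param location Spectral location: the mouse range name (`"low"`,
#'   `"middle"`, `"high"`) or the human reference frequency in Hz. Ignored for
#'   detection experiments.
#' @return An [observer_params()] object.
#' @export
default_observer <- function(experiment, location = NULL) {
  mouse_v <- sensitivity_curve_params(1000, 0.1, 1.6)
  human_v <- sensitivity_curve_params(240, 0.2, 0.4)
  switch(experiment,
    mouse_freq_gonogo = {
      loc <- location %||% "low"
      switch(as.character(loc),
        low = observer_params(k_true = 0.32, sigma_pitch = 110,
                              lapse = 0.02, guess = 0.02, sigma_detect_db = 3,
                              vcurve = mouse_v),
        middle = observer_params(k_true = 0, sigma_pitch = 60,
                                 lapse = 0.05, guess = 0.10, sigma_detect_db = 3,
                                 vcurve = mouse_v),
        high = observer_params(k_true = -0.044, sigma_pitch = 60,
                               lapse = 0.02, guess = 0.02, sigma_detect_db = 3,
                               vcurve = mouse_v),
        abort("Unknown mouse range; use 'low', 'middle' or 'high'.",
              class = "vibropitch_config_error")
      )
    },
    human_freq_2afc = ,
    equal_intensity_control = {
      f_ref <- as.numeric(location %||% 440)
      k_by_f <- c(`160` = 0.35, `200` = 0.20, `280` = -0.10,
                  `440` = -0.24, `480` = -0.30)
      key <- as.character(f_ref)
      if (!key %in% names(k_by_f)) {
        abort("Unknown human reference frequency.", class = "vibropitch_config_error")
      }
      k <- unname(k_by_f[key])
      # pitch noise scaled so the 2AFC psychometric SD along frequency is
      # ~9% of the reference frequency at the test amplitude
      a_test <- stimulus_plans()$human_freq$a_test_um
      sigma <- 0.065 * exp(k * log(a_test)) * f_ref
      observer_params(k_true = k, sigma_pitch = sigma, lapse = 0.03,
                      guess = 0, sigma_detect_db = 4, vcurve = human_v)
    },
    human_amp_2afc = observer_params(k_true = -0.24, sigma_pitch = 16,
                                     lapse = 0.03, guess = 0,
                                     sigma_intensity = 0.12,
                                     sigma_detect_db = 4, vcurve = human_v),
    mouse_detection = observer_params(k_true = 0, sigma_pitch = 60,
                                      lapse = 0.02, guess = 0.02,
                                      sigma_detect_db = 3, vcurve = mouse_v),
    human_detection = observer_params(k_true = -0.24, sigma_pitch = 16,
                                      lapse = 0.03, guess = 0,
                                      sigma_detect_db = 4, vcurve = human_v),
    abort(sprintf("Unknown experiment '%s'.", experiment),
          class = "vibropitch_config_error")
  )
}
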