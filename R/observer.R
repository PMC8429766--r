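#' Parameters of a V-shaped sensitivity curve
#'
#' Detection thresholds as a function of vibration frequency form a V-shaped
#' curve on log-log axes, minimal at the frequency of highest vibrotactile
#' sensitivity (about 1000 Hz for the mouse forelimb, about 240 Hz for the
#' human fingertip). The generative model is log-quadratic:
#' `T(f) = threshold_at_best * exp(curvature * (ln f - ln best_frequency)^2)`.
#'
#' @param best_frequency Frequency of the V minimum, Hz (> 0).
#' @param threshold_at_best Detection threshold at the minimum, micrometres (> 0).
#' @param curvature Quadratic coefficient in log-log space (> 0).
#' @return A list of class `sensitivity_curve_params`.
#' @examples
#' sensitivity_curve_params(1000, 0.1, 1.6)
#' @export
sensitivity_curve_params <- function(best_frequency, threshold_at_best, curvature) {
  check_positive(best_frequency, "best_frequency", scalar = TRUE)
  check_positive(threshold_at_best, "threshold_at_best", scalar = TRUE)
  check_positive(curvature, "curvature", scalar = TRUE)
  structure(
    list(
      best_frequency = best_frequency,
      threshold_at_best = threshold_at_best,
      curvature = curvature
    ),
    class = "sensitivity_curve_params"
  )
}

#' Detection threshold of the generative sensitivity curve
#'
#' @param frequency Frequency in Hz (> 0). Vectorised.
#' @param vcurve A [sensitivity_curve_params()] object.
#' @return Threshold amplitude in micrometres; minimal exactly at
#'   `vcurve$best_frequency` and symmetric in log frequency about it.
#' @examples
#' v <- sensitivity_curve_params(1000, 0.1, 1.6)
#' detection_threshold(c(200, 1000, 2000), v)
#' @export
detection_threshold <- function(frequency, vcurve) {
  check_positive(frequency, "frequency")
  stopifnot(inherits(vcurve, "sensitivity_curve_params"))
  vcurve$threshold_at_best *
    exp(vcurve$curvature * (log(frequency) - log(vcurve$best_frequency))^2)
}

#' Generative observer parameters
#'
#' The synthetic subjects all perceive vibrotactile pitch as `A^k_true * f`
#' corrupted by additive Gaussian noise on the linear pitch axis, perceived
#' intensity as amplitude relative to the detection threshold (`A / T(f)`) with
#' Gaussian noise on its logarithm, and detectability as a cumulative Gaussian
#' in dB re threshold. Lapses are stimulus-independent random responses; the
#' guess rate is the lower asymptote of the go/no-go response function.
#'
#' These observers are an explicit modelling assumption: published behavioural
#' work fits the psychometric description of responses but does not specify the
#' subjects' internal decision model.
#'
#' @param k_true Generative pitch exponent (dimensionless).
#' @param sigma_pitch SD of perceptual noise on the pitch axis (um^k * Hz, > 0).
#' @param lapse Probability of a stimulus-independent random response, in [0, 0.5).
#' @param guess Lower-asymptote guess rate (go/no-go only), in [0, 0.5).
#' @param sigma_intensity SD of noise on log perceived intensity (> 0).
#' @param sigma_detect_db SD of detection noise in amplitude dB (> 0).
#' @param vcurve A [sensitivity_curve_params()] object.
#' @return A list of class `observer_params`.
#' @examples
#' observer_params(k_true = 0.32, sigma_pitch = 110,
#'                 vcurve = sensitivity_curve_params(1000, 0.1, 1.6))
#' @export
observer_params <- function(k_true = 0,
                            sigma_pitch = 1,
                            lapse = 0.02,
                            guess = 0.02,
                            sigma_intensity = 0.12,
                            sigma_detect_db = 4,
                            vcurve = sensitivity_curve_params(1000, 0.1, 1.6)) {
  check_positive(sigma_pitch, "sigma_pitch", scalar = TRUE)
  check_positive(sigma_intensity, "sigma_intensity", scalar = TRUE)
  check_positive(sigma_detect_db, "sigma_detect_db", scalar = TRUE)
  if (lapse < 0 || lapse >= 0.5) abort("`lapse` must be in [0, 0.5).", class = "vibropitch_domain_error")
  if (guess < 0 || guess >= 0.5) abort("`guess` must be in [0, 0.5).", class = "vibropitch_domain_error")
  if (lapse + guess >= 1) abort("`lapse` + `guess` must be < 1.", class = "vibropitch_domain_error")
  stopifnot(inherits(vcurve, "sensitivity_curve_params"))
  structure(
    list(
      k_true = k_true, sigma_pitch = sigma_pitch, lapse = lapse, guess = guess,
      sigma_intensity = sigma_intensity, sigma_detect_db = sigma_detect_db,
      vcurve = vcurve
    ),
    class = "observer_params"
  )
}

#' Probability of a go response in the go/no-go task
#'
#' The observer licks when its noisy internal pitch estimate exceeds the
#' learned category boundary:
#' `p = guess + (1 - guess - lapse) * Phi((A^k_true * f - boundary) / sigma_pitch)`.
#' Stimuli on one equal-pitch curve (with `k = k_true`) therefore yield exactly
#' equal go probabilities.
#'
#' @param frequency,amplitude Stimulus (Hz, micrometres). Vectorised.
#' @param boundary_pitch Category boundary on the pitch axis (> 0).
#' @param obs An [observer_params()] object.
#' @return Go probability in `[guess, 1 - lapse]`.
#' @export
p_go <- function(frequency, amplitude, boundary_pitch, obs) {
  check_positive(boundary_pitch, "boundary_pitch", scalar = TRUE)
  stopifnot(inherits(obs, "observer_params"))
  pv <- pitch_value(frequency, amplitude, obs$k_true)
  obs$guess + (1 - obs$guess - obs$lapse) * pnorm((pv - boundary_pitch) / obs$sigma_pitch)
}

#' Probability that the first of two stimuli is judged higher
#'
#' Two-interval comparison under signal detection assumptions: the decision
#' variable is the difference of two independent noisy percepts, so comparison
#' noise is `sqrt(2)` times the single-interval noise. In `"frequency_pitch"`
#' mode the percept is the pitch value `A^k_true * f`; in
#' `"amplitude_intensity"` mode it is log perceived intensity `ln(A / T(f))`.
#'
#' @param f_first,a_first First stimulus (Hz, micrometres).
#' @param f_second,a_second Second stimulus.
#' @param obs An [observer_params()] object.
#' @param attribute `"frequency_pitch"` or `"amplitude_intensity"`.
#' @return Probability of reporting the first stimulus higher, in
#'   `[lapse/2, 1 - lapse/2]`.
#' @export
p_first_higher <- function(f_first, a_first, f_second, a_second, obs,
                           attribute = c("frequency_pitch", "amplitude_intensity")) {
  attribute <- match.arg(attribute)
  stopifnot(inherits(obs, "observer_params"))
  if (attribute == "frequency_pitch") {
    d <- pitch_value(f_first, a_first, obs$k_true) -
      pitch_value(f_second, a_second, obs$k_true)
    s <- sqrt(2) * obs$sigma_pitch
  } else {
    d <- log(a_first / detection_threshold(f_first, obs$vcurve)) -
      log(a_second / detection_threshold(f_second, obs$vcurve))
    s <- sqrt(2) * obs$sigma_intensity
  }
  obs$lapse / 2 + (1 - obs$lapse) * pnorm(d / s)
}

#' Probability of a correct response in the 2AFC detection task
#'
#' `p = 0.5 + (0.5 - lapse/2) * Phi(20 * log10(A / T(f)) / sigma_detect_db)`:
#' chance far below threshold, `1 - lapse/2` far above, and 0.75 exactly at
#' threshold for a lapse-free observer. dB are amplitude dB (20 log10 ratio).
#'
#' @param frequency Frequency in Hz (> 0).
#' @param amplitude Amplitude in micrometres (>= 0; 0 gives chance performance).
#' @param obs An [observer_params()] object.
#' @return Probability correct in `[0.5, 1 - lapse/2]`.
#' @export
p_detect_correct <- function(frequency, amplitude, obs) {
  check_positive(frequency, "frequency")
  stopifnot(inherits(obs, "observer_params"))
  if (any(amplitude < 0)) abort("`amplitude` must be non-negative.", class = "vibropitch_domain_error")
  db <- 20 * log10(amplitude / detection_threshold(frequency, obs$vcurve))
  0.5 + (0.5 - obs$lapse / 2) * pnorm(db / obs$sigma_detect_db)
}
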