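#' Construct a table of sinusoidal vibration stimuli
#'
#' A vibrotactile stimulus is a pure sinusoid characterised by its frequency
#' (Hz) and peak displacement amplitude (micrometres). These two physical
#' attributes are the only stimulus properties the perceptual model consumes.
#'
#' @param frequency Vibration frequency in Hz (> 0). Vectorised.
#' @param amplitude Peak displacement amplitude in micrometres (> 0). Vectorised.
#' @param duration Stimulus duration in seconds (default 0.5).
#' @return A tibble with columns `frequency_hz`, `amplitude_um`, `duration_s`.
#' @examples
#' vibration_stimulus(450, 5.6)
#' @export
vibration_stimulus <- function(frequency, amplitude, duration = 0.5) {
  check_positive(frequency, "frequency")
  check_positive(amplitude, "amplitude")
  if (any(duration <= 0)) abort("`duration` must be positive.", class = "vibropitch_domain_error")
  tibble(frequency_hz = frequency, amplitude_um = amplitude, duration_s = duration)
}

#' Pitch value of a vibration under the power-law model
#'
#' Perceived vibrotactile pitch is modelled as the product of vibration
#' frequency and a power function of amplitude, `A^k * f`. All stimuli sharing
#' one pitch value are perceptual metamers. Evaluation is done in log space
#' (`exp(k * log(A) + log(f))`) so extreme exponents cannot overflow.
#'
#' @param frequency Frequency in Hz (> 0). Vectorised.
#' @param amplitude Amplitude in micrometres (> 0). Vectorised.
#' @param k Dimensionless pitch exponent.
#' @return Pitch values (units um^k * Hz), strictly positive.
#' @examples
#' pitch_value(450, 1, k = 0.32)    # amplitude 1 um: pitch equals frequency
#' pitch_value(450, 5.6, k = 0.32)
#' @export
pitch_value <- function(frequency, amplitude, k) {
  check_positive(frequency, "frequency")
  check_positive(amplitude, "amplitude")
  exp(k * log(amplitude) + log(frequency))
}

#' Frequency that preserves pitch after an amplitude change
#'
#' If the amplitude of a reference vibration is changed by a factor
#' `N = new_amplitude / ref_amplitude`, its frequency must be scaled by
#' `(1/N)^k` to keep the same pitch percept. This returns the frequency of the
#' pitch-matched stimulus at `new_amplitude`.
#'
#' @param new_amplitude Amplitude of the new stimulus in micrometres (> 0).
#' @param ref_frequency,ref_amplitude The reference stimulus.
#' @param k Pitch exponent.
#' @return Frequency in Hz such that the new stimulus has the same pitch value
#'   as the reference.
#' @examples
#' equal_pitch_frequency(11.2, ref_frequency = 450, ref_amplitude = 5.6, k = 0.32)
#' @export
equal_pitch_frequency <- function(new_amplitude, ref_frequency, ref_amplitude, k) {
  check_positive(new_amplitude, "new_amplitude")
  check_positive(ref_frequency, "ref_frequency")
  check_positive(ref_amplitude, "ref_amplitude")
  exp(log(ref_frequency) + k * (log(ref_amplitude) - log(new_amplitude)))
}

#' Build an equal-pitch curve
#'
#' Tabulates the set of (amplitude, frequency) pairs that evoke the same pitch
#' percept as a reference stimulus, under the `A^k * f` model, at the requested
#' amplitudes.
#'
#' @param ref_frequency,ref_amplitude Reference stimulus (Hz, micrometres).
#' @param k Pitch exponent.
#' @param amplitudes Amplitude grid in micrometres (> 0, non-empty).
#' @return A tibble of class `equal_pitch_curve` with columns `amplitude_um`,
#'   `frequency_hz` and attributes `ref_frequency_hz`, `ref_amplitude_um`, `k`.
#' @examples
#' equal_pitch_curve(450, 5.6, k = 0.32, amplitudes = c(1.1, 2.6, 4.1, 5.6, 7.1, 8.6))
#' @export
equal_pitch_curve <- function(ref_frequency, ref_amplitude, k, amplitudes) {
  if (length(amplitudes) == 0L) {
    abort("`amplitudes` must contain at least one value.", class = "vibropitch_domain_error")
  }
  check_positive(amplitudes, "amplitudes")
  out <- tibble(
    amplitude_um = amplitudes,
    frequency_hz = equal_pitch_frequency(amplitudes, ref_frequency, ref_amplitude, k)
  )
  structure(out,
    ref_frequency_hz = ref_frequency,
    ref_amplitude_um = ref_amplitude,
    k = k,
    class = c("equal_pitch_curve", class(out))
  )
}

#' Write / read an equal-pitch curve as CSV
#'
#' The file holds one comment line with a JSON header (reference stimulus and
#' exponent) followed by a plain CSV table with columns `amplitude_um`,
#' `frequency_hz`.
#'
#' @param curve An [equal_pitch_curve()].
#' @param path File path.
#' @return `write_equal_pitch_curve()` returns `path` invisibly;
#'   `read_equal_pitch_curve()` returns the curve.
#' @export
write_equal_pitch_curve <- function(curve, path) {
  stopifnot(inherits(curve, "equal_pitch_curve"))
  header <- jsonlite::toJSON(
    list(
      ref_frequency_hz = attr(curve, "ref_frequency_hz"),
      ref_amplitude_um = attr(curve, "ref_amplitude_um"),
      k = attr(curve, "k")
    ),
    auto_unbox = TRUE, digits = NA
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  writeLines("amplitude_um,frequency_hz", con)
  writeLines(sprintf("%.12g,%.12g", curve$amplitude_um, curve$frequency_hz), con)
  invisible(path)
}

#' @rdname write_equal_pitch_curve
#' @export
read_equal_pitch_curve <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# ")) {
    abort("Missing JSON header line in equal-pitch curve file.", class = "vibropitch_io_error")
  }
  hdr <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  tab <- readr::read_csv(I(lines[-1]), show_col_types = FALSE)
  equal_pitch_curve(hdr$ref_frequency_hz, hdr$ref_amplitude_um, hdr$k, tab$amplitude_um)
}

#' @export
print.equal_pitch_curve <- function(x, ...) {
  cat(sprintf(
    "Equal-pitch curve: A^k x f = const, k = %.4g (ref %.4g um @ %.4g Hz), %d points\n",
    attr(x, "k"), attr(x, "ref_amplitude_um"), attr(x, "ref_frequency_hz"), nrow(x)
  ))
  NextMethod()
}
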