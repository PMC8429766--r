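# shared fixtures: small-scale configs and noiseless generators used across files

# a fast mouse go/no-go config (short sessions, few mice)
tiny_mouse_config <- function(location = "low", ...) {
  experiment_config("mouse_freq_gonogo", location = location,
                    n_subjects = 2, min_repeats = 4, max_trials = 400, ...)
}

# binned responses drawn from a known psychometric function
make_binned <- function(levels, mu, sigma, lapse = 0, guess = lapse,
                        n_per_level = 1000L, seed = 1L) {
  p <- guess + (1 - guess - lapse) * pnorm((levels - mu) / sigma)
  withr::with_seed(seed, tibble::tibble(
    level = levels,
    n_total = n_per_level,
    n_chosen = rbinom(length(levels), n_per_level, p)
  ))
}

# noiseless shift-ratio data exactly on the power law
noiseless_shift <- function(k, acf = c(0.196, 0.464, 0.732, 1.268, 1.536)) {
  tibble::tibble(acf = acf, shift_ratio = acf^(-k))
}

mouse_levels <- c(310, 345, 380, 415, 485, 520, 555, 590)
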