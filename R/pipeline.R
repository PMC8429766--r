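#' Run a full synthetic experiment end to end
#'
#' Simulates every subject and session of the configured experiment, performs
#' the corresponding analysis chain, and returns all intermediate artifacts.
#' For the discrimination experiments the chain is: sessions -> per-condition
#' psychometric fits -> PSE shift ratios -> pitch-exponent fit with the
#' significance gate -> equal-pitch curve. For the detection experiments:
#' sessions -> per-frequency thresholds -> aggregated V-shaped sensitivity
#' curve. For the amplitude task: sessions -> PSE shifts -> equal-intensity
#' points -> sum-of-exponentials fit. The run is reproducible: the same
#' configuration and master seed give identical results.
#'
#' @param config An [experiment_config()].
#' @param seed Master integer seed; every subject/session draws from an
#'   independent stream derived from it.
#' @param keep_sessions Keep the combined trial table in the bundle (default
#'   `TRUE`; set `FALSE` to save memory in large recovery studies).
#' @return A list of class `experiment_results`. Components depend on the
#'   experiment and include `sessions`, `psychometric`, `shift_data`,
#'   `pitch_fit`, `equal_pitch`, `intensity_fit`, `thresholds`, `sensitivity`
#'   and `provenance`.
#' @examples
#' cfg <- experiment_config("mouse_freq_gonogo", location = "low",
#'                          n_subjects = 2, min_repeats = 4, max_trials = 400)
#' res <- run_experiment(cfg, seed = 42)
#' res$pitch_fit
#' @export
run_experiment <- function(config, seed, keep_sessions = TRUE) {
  validate_config(config)
  out <- switch(config$experiment,
    mouse_freq_gonogo = run_mouse_freq(config, seed, keep_sessions),
    human_freq_2afc = run_human_freq(config, seed, keep_sessions),
    human_amp_2afc = run_human_amp(config, seed, keep_sessions),
    mouse_detection = run_mouse_detection(config, seed),
    human_detection = run_human_detection(config, seed),
    equal_intensity_control = run_equal_intensity(config, seed, keep_sessions)
  )
  out$config <- config
  out$provenance <- list(
    package = "vibropitch",
    version = tryCatch(as.character(utils::packageVersion("vibropitch")),
                       error = function(e) NA_character_),
    config_hash = rlang::hash(config),
    master_seed = as.integer(seed)
  )
  structure(out, class = "experiment_results")
}

#' @export
print.experiment_results <- function(x, ...) {
  cat(sprintf("Synthetic experiment: %s (seed %d)\n",
              x$config$experiment, x$provenance$master_seed))
  for (nm in intersect(c("pitch_fit", "intensity_fit", "sensitivity"), names(x))) {
    print(x[[nm]])
  }
  invisible(x)
}

# fit one psychometric curve, returning NULL on degenerate data or when the
# PSE is unidentifiable (pinned to the boundary of its admissible range)
safe_psycho_mu <- function(binned, equal_asymptotes) {
  fit <- tryCatch(
    fit_psychometric(binned, equal_asymptotes = equal_asymptotes),
    error = function(e) NULL
  )
  if (!is.null(fit) && fit$mu_at_bound) return(NULL)
  fit
}

fit_row <- function(fit, ...) {
  if (is.null(fit)) {
    tibble(..., mu = NA_real_, sigma = NA_real_, lapse = NA_real_,
           guess = NA_real_, n_trials = NA_integer_)
  } else {
    tibble(..., mu = fit$mu, sigma = fit$sigma, lapse = fit$lapse,
           guess = fit$guess, n_trials = sum(fit$data$n_total))
  }
}

run_mouse_freq <- function(config, seed, keep_sessions) {
  plan <- config$plan
  probes <- plan$probe_amps_um
  n_m <- config$n_subjects; n_p <- length(probes)
  seeds <- matrix(make_stream_seeds(seed, n_m * n_p), nrow = n_m)

  sessions <- purrr::map_dfr(seq_len(n_m), function(m) {
    purrr::map_dfr(seq_len(n_p), function(p) {
      simulate_session(config, seeds[m, p], subject = m, session = p)
    })
  })

  psychometric <- purrr::map_dfr(seq_len(n_m), function(m) {
    sm <- sessions[sessions$subject == m, ]
    ref <- bin_responses(sm[sm$amplitude_um == plan$a_ref_um, ],
                         .data$frequency_hz, .data$response == "lick")
    ref_fit <- safe_psycho_mu(ref, config$equal_asymptotes)
    rows <- fit_row(ref_fit, subject = m, amplitude_um = plan$a_ref_um,
                    acf = 1, is_reference = TRUE)
    probe_rows <- purrr::map_dfr(probes, function(a) {
      d <- bin_responses(sm[sm$amplitude_um == a, ],
                         .data$frequency_hz, .data$response == "lick")
      fit_row(safe_psycho_mu(d, config$equal_asymptotes),
              subject = m, amplitude_um = a, acf = a / plan$a_ref_um,
              is_reference = FALSE)
    })
    dplyr::bind_rows(rows, probe_rows)
  })

  mu_ref <- psychometric |>
    dplyr::filter(.data$is_reference) |>
    dplyr::select("subject", mu_ref = "mu")
  shift_data <- psychometric |>
    dplyr::filter(!.data$is_reference) |>
    dplyr::left_join(mu_ref, by = "subject") |>
    dplyr::mutate(shift_ratio = .data$mu / .data$mu_ref,
                  spectral_location = plan$center_hz) |>
    dplyr::filter(is.finite(.data$shift_ratio), .data$shift_ratio > 0) |>
    dplyr::select("subject", "spectral_location", "acf", "shift_ratio")

  pitch_fit <- fit_pitch_exponent(shift_data)
  list(
    sessions = if (keep_sessions) sessions else NULL,
    psychometric = psychometric,
    shift_data = shift_data,
    pitch_fit = pitch_fit,
    equal_pitch = equal_pitch_points(pitch_fit, plan$center_hz, plan$a_ref_um)
  )
}

run_human_freq <- function(config, seed, keep_sessions) {
  plan <- config$plan
  n_s <- config$n_subjects
  seeds <- make_stream_seeds(seed, n_s)

  sessions <- purrr::map_dfr(seq_len(n_s), function(m) {
    simulate_session(config, seeds[m], subject = m)
  })

  psychometric <- purrr::map_dfr(seq_len(n_s), function(m) {
    sm <- sessions[sessions$subject == m, ]
    purrr::map_dfr(plan$a_ref_um, function(a_ref) {
      d <- bin_responses(sm[sm$amplitude_b_um == a_ref, ],
                         .data$frequency_hz, .data$response == "test_higher")
      fit_row(safe_psycho_mu(d, config$equal_asymptotes),
              subject = m, a_ref_um = a_ref, acf = plan$a_test_um / a_ref,
              is_reference = a_ref == plan$a_test_um)
    })
  })

  mu_ref <- psychometric |>
    dplyr::filter(.data$is_reference) |>
    dplyr::select("subject", mu_ref = "mu")
  subject_shifts <- psychometric |>
    dplyr::left_join(mu_ref, by = "subject") |>
    dplyr::mutate(shift_ratio = .data$mu / .data$mu_ref,
                  spectral_location = plan$f_ref_hz) |>
    dplyr::filter(is.finite(.data$shift_ratio), .data$shift_ratio > 0) |>
    dplyr::select("subject", "spectral_location", "acf", "shift_ratio")

  shift_data <- subject_shifts |>
    dplyr::group_by(.data$acf) |>
    dplyr::summarise(shift_ratio = median(.data$shift_ratio),
                     spectral_location = plan$f_ref_hz, .groups = "drop")

  pitch_fit <- fit_pitch_exponent(shift_data)
  list(
    sessions = if (keep_sessions) sessions else NULL,
    psychometric = psychometric,
    subject_shifts = subject_shifts,
    shift_data = shift_data,
    pitch_fit = pitch_fit,
    equal_pitch = equal_pitch_points(pitch_fit, plan$f_ref_hz, plan$a_test_um)
  )
}

run_human_amp <- function(config, seed, keep_sessions) {
  plan <- config$plan
  n_s <- config$n_subjects
  seeds <- make_stream_seeds(seed, n_s + 1L)

  sessions <- purrr::map_dfr(seq_len(n_s), function(m) {
    simulate_session(config, seeds[m], subject = m)
  })

  psychometric <- purrr::map_dfr(seq_len(n_s), function(m) {
    sm <- sessions[sessions$subject == m, ]
    purrr::map_dfr(plan$f_ref_hz, function(f_ref) {
      d <- bin_responses(sm[sm$frequency_b_hz == f_ref, ],
                         .data$amplitude_um, .data$response == "test_higher")
      fit_row(safe_psycho_mu(d, config$equal_asymptotes),
              subject = m, f_ref_hz = f_ref,
              is_reference = f_ref == plan$f_test_hz)
    })
  })

  mu_ref <- psychometric |>
    dplyr::filter(.data$is_reference) |>
    dplyr::select("subject", mu_ref = "mu")
  # amplitude shift ratio: the amplitude at frequency f judged as intense as
  # the reference, relative to the reference amplitude (mu_ref / mu maps the
  # test-side PSE back onto the standard's frequency axis)
  intensity_points <- psychometric |>
    dplyr::left_join(mu_ref, by = "subject") |>
    dplyr::mutate(shift_ratio = .data$mu_ref / .data$mu) |>
    dplyr::filter(is.finite(.data$shift_ratio), .data$shift_ratio > 0) |>
    dplyr::transmute(subject = .data$subject, frequency = .data$f_ref_hz,
                     shift_ratio = .data$shift_ratio,
                     amplitude = .data$shift_ratio * plan$a_ref_um)

  intensity_fit <- fit_intensity_curve(
    intensity_points |> dplyr::select("subject", "frequency", "amplitude"),
    n_boot = 100L, seed = seeds[n_s + 1L]
  )
  list(
    sessions = if (keep_sessions) sessions else NULL,
    psychometric = psychometric,
    intensity_points = intensity_points,
    intensity_fit = intensity_fit
  )
}

run_mouse_detection <- function(config, seed) {
  plan <- config$plan
  n_m <- config$n_subjects
  freqs <- plan$frequencies_hz
  n_sess <- config$n_sessions
  seeds <- array(make_stream_seeds(seed, n_m * length(freqs) * n_sess),
                 dim = c(n_m, length(freqs), n_sess))

  thresholds <- purrr::map_dfr(seq_len(n_m), function(m) {
    purrr::map_dfr(seq_along(freqs), function(fi) {
      thr <- purrr::map_dbl(seq_len(n_sess), function(s) {
        withr::with_seed(seeds[m, fi, s],
                         sim_mouse_detection(config, freqs[fi])$threshold)
      })
      tibble(subject = m, frequency = freqs[fi], session = seq_len(n_sess),
             threshold = thr)
    })
  })

  per_subject <- thresholds |>
    dplyr::group_by(.data$subject, .data$frequency) |>
    dplyr::summarise(threshold = mean(.data$threshold, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(threshold = ifelse(is.nan(.data$threshold), NA_real_,
                                     .data$threshold))

  list(
    thresholds = thresholds,
    per_subject = per_subject,
    sensitivity = aggregate_sensitivity(per_subject)
  )
}

run_human_detection <- function(config, seed) {
  plan <- config$plan
  n_s <- config$n_subjects
  freqs <- plan$frequencies_hz
  seeds <- matrix(make_stream_seeds(seed, n_s * length(freqs)), nrow = n_s)

  per_subject <- purrr::map_dfr(seq_len(n_s), function(m) {
    purrr::map_dfr(seq_along(freqs), function(fi) {
      thr <- withr::with_seed(seeds[m, fi],
                              sim_human_detection(config, freqs[fi])$threshold)
      tibble(subject = m, frequency = freqs[fi], threshold = thr)
    })
  })

  list(
    per_subject = per_subject,
    sensitivity = aggregate_sensitivity(per_subject)
  )
}

run_equal_intensity <- function(config, seed, keep_sessions) {
  n_s <- config$n_subjects
  seeds <- make_stream_seeds(seed, n_s)
  sessions <- purrr::map_dfr(seq_len(n_s), function(m) {
    simulate_session(config, seeds[m], subject = m)
  })
  conds <- unique(sessions[, c("condition", "acf")])
  psychometric <- purrr::map_dfr(seq_len(n_s), function(m) {
    sm <- sessions[sessions$subject == m, ]
    purrr::map_dfr(seq_len(nrow(conds)), function(ci) {
      d <- bin_responses(sm[sm$condition == conds$condition[ci], ],
                         .data$frequency_hz, .data$response == "test_higher")
      fit_row(safe_psycho_mu(d, config$equal_asymptotes),
              subject = m, condition = conds$condition[ci], acf = conds$acf[ci],
              is_reference = conds$condition[ci] == "reference")
    })
  })
  mu_ref <- psychometric |>
    dplyr::filter(.data$is_reference) |>
    dplyr::select("subject", mu_ref = "mu")
  shifts <- psychometric |>
    dplyr::filter(!.data$is_reference) |>
    dplyr::left_join(mu_ref, by = "subject") |>
    dplyr::mutate(shift_ratio = .data$mu / .data$mu_ref) |>
    dplyr::select("subject", "condition", "acf", "shift_ratio")
  list(
    sessions = if (keep_sessions) sessions else NULL,
    psychometric = psychometric,
    shifts = shifts,
    shift_summary = shifts |>
      dplyr::group_by(.data$condition, .data$acf) |>
      dplyr::summarise(median_shift = median(.data$shift_ratio, na.rm = TRUE),
                       .groups = "drop")
  )
}

#' Simulate-and-refit parameter recovery study
#'
#' Repeatedly simulates the configured discrimination experiment at one or
#' more generative exponents, refits the pitch exponent through the full
#' pipeline, and summarises bias, RMSE, confidence-interval coverage and the
#' rate at which the significance gate fires. Deterministic given the master
#' seed; each replicate draws an independent seed stream.
#'
#' @param config An [experiment_config()] for `"mouse_freq_gonogo"` or
#'   `"human_freq_2afc"`.
#' @param n_replicates Number of replicate experiments per exponent (>= 10).
#' @param k_true Vector of generative exponents (default: the configured
#'   observer's).
#' @param seed Master integer seed.
#' @return An object of class `recovery_report`: a list with `replicates`
#'   (one row per replicate: `k_true`, `k_hat`, CI, significance, seed) and
#'   `summary` (per `k_true`: bias, RMSE, coverage, significance rate).
#' @export
recovery_study <- function(config, n_replicates, k_true = NULL, seed = 1L) {
  validate_config(config)
  if (!config$experiment %in% c("mouse_freq_gonogo", "human_freq_2afc")) {
    abort("Recovery studies are defined for the frequency-discrimination experiments.",
          class = "vibropitch_config_error")
  }
  if (n_replicates < 10L) {
    abort("`n_replicates` must be >= 10.", class = "vibropitch_config_error")
  }
  grid <- k_true %||% config$observer$k_true
  seeds <- matrix(make_stream_seeds(seed, length(grid) * n_replicates),
                  nrow = length(grid))

  replicates <- purrr::map_dfr(seq_along(grid), function(gi) {
    cfg <- config
    cfg$observer$k_true <- grid[gi]
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      res <- run_experiment(cfg, seeds[gi, r], keep_sessions = FALSE)
      f <- res$pitch_fit
      tibble(
        k_true = grid[gi], replicate = r, seed = seeds[gi, r],
        k_hat = f$k, ci_low = f$k_ci[1], ci_high = f$k_ci[2],
        significant = f$significant, k_effective = f$k_effective,
        n_points = f$n_points
      )
    })
  })

  summary <- replicates |>
    dplyr::group_by(.data$k_true) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      bias = mean(.data$k_hat - .data$k_true),
      rmse = sqrt(mean((.data$k_hat - .data$k_true)^2)),
      median_k_hat = median(.data$k_hat),
      coverage = mean(.data$ci_low <= .data$k_true & .data$k_true <= .data$ci_high),
      significance_rate = mean(.data$significant),
      .groups = "drop"
    )
  structure(list(replicates = replicates, summary = summary),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery study\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.recovery_report <- function(x, ...) x$replicates

#' @export
glance.recovery_report <- function(x, ...) x$summary

# ---- session-table and results IO -----------------------------------------

session_required_cols <- c("trial_index", "task", "frequency_hz",
                           "amplitude_um", "response", "correct")
session_integer_cols <- c("trial_index", "subject", "session",
                          "seed_stream_id", "bout")

#' Read and write session tables
#'
#' Session tables are CSV files with one row per trial. The required columns
#' are `trial_index`, `task`, `frequency_hz`, `amplitude_um`, `response`,
#' `correct`; task-specific columns (two-stimulus fields, scheduler state,
#' staircase state) are preserved as-is. `read_session_table()` validates the
#' schema and errors with the list of missing columns; reading a written table
#' reproduces it field for field.
#'
#' @param data A session table (see [simulate_session()]).
#' @param path CSV file path.
#' @return `write_session_table()` returns `path` invisibly;
#'   `read_session_table()` returns a tibble.
#' @export
write_session_table <- function(data, path) {
  miss <- setdiff(session_required_cols, names(data))
  if (length(miss) > 0) {
    abort(paste0("Session table is missing required columns: ",
                 paste(miss, collapse = ", ")),
          class = "vibropitch_schema_error")
  }
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_session_table
#' @export
read_session_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(session_required_cols, names(x))
  if (length(miss) > 0) {
    abort(paste0("Session table is missing required columns: ",
                 paste(miss, collapse = ", ")),
          class = "vibropitch_schema_error")
  }
  for (cc in intersect(session_integer_cols, names(x))) {
    x[[cc]] <- as.integer(x[[cc]])
  }
  x
}

#' Write an experiment-results bundle to a directory
#'
#' Writes every tabular artifact of a [run_experiment()] bundle as CSV, the
#' fitted models as JSON, and a manifest with provenance (package version,
#' configuration hash, master seed) and the file list.
#'
#' @param bundle An `experiment_results` object.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "experiment_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  tab_fields <- c("sessions", "psychometric", "shift_data", "subject_shifts",
                  "intensity_points", "thresholds", "per_subject", "shifts",
                  "shift_summary")
  for (nm in intersect(tab_fields, names(bundle))) {
    if (is.null(bundle[[nm]])) next
    f <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(bundle[[nm]], f)
    files <- c(files, basename(f))
  }
  fits <- list()
  if (!is.null(bundle$pitch_fit)) {
    pf <- bundle$pitch_fit
    fits$pitch_exponent <- list(
      k = pf$k, k_se = pf$k_se, k_ci = pf$k_ci, significant = pf$significant,
      k_effective = pf$k_effective, k_nls = pf$k_nls, n_points = pf$n_points
    )
  }
  if (!is.null(bundle$intensity_fit)) {
    itf <- bundle$intensity_fit
    fits$intensity_curve <- list(
      a = itf$a, b = itf$b, c = itf$c, d = itf$d,
      param_sd = as.list(itf$param_sd), rss = itf$rss,
      fit_range = itf$fit_range
    )
  }
  if (!is.null(bundle$sensitivity)) {
    f <- file.path(dir, "sensitivity.csv")
    readr::write_csv(as_tibble(bundle$sensitivity), f)
    files <- c(files, basename(f))
    fits$sensitivity <- list(
      best_frequency = attr(bundle$sensitivity, "best_frequency"),
      best_frequency_interp = attr(bundle$sensitivity, "best_frequency_interp")
    )
  }
  if (length(fits) > 0) {
    jsonlite::write_json(fits, file.path(dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "fits.json")
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(provenance = bundle$provenance, experiment = bundle$config$experiment,
         files = files),
    manifest, auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}
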