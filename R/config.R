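#' Build an experiment configuration
#'
#' Assembles the full, validated description of one synthetic experiment: the
#' stimulus plan, the generative observer, the trial scheduler (go/no-go only)
#' and the study size. All numeric defaults come from [stimulus_plans()] and
#' [default_observer()].
#'
#' @param experiment One of `"mouse_freq_gonogo"`, `"human_freq_2afc"`,
#'   `"human_amp_2afc"`, `"mouse_detection"`, `"human_detection"`,
#'   `"equal_intensity_control"`.
#' @param location Spectral location (mouse range `"low"`/`"middle"`/`"high"`,
#'   human reference frequency in Hz, or reference amplitude in micrometres for
#'   the amplitude task / equal-intensity control).
#' @param observer An [observer_params()] override (default: the experiment's
#'   [default_observer()]).
#' @param scheduler A [scheduler_params()] override (go/no-go only).
#' @param n_subjects Number of synthetic subjects (default: the plan's value).
#' @param ... Experiment-specific overrides: `min_repeats`, `max_trials`,
#'   `probe_fraction`, `equal_asymptotes` (mouse go/no-go);
#'   `trials_per_a_ref` (human frequency task); `trials_per_f_ref` (human
#'   amplitude task); `n_sessions`, `n_bouts` (mouse detection);
#'   `n_trials`, `probe_acfs` (equal-intensity control).
#' @return A list of class `experiment_config`.
#' @examples
#' cfg <- experiment_config("mouse_freq_gonogo", location = "low")
#' cfg$plan$center_hz
#' @export
experiment_config <- function(experiment = c("mouse_freq_gonogo", "human_freq_2afc",
                                             "human_amp_2afc", "mouse_detection",
                                             "human_detection",
                                             "equal_intensity_control"),
                              location = NULL, observer = NULL, scheduler = NULL,
                              n_subjects = NULL, ...) {
  experiment <- match.arg(experiment)
  plans <- stimulus_plans()
  extra <- list(...)
  cfg <- switch(experiment,
    mouse_freq_gonogo = {
      loc <- location %||% "low"
      plan <- plans$mouse_freq[[loc]]
      if (is.null(plan)) abort("`location` must be 'low', 'middle' or 'high'.",
                               class = "vibropitch_config_error")
      list(
        experiment = experiment, location = loc, plan = plan,
        observer = observer %||% default_observer(experiment, loc),
        scheduler = scheduler %||% scheduler_params("double_sigmoid"),
        n_subjects = n_subjects %||% plan$n_mice,
        min_repeats = extra$min_repeats %||% plan$min_repeats,
        max_trials = extra$max_trials %||% 2000L,
        probe_fraction = extra$probe_fraction %||% plan$probe_fraction,
        equal_asymptotes = extra$equal_asymptotes %||% (loc != "middle")
      )
    },
    human_freq_2afc = {
      f_ref <- as.numeric(location %||% 440)
      hp <- plans$human_freq
      i <- match(f_ref, hp$f_ref_hz)
      if (is.na(i)) abort("`location` must be one of the tested reference frequencies.",
                          class = "vibropitch_config_error")
      list(
        experiment = experiment, location = f_ref,
        plan = list(
          f_ref_hz = f_ref, delta_max_hz = hp$delta_max_hz[i],
          step_min_hz = hp$step_min_hz[i], step_max_hz = hp$step_max_hz[i],
          a_test_um = hp$a_test_um, a_ref_um = hp$a_ref_um,
          min_trials_per_a_ref = hp$min_trials_per_a_ref
        ),
        observer = observer %||% default_observer(experiment, f_ref),
        n_subjects = n_subjects %||% hp$n_subjects,
        trials_per_a_ref = extra$trials_per_a_ref %||% 72L,
        equal_asymptotes = TRUE
      )
    },
    human_amp_2afc = {
      a_ref <- as.numeric(location %||% 10)
      hp <- plans$human_amp
      i <- match(a_ref, hp$a_ref_um)
      if (is.na(i)) abort("`location` must be one of the tested reference amplitudes.",
                          class = "vibropitch_config_error")
      list(
        experiment = experiment, location = a_ref,
        plan = list(
          a_ref_um = a_ref, delta_max_up_um = hp$delta_max_up_um[i],
          delta_max_down_um = hp$delta_max_down_um[i],
          step_min_um = hp$step_min_um, step_max_um = hp$step_max_um,
          f_test_hz = hp$f_test_hz, f_ref_hz = hp$f_ref_hz
        ),
        observer = observer %||% default_observer(experiment),
        n_subjects = n_subjects %||% hp$n_subjects,
        trials_per_f_ref = extra$trials_per_f_ref %||% 42L,
        equal_asymptotes = TRUE
      )
    },
    mouse_detection = {
      plan <- plans$mouse_detection
      list(
        experiment = experiment, location = NULL, plan = plan,
        observer = observer %||% default_observer(experiment),
        n_subjects = n_subjects %||% plan$n_mice,
        n_sessions = extra$n_sessions %||% plan$n_sessions,
        n_bouts = extra$n_bouts %||% 20L
      )
    },
    human_detection = {
      plan <- plans$human_detection
      list(
        experiment = experiment, location = NULL, plan = plan,
        observer = observer %||% default_observer(experiment),
        n_subjects = n_subjects %||% plan$n_subjects
      )
    },
    equal_intensity_control = {
      amp <- as.numeric(location %||% 10)
      if (!amp %in% c(10, 12)) {
        abort("`location` must be 10 or 12 (the tested equal-intensity curves, um).",
              class = "vibropitch_config_error")
      }
      list(
        experiment = experiment, location = amp,
        plan = list(
          f_ref_hz = 440, f_test_range_hz = c(352, 528), curve_amplitude_um = amp,
          curve_f_hz = plans$human_amp$f_ref_hz,
          probe_acfs = if (amp == 10) c(1.67, 0.77) else c(1.25, 0.85)
        ),
        observer = observer %||% default_observer(experiment, 440),
        n_subjects = n_subjects %||% 6L,
        n_trials = extra$n_trials %||% 540L,
        equal_asymptotes = TRUE
      )
    }
  )
  structure(cfg, class = "experiment_config")
}

#' Validate an experiment configuration
#'
#' Checks all parameter blocks of an [experiment_config()] and errors with the
#' list of offending fields.
#'
#' @param config An `experiment_config`.
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  if (!inherits(config, "experiment_config")) {
    abort("Not an `experiment_config` object.", class = "vibropitch_config_error")
  }
  if (!inherits(config$observer, "observer_params")) {
    problems <- c(problems, "observer: not an observer_params object")
  }
  if (is.null(config$n_subjects) || config$n_subjects < 1) {
    problems <- c(problems, "n_subjects: must be >= 1")
  }
  if (config$experiment == "mouse_freq_gonogo") {
    p <- config$plan
    if (!inherits(config$scheduler, "scheduler_params")) {
      problems <- c(problems, "scheduler: not a scheduler_params object")
    }
    if (any(p$no_go_hz >= p$center_hz) || any(p$go_hz <= p$center_hz)) {
      problems <- c(problems, "plan: no-go frequencies must lie below and go frequencies above the center")
    }
    if (config$probe_fraction <= 0 || config$probe_fraction >= 1) {
      problems <- c(problems, "probe_fraction: must be in (0, 1)")
    }
    if (config$min_repeats < 1) problems <- c(problems, "min_repeats: must be >= 1")
  }
  if (config$experiment == "human_freq_2afc") {
    p <- config$plan
    if (p$step_min_hz > p$step_max_hz) problems <- c(problems, "plan: step_min_hz > step_max_hz")
    if (config$trials_per_a_ref < p$min_trials_per_a_ref) {
      problems <- c(problems,
                    sprintf("trials_per_a_ref: must be >= %d", p$min_trials_per_a_ref))
    }
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid experiment configuration:\n",
                 paste0("  - ", problems, collapse = "\n")),
          class = "vibropitch_config_error")
  }
  invisible(config)
}

#' Write / read an experiment configuration as YAML
#'
#' Serialises the scalar and vector fields of a configuration to a structured
#' key-value file. Reading rebuilds the config through [experiment_config()]
#' so that validation and class structure are restored.
#'
#' @param config An `experiment_config`.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   an `experiment_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  obs <- config$observer
  out <- list(
    experiment = config$experiment,
    location = config$location,
    n_subjects = config$n_subjects,
    observer = list(
      k_true = obs$k_true, sigma_pitch = obs$sigma_pitch, lapse = obs$lapse,
      guess = obs$guess, sigma_intensity = obs$sigma_intensity,
      sigma_detect_db = obs$sigma_detect_db,
      vcurve = unclass(obs$vcurve)
    ),
    extras = config[setdiff(names(config),
                            c("experiment", "location", "plan", "observer",
                              "scheduler", "n_subjects"))]
  )
  if (!is.null(config$scheduler)) out$scheduler <- unclass(config$scheduler)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  obs <- do.call(observer_params, c(
    raw$observer[setdiff(names(raw$observer), "vcurve")],
    list(vcurve = do.call(sensitivity_curve_params, raw$observer$vcurve))
  ))
  sched <- if (!is.null(raw$scheduler)) do.call(scheduler_params, raw$scheduler)
  args <- c(
    list(experiment = raw$experiment, location = raw$location,
         observer = obs, scheduler = sched, n_subjects = raw$n_subjects),
    raw$extras
  )
  cfg <- do.call(experiment_config, args)
  validate_config(cfg)
  cfg
}
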