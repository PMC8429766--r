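#' Simulate one behavioural session
#'
#' Generates a synthetic session of the configured experiment by driving the
#' generative observer through the experiment's trial-selection machinery
#' (the go/no-go scheduler, the frequency/amplitude staircases, the 3-down/1-up
#' detection staircase, or the bout-based mouse detection procedure). The
#' output is a trial table (one `TrialRecord` per row) and is byte-identical
#' across calls with the same configuration and seed.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed for this session.
#' @param subject,session Indices recorded in the output; for the mouse
#'   go/no-go task the session index selects the probe amplitude (cycling
#'   through the plan's probe set), and for mouse detection it selects the
#'   tested frequency.
#' @return A tibble with the documented session-table columns (`trial_index`,
#'   `task`, `frequency_hz`, `amplitude_um`, response and correctness fields,
#'   and per-task extras such as `bias`, `p_go_scheduler`, `delta`, `step`).
#' @examples
#' cfg <- experiment_config("mouse_freq_gonogo", location = "low",
#'                          min_repeats = 2, max_trials = 200)
#' s <- simulate_session(cfg, seed = 1)
#' dplyr::count(s, is_go_stimulus, response)
#' @export
simulate_session <- function(config, seed, subject = 1L, session = 1L) {
  validate_config(config)
  out <- withr::with_seed(as.integer(seed), {
    switch(config$experiment,
      mouse_freq_gonogo = {
        amps <- config$plan$probe_amps_um
        probe <- amps[(as.integer(session) - 1L) %% length(amps) + 1L]
        sim_gonogo(config, probe)
      },
      human_freq_2afc = sim_human_freq(config),
      human_amp_2afc = sim_human_amp(config),
      mouse_detection = {
        fr <- config$plan$frequencies_hz
        f <- fr[(as.integer(session) - 1L) %% length(fr) + 1L]
        sim_mouse_detection(config, f, keep_trials = TRUE)$trials
      },
      human_detection = {
        purrr::map_dfr(config$plan$frequencies_hz, function(f) {
          sim_human_detection(config, f, keep_trials = TRUE)$trials
        })
      },
      equal_intensity_control = sim_equal_intensity(config)
    )
  })
  out$subject <- as.integer(subject)
  out$session <- as.integer(session)
  out$seed_stream_id <- as.integer(seed)
  out
}

# ---- mouse go/no-go -------------------------------------------------------

# One go/no-go session at a single probe amplitude. Trials continue until
# every stimulus frequency-amplitude pair has been seen `min_repeats` times
# (capped at `max_trials`). The scheduler columns (`bias`, `p_go_scheduler`)
# log the state that produced each trial-type draw.
sim_gonogo <- function(config, probe_amp) {
  plan <- config$plan; obs <- config$observer; sched <- config$scheduler
  k <- obs$k_true
  freqs <- c(plan$no_go_hz, plan$go_hz)
  n_ng <- length(plan$no_go_hz)
  n_f <- length(freqs)
  a_ref <- plan$a_ref_um
  boundary <- exp(k * log(a_ref)) * plan$center_hz
  ampk <- c(exp(k * log(a_ref)), exp(k * log(probe_amp)))
  amp_vals <- c(a_ref, probe_amp)
  has_probe <- probe_amp != a_ref
  gl <- 1 - obs$guess - obs$lapse
  sig <- obs$sigma_pitch
  W <- sched$window
  double_sig <- sched$strategy == "double_sigmoid"
  t1m <- sched$tau1 - 1; t2m <- sched$tau2 - 1
  s1 <- sched$s1; s2 <- sched$s2
  max_trials <- config$max_trials
  min_rep <- config$min_repeats
  p_probe <- config$probe_fraction

  win_go <- logical(W); win_c <- logical(W)
  win_len <- 0L; pos <- 0L
  n_go_w <- 0L; c_go_w <- 0L; n_ng_w <- 0L; c_ng_w <- 0L
  cr_run <- 0L
  pair_counts <- matrix(0L, nrow = 2L, ncol = n_f)

  o_f <- numeric(max_trials); o_a <- numeric(max_trials)
  o_go <- logical(max_trials); o_lick <- logical(max_trials)
  o_corr <- logical(max_trials); o_bias <- numeric(max_trials)
  o_pgo <- numeric(max_trials)

  t <- 0L
  repeat {
    t <- t + 1L
    f_go <- if (n_go_w > 0L) c_go_w / n_go_w else 0
    f_ng <- if (n_ng_w > 0L) c_ng_w / n_ng_w else 0
    bias <- min(max(f_ng - f_go, -1), 1)
    if (double_sig) {
      p_sched <- 1 - 0.5 / (1 + abs((bias + 1) / t1m)^s1) -
        0.5 / (1 + abs((bias + 1) / t2m)^s2)
      p_sched <- min(max(p_sched, 0), 1)
      is_go <- runif(1) < p_sched
    } else {
      p_sched <- NA_real_
      is_go <- if (cr_run >= 3L) runif(1) < 0.5 else FALSE
    }
    fi <- sample.int(n_ng, 1L) + if (is_go) n_ng else 0L
    ai <- if (has_probe && runif(1) < p_probe) 2L else 1L
    f <- freqs[fi]
    p_lick <- obs$guess + gl * pnorm((ampk[ai] * f - boundary) / sig)
    lick <- runif(1) < p_lick
    correct <- lick == is_go
    cr_run <- if (!is_go && !lick) cr_run + 1L else 0L

    pos <- pos %% W + 1L
    if (win_len == W) {
      if (win_go[pos]) {
        n_go_w <- n_go_w - 1L
        if (win_c[pos]) c_go_w <- c_go_w - 1L
      } else {
        n_ng_w <- n_ng_w - 1L
        if (win_c[pos]) c_ng_w <- c_ng_w - 1L
      }
    } else {
      win_len <- win_len + 1L
    }
    win_go[pos] <- is_go; win_c[pos] <- correct
    if (is_go) {
      n_go_w <- n_go_w + 1L
      if (correct) c_go_w <- c_go_w + 1L
    } else {
      n_ng_w <- n_ng_w + 1L
      if (correct) c_ng_w <- c_ng_w + 1L
    }

    pair_counts[ai, fi] <- pair_counts[ai, fi] + 1L
    o_f[t] <- f; o_a[t] <- amp_vals[ai]; o_go[t] <- is_go
    o_lick[t] <- lick; o_corr[t] <- correct
    o_bias[t] <- bias; o_pgo[t] <- p_sched

    if (t >= max_trials) break
    if (t %% 20L == 0L) {
      need <- if (has_probe) pair_counts else pair_counts[1L, , drop = FALSE]
      if (all(need >= min_rep)) break
    }
  }
  idx <- seq_len(t)
  tibble(
    trial_index = idx, task = "go_nogo_freq",
    frequency_hz = o_f[idx], amplitude_um = o_a[idx],
    is_go_stimulus = o_go[idx],
    response = ifelse(o_lick[idx], "lick", "no_lick"),
    correct = o_corr[idx],
    bias = o_bias[idx], p_go_scheduler = o_pgo[idx]
  )
}

# ---- human 2AFC frequency comparison --------------------------------------

sim_human_freq <- function(config) {
  plan <- config$plan; obs <- config$observer
  k <- obs$k_true
  f_ref <- plan$f_ref_hz
  a_test <- plan$a_test_um
  atk <- exp(k * log(a_test))
  s2 <- sqrt(2) * obs$sigma_pitch
  lp <- obs$lapse
  n_per <- config$trials_per_a_ref
  a_refs <- sample(plan$a_ref_um)

  res <- purrr::map(a_refs, function(a_ref) {
    pitch_std <- exp(k * log(a_ref)) * f_ref
    st <- list(
      above = freq_staircase(plan$delta_max_hz, plan$step_min_hz,
                             plan$step_max_hz, side = "above"),
      below = freq_staircase(plan$delta_max_hz, plan$step_min_hz,
                             plan$step_max_hz, side = "below")
    )
    f_t <- numeric(n_per); dlt <- numeric(n_per); stp <- numeric(n_per)
    sd_ <- character(n_per); rh <- logical(n_per); cor <- logical(n_per)
    for (t in seq_len(n_per)) {
      side <- if (t %% 2L == 1L) "above" else "below"
      s <- st[[side]]
      f_test <- if (side == "above") f_ref + s$delta else f_ref - s$delta
      p <- lp / 2 + (1 - lp) * pnorm((atk * f_test - pitch_std) / s2)
      resp_higher <- runif(1) < p
      correct <- resp_higher == (f_test > f_ref)
      f_t[t] <- f_test; dlt[t] <- s$delta; stp[t] <- s$step
      sd_[t] <- side; rh[t] <- resp_higher; cor[t] <- correct
      st[[side]] <- freq_staircase_update(s, correct)
    }
    tibble(
      trial_index = seq_len(n_per), task = "afc_freq",
      frequency_hz = f_t, amplitude_um = a_test,
      frequency_b_hz = f_ref, amplitude_b_um = a_ref,
      acf = a_test / a_ref,
      standard_first = runif(n_per) < 0.5,
      response = ifelse(rh, "test_higher", "standard_higher"),
      correct = cor,
      delta = dlt, step = stp, side = sd_
    )
  })
  out <- dplyr::bind_rows(res)
  out$trial_index <- seq_len(nrow(out))
  out
}

# ---- human 2AFC amplitude comparison --------------------------------------

sim_human_amp <- function(config) {
  plan <- config$plan; obs <- config$observer
  a_ref <- plan$a_ref_um
  f_test <- plan$f_test_hz
  t200 <- detection_threshold(f_test, obs$vcurve)
  s2 <- sqrt(2) * obs$sigma_intensity
  lp <- obs$lapse
  n_per <- config$trials_per_f_ref
  f_refs <- sample(plan$f_ref_hz)

  res <- purrr::map(f_refs, function(f_ref) {
    i_std <- log(a_ref / detection_threshold(f_ref, obs$vcurve))
    st <- list(
      above = freq_staircase(plan$delta_max_up_um, plan$step_min_um,
                             plan$step_max_um, side = "above"),
      below = freq_staircase(plan$delta_max_down_um, plan$step_min_um,
                             plan$step_max_um, side = "below")
    )
    a_t <- numeric(n_per); dlt <- numeric(n_per); stp <- numeric(n_per)
    sd_ <- character(n_per); rh <- logical(n_per); cor <- logical(n_per)
    for (t in seq_len(n_per)) {
      side <- if (t %% 2L == 1L) "above" else "below"
      s <- st[[side]]
      a_test <- if (side == "above") a_ref + s$delta else a_ref - s$delta
      p <- lp / 2 + (1 - lp) * pnorm((log(a_test / t200) - i_std) / s2)
      resp_higher <- runif(1) < p
      correct <- resp_higher == (a_test > a_ref)
      a_t[t] <- a_test; dlt[t] <- s$delta; stp[t] <- s$step
      sd_[t] <- side; rh[t] <- resp_higher; cor[t] <- correct
      st[[side]] <- freq_staircase_update(s, correct)
    }
    tibble(
      trial_index = seq_len(n_per), task = "afc_amp",
      frequency_hz = f_test, amplitude_um = a_t,
      frequency_b_hz = f_ref, amplitude_b_um = a_ref,
      standard_first = runif(n_per) < 0.5,
      response = ifelse(rh, "test_higher", "standard_higher"),
      correct = cor,
      delta = dlt, step = stp, side = sd_
    )
  })
  out <- dplyr::bind_rows(res)
  out$trial_index <- seq_len(nrow(out))
  out
}

# ---- mouse detection (bout procedure) -------------------------------------

# One session at one frequency. Trial types (stimulus present/absent) are
# drawn 50/50 with at most two of the same type in a row. Accuracy follows the
# detection psychometric at the bout's amplitude for both trial types (the
# session-level proportion correct the bout rule consumes).
sim_mouse_detection <- function(config, frequency, keep_trials = FALSE) {
  plan <- config$plan; obs <- config$observer
  a_max <- mouse_max_amplitude(frequency)
  thr <- detection_threshold(frequency, obs$vcurve)
  sdb <- obs$sigma_detect_db
  lp <- obs$lapse
  n_bouts <- config$n_bouts
  min_pres <- plan$bout_min_present; min_tot <- plan$bout_min_total
  step_fac_dn <- 10^(-plan$step_db / 20)
  step_fac_up <- 10^(plan$step_db / 20)

  amp <- a_max
  b_amp <- numeric(n_bouts); b_nc <- integer(n_bouts)
  b_np <- integer(n_bouts); b_nt <- integer(n_bouts)
  trials <- if (keep_trials) vector("list", n_bouts) else NULL
  run_type <- NA; run_len <- 0L   # trial-type run constraint spans bouts

  for (b in seq_len(n_bouts)) {
    p_corr <- 0.5 + (0.5 - lp / 2) * pnorm(20 * log10(amp / thr) / sdb)
    n_pres <- 0L; n_tot <- 0L; n_corr <- 0L
    pres_v <- logical(40L); corr_v <- logical(40L)
    while (n_pres < min_pres || n_tot < min_tot) {
      present <- if (!is.na(run_type) && run_len >= 2L) !run_type else runif(1) < 0.5
      if (!is.na(run_type) && present == run_type) run_len <- run_len + 1L
      else { run_type <- present; run_len <- 1L }
      correct <- runif(1) < p_corr
      n_tot <- n_tot + 1L
      if (present) n_pres <- n_pres + 1L
      if (correct) n_corr <- n_corr + 1L
      if (keep_trials && n_tot <= 40L) {
        pres_v[n_tot] <- present; corr_v[n_tot] <- correct
      }
    }
    b_amp[b] <- amp; b_nc[b] <- n_corr; b_np[b] <- n_pres; b_nt[b] <- n_tot
    if (keep_trials) {
      trials[[b]] <- tibble(
        bout = b, amplitude_um = amp,
        stimulus_present = pres_v[seq_len(n_tot)],
        correct = corr_v[seq_len(n_tot)]
      )
    }
    frac <- n_corr / n_tot
    if (frac > 0.7) amp <- amp * step_fac_dn
    else if (frac < 0.6) amp <- min(a_max, amp * step_fac_up)
  }

  bouts <- tibble(amplitude_um = b_amp, n_correct = b_nc,
                  n_present = b_np, n_total = b_nt)
  pv <- binomial_onesided_p(bouts$n_correct, bouts$n_total)
  sig <- bouts$amplitude_um[pv < plan$alpha]
  threshold <- if (length(sig) > 0) min(sig) else NA_real_

  trials_tbl <- NULL
  if (keep_trials) {
    trials_tbl <- dplyr::bind_rows(trials)
    trials_tbl <- tibble(
      trial_index = seq_len(nrow(trials_tbl)), task = "detect_mouse",
      frequency_hz = frequency, amplitude_um = trials_tbl$amplitude_um,
      stimulus_present = trials_tbl$stimulus_present,
      response = ifelse(trials_tbl$correct == trials_tbl$stimulus_present,
                        "present", "absent"),
      correct = trials_tbl$correct, bout = trials_tbl$bout
    )
  }
  list(threshold = threshold, bouts = bouts, trials = trials_tbl)
}

# ---- human detection (3-down/1-up) ----------------------------------------

sim_human_detection <- function(config, frequency, keep_trials = FALSE,
                                max_trials = 400L) {
  obs <- config$observer; plan <- config$plan
  a_max <- human_max_amplitude(frequency)
  thr <- detection_threshold(frequency, obs$vcurve)
  sdb <- obs$sigma_detect_db
  lp <- obs$lapse
  st <- updown_staircase(a_max, max_amplitude = a_max,
                         step_db = plan$start_step_db,
                         step_db_min = plan$step_db_min,
                         reversal_limit = plan$reversal_limit)
  corr_v <- logical(max_trials)
  t <- 0L
  while (!st$finished && t < max_trials) {
    t <- t + 1L
    p <- 0.5 + (0.5 - lp / 2) * pnorm(20 * log10(st$amplitude / thr) / sdb)
    correct <- runif(1) < p
    corr_v[t] <- correct
    st <- updown_update(st, correct)
  }
  threshold <- if (st$finished && length(st$amplitude_history) >= 10L) {
    updown_threshold(st)
  } else NA_real_
  trials_tbl <- NULL
  if (keep_trials) {
    trials_tbl <- tibble(
      trial_index = seq_len(t), task = "detect_human",
      frequency_hz = frequency,
      amplitude_um = st$amplitude_history[seq_len(t)],
      stimulus_present = TRUE,
      response = ifelse(corr_v[seq_len(t)], "correct_interval", "wrong_interval"),
      correct = corr_v[seq_len(t)]
    )
  }
  list(threshold = threshold, staircase = st, trials = trials_tbl)
}

# ---- equal-intensity control ----------------------------------------------

# All stimuli are drawn from one interpolated equal-intensity curve; the
# standard sits at 440 Hz and probe conditions rescale its amplitude by the
# configured amplitude change factors (test relative to standard).
sim_equal_intensity <- function(config) {
  plan <- config$plan; obs <- config$observer
  k <- obs$k_true
  ei <- equal_intensity_reference(plan, obs)
  f_levels <- seq(plan$f_test_range_hz[1], plan$f_test_range_hz[2], by = 16)
  a_levels <- interpolate_equal_intensity(ei, f_levels)
  a_std_base <- interpolate_equal_intensity(ei, plan$f_ref_hz)
  acfs <- c(1, plan$probe_acfs)
  n <- config$n_trials
  s2 <- sqrt(2) * obs$sigma_pitch
  lp <- obs$lapse

  cond <- sample.int(3L, n, replace = TRUE, prob = c(2 / 3, 1 / 6, 1 / 6))
  li <- sample.int(length(f_levels), n, replace = TRUE)
  f_test <- f_levels[li]; a_test <- a_levels[li]
  a_std <- a_std_base / acfs[cond]
  p <- lp / 2 + (1 - lp) *
    pnorm((exp(k * log(a_test)) * f_test - exp(k * log(a_std)) * plan$f_ref_hz) / s2)
  resp_higher <- runif(n) < p
  tibble(
    trial_index = seq_len(n), task = "afc_freq",
    frequency_hz = f_test, amplitude_um = a_test,
    frequency_b_hz = plan$f_ref_hz, amplitude_b_um = a_std,
    acf = acfs[cond], condition = c("reference", "probe_1", "probe_2")[cond],
    standard_first = runif(n) < 0.5,
    response = ifelse(resp_higher, "test_higher", "standard_higher"),
    correct = resp_higher == (f_test > plan$f_ref_hz)
  )
}

# equal-intensity knots used by the control experiment: the generative
# observer's V-curve scaled through (200 Hz, curve amplitude)
equal_intensity_reference <- function(plan, obs) {
  f <- plan$curve_f_hz
  tibble(
    frequency = f,
    amplitude = plan$curve_amplitude_um *
      detection_threshold(f, obs$vcurve) / detection_threshold(200, obs$vcurve)
  )
}
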