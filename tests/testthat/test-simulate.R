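test_that("sessions are byte-identical for identical configuration and seed", {
  cfg <- tiny_mouse_config()
  s1 <- simulate_session(cfg, seed = 123)
  s2 <- simulate_session(cfg, seed = 123)
  expect_identical(s1, s2)
  s3 <- simulate_session(cfg, seed = 124)
  expect_false(identical(s1, s3))
})

test_that("go fractions converge to the observer model per stimulus pair", {
  cfg <- experiment_config("mouse_freq_gonogo", location = "low",
                           n_subjects = 1, min_repeats = 60, max_trials = 4000)
  s <- simulate_session(cfg, seed = 31)
  obs <- cfg$observer
  boundary <- pitch_value(cfg$plan$center_hz, cfg$plan$a_ref_um, obs$k_true)
  emp <- s |>
    dplyr::group_by(frequency_hz, amplitude_um) |>
    dplyr::summarise(n = dplyr::n(), go = mean(response == "lick"),
                     .groups = "drop") |>
    dplyr::mutate(p = p_go(frequency_hz, amplitude_um, boundary, obs),
                  se = sqrt(p * (1 - p) / n))
  expect_true(all(abs(emp$go - emp$p) <= pmax(3 * emp$se, 0.02)))
})

test_that("the low-range plan yields every stimulus pair at least 10 times", {
  cfg <- experiment_config("mouse_freq_gonogo", location = "low", n_subjects = 1)
  s <- simulate_session(cfg, seed = 8, session = 1)   # probe 8.6 um
  counts <- dplyr::count(s, frequency_hz, amplitude_um)
  expect_equal(nrow(counts), 16L)                     # 8 frequencies x 2 amplitudes
  expect_true(all(counts$n >= 10L))
  expect_setequal(unique(s$frequency_hz),
                  c(310, 345, 380, 415, 485, 520, 555, 590))
  expect_setequal(unique(s$amplitude_um), c(5.6, 8.6))
})

test_that("human frequency sessions run the staircase per reference amplitude", {
  cfg <- experiment_config("human_freq_2afc", location = 440)
  s <- simulate_session(cfg, seed = 21)
  n_per <- dplyr::count(s, amplitude_b_um)
  expect_equal(nrow(n_per), 7L)
  expect_true(all(n_per$n >= 70L))
  expect_true(all(s$delta >= 32 & s$delta <= 256))
  expect_true(all(s$step >= 32 & s$step <= 64))
  expect_true(all(abs(s$frequency_hz - 440) == s$delta))
  expect_equal(unique(s$amplitude_um), 11.8)
})

test_that("human amplitude sessions staircase around each reference frequency", {
  cfg <- experiment_config("human_amp_2afc", location = 10,
                           n_subjects = 1, trials_per_f_ref = 42L)
  s <- simulate_session(cfg, seed = 13)
  expect_setequal(unique(s$frequency_b_hz), c(75, 100, 150, 200, 266, 400, 534))
  expect_equal(unique(s$frequency_hz), 200)           # test always at 200 Hz
  expect_true(all(s$amplitude_um > 0))
  above <- s$side == "above"
  expect_true(all(s$amplitude_um[above] > 10) && all(s$amplitude_um[!above] < 10))
  expect_true(all(s$delta <= 9) && all(s$step >= 1 & s$step <= 3))
})

test_that("mouse detection sessions respect the bout structure", {
  cfg <- experiment_config("mouse_detection", n_bouts = 10L)
  s <- simulate_session(cfg, seed = 17, session = 4)  # 1000 Hz
  expect_equal(unique(s$frequency_hz), 1000)
  per_bout <- s |>
    dplyr::group_by(bout) |>
    dplyr::summarise(n = dplyr::n(), n_present = sum(stimulus_present),
                     amp = dplyr::first(amplitude_um))
  expect_true(all(per_bout$n >= 12L))
  expect_true(all(per_bout$n_present >= 6L))
  # never more than two identical trial types in a row
  runs <- rle(s$stimulus_present)
  expect_lte(max(runs$lengths), 2L)
  # amplitudes move on the 4 dB grid
  ratio_db <- 20 * log10(per_bout$amp / max(per_bout$amp))
  expect_true(all(abs(ratio_db / 4 - round(ratio_db / 4)) < 1e-9))
})

test_that("session tables round-trip through CSV field for field", {
  cfg <- tiny_mouse_config()
  s <- simulate_session(cfg, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_table(s, path)
  s2 <- read_session_table(path)
  expect_equal(as.data.frame(s2), as.data.frame(s))
})

test_that("session-table IO validates the schema and tolerates CSV dialects", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(trial_index = 1, task = "x"), path)
  expect_error(read_session_table(path), class = "vibropitch_schema_error")
  expect_error(write_session_table(tibble::tibble(a = 1), path),
               class = "vibropitch_schema_error")
  # CRLF line endings and quoted fields parse identically
  lines <- c("trial_index,task,frequency_hz,amplitude_um,response,correct",
             '1,"go_nogo_freq",450,5.6,"lick",TRUE',
             '2,"go_nogo_freq",310,5.6,"no_lick",TRUE')
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste0(lines, "\r"), path2, sep = "\n")
  x <- read_session_table(path2)
  expect_equal(nrow(x), 2L)
  expect_equal(x$response, c("lick", "no_lick"))
})

test_that("configuration defaults reproduce the checked-in stimulus-plan constants", {
  plans <- stimulus_plans()
  ref <- jsonlite::fromJSON(system.file("extdata", "stimulus_plans.json",
                                        package = "vibropitch"),
                            simplifyVector = TRUE)
  norm <- function(x) rapply(x, as.numeric, classes = c("numeric", "integer"),
                             how = "replace")
  expect_equal(norm(plans), norm(ref))
})

test_that("invalid configurations fail validation with named fields", {
  cfg <- experiment_config("mouse_freq_gonogo", location = "low")
  cfg$probe_fraction <- 1.5
  cfg$n_subjects <- 0
  err <- tryCatch(validate_config(cfg), error = function(e) conditionMessage(e))
  expect_match(err, "probe_fraction")
  expect_match(err, "n_subjects")
  expect_error(experiment_config("human_freq_2afc", location = 999),
               class = "vibropitch_config_error")
  expect_error(experiment_config("human_freq_2afc", trials_per_a_ref = 10L) |>
                 validate_config(),
               class = "vibropitch_config_error")
})

test_that("configurations round-trip through YAML", {
  cfg <- experiment_config("human_freq_2afc", location = 440,
                           n_subjects = 3, trials_per_a_ref = 80L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$plan, cfg$plan)
  expect_equal(cfg2$observer$k_true, cfg$observer$k_true)
  expect_equal(cfg2$trials_per_a_ref, 80L)
  # a round-tripped config drives an identical simulation
  expect_identical(simulate_session(cfg, 5), simulate_session(cfg2, 5))
})
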