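test_that("FIR position smoothing preserves DC and suppresses jitter", {
  t <- seq(0, 3000, by = 2)
  const <- gaze_trial(t, rep(12, length(t)), target_amplitude = 12,
                      target_onset_time = 1750)
  expect_equal(filter_gaze(const)$data$x, rep(12, length(t)),
               tolerance = 1e-9)
  jit <- 0.2 * sin(2 * pi * 100 * t / 1000)
  step <- ifelse(t > 1500, 12, 0)
  noisy <- gaze_trial(t, step + jit, target_amplitude = 12,
                      target_onset_time = 1750)
  resid <- filter_gaze(noisy)$data$x - step
  mid <- t > 2000 & t < 2900 # away from the step edge
  expect_lt(max(abs(resid[mid])), 0.02) # >= 10x attenuation of 0.2 deg
  # a noiseless saccade's landing barely moves
  tr <- generate_saccade_trial(saccade_trial_spec(gain = 0.9))
  expect_lt(abs(filter_gaze(tr)$data$x[length(t)] - tr$truth$landing),
            0.05)
})

test_that("velocity is the central-difference derivative", {
  t <- seq(0, 1000, by = 2)
  lin <- gaze_trial(t, 10 * t / 1000, target_amplitude = 12,
                    target_onset_time = 500)
  expect_equal(compute_velocity(lin), rep(10, length(t)), tolerance = 1e-9)
  const <- gaze_trial(t, rep(3, length(t)), target_amplitude = 12,
                      target_onset_time = 500)
  expect_equal(compute_velocity(const), rep(0, length(t)))
})

test_that("saccade detection finds events at annotated onsets, in order", {
  tr <- generate_saccade_trial(saccade_trial_spec(target_amplitude = 12))
  ev <- detect_saccades(filter_gaze(tr))
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$onset_time - tr$truth$onset), 2)
  expect_equal(ev$amplitude, 12, tolerance = 0.1)
  # stationary gaze yields no events
  t <- seq(0, 3000, by = 2)
  still <- gaze_trial(t, rep(0, length(t)), target_amplitude = 12,
                      target_onset_time = 1750)
  expect_equal(nrow(detect_saccades(still)), 0)
  # primary + corrective come back in time order
  tr2 <- generate_saccade_trial(saccade_trial_spec(
    target_amplitude = 24, gain = 0.85,
    corrective = list(delay_ms = 120, gain = 0.8)))
  ev2 <- detect_saccades(filter_gaze(tr2))
  expect_equal(nrow(ev2), 2)
  expect_true(ev2$onset_time[2] > ev2$offset_time[1])
})

test_that("the 20%-of-distance primary rule is applied at the boundary", {
  t <- seq(0, 3000, by = 2)
  x <- ifelse(t >= 2000, 2.4, 0)
  series <- gaze_trial(t, x, target_amplitude = 12,
                       target_onset_time = 1750)
  ev <- function(amp) data.frame(onset_time = 2000, offset_time = 2100,
                                 amplitude = amp, peak_velocity = 300)
  hit <- select_primary(ev(2.4), series)    # exactly 20% of 12 qualifies
  expect_true(hit$valid)
  expect_equal(hit$error, 12 - 2.4)
  miss <- select_primary(ev(2.3999), series)
  expect_equal(miss$exclusion_reason, "no_primary")
  away <- select_primary(ev(-5), series)    # moves away from the target
  expect_equal(away$exclusion_reason, "no_primary")
})

test_that("a small first saccade is skipped in favor of the real response", {
  # first saccade +2 (< 2.4 = 20% of 12), corrective +11 -> lands at 13
  tr <- generate_saccade_trial(saccade_trial_spec(
    target_amplitude = 12, gain = 2 / 12,
    corrective = list(delay_ms = 100, gain = 1.1)))
  s <- score_saccade_trial(tr)
  expect_true(s$valid)
  expect_equal(s$error, 1, tolerance = 0.08)
  expect_gt(s$latency_ms, 250) # the selected event is the second one
})

test_that("latencies at the 70 ms anticipatory boundary are excluded", {
  lat70 <- score_saccade_trial(generate_saccade_trial(
    saccade_trial_spec(latency_ms = 70)))
  expect_false(lat70$valid)
  expect_equal(lat70$exclusion_reason, "anticipatory")
  lat50 <- score_saccade_trial(generate_saccade_trial(
    saccade_trial_spec(latency_ms = 50)))
  expect_equal(lat50$exclusion_reason, "anticipatory")
  lat74 <- score_saccade_trial(generate_saccade_trial(
    saccade_trial_spec(latency_ms = 74)))
  expect_true(lat74$valid)
  expect_equal(lat74$latency_ms, 74)
})

test_that("artifacts in the response window exclude the trial; fixation
           artifacts do not", {
  clean <- generate_saccade_trial(saccade_trial_spec())
  expect_equal(nrow(detect_blinks(clean)), 0)
  resp_blink <- generate_saccade_trial(saccade_trial_spec(
    blink = list(start_ms = 1750 + 300, duration_ms = 150)))
  s <- score_saccade_trial(resp_blink)
  expect_false(s$valid)
  expect_equal(s$exclusion_reason, "blink")
  fix_blink <- generate_saccade_trial(saccade_trial_spec(
    blink = list(start_ms = 300, duration_ms = 150)))
  s2 <- score_saccade_trial(fix_blink)
  expect_true(s2$valid)
})

test_that("scoring is mirror symmetric", {
  tr <- generate_saccade_trial(saccade_trial_spec(
    target_amplitude = 12, gain = 0.92, position_noise_sd = 0.05),
    seed = 21)
  mirrored <- gaze_trial(tr$data$time_ms, -tr$data$x, tr$data$y,
                         target_amplitude = -12,
                         target_onset_time = tr$target_onset_time)
  a <- score_saccade_trial(tr)
  b <- score_saccade_trial(mirrored)
  expect_equal(b$error, a$error, tolerance = 1e-9)
  expect_equal(b$latency_ms, a$latency_ms)
  expect_equal(a$direction, "right")
  expect_equal(b$direction, "left")
})

test_that("noiseless sessions score error = |gain - 1| x |target|", {
  sess <- generate_saccade_session(position_noise_sd = 0, seed = 33)
  scores <- score_saccade_trials(sess$trials)
  expect_true(all(scores$valid))
  # one sample's displacement at the offset threshold: 30 deg/s * 2 ms
  expect_lt(max(abs(scores$error - sess$manifest$true_error)), 0.06 + 1e-9)
})

test_that("condition summaries compute per-cell means and sample SDs", {
  mk <- function(err, amp, dir) {
    data.frame(participant_id = "P1", amplitude = amp, direction = dir,
               valid = TRUE, error = err)
  }
  sc <- rbind(mk(1, 12, "left"), mk(1, 12, "left"), mk(1, 12, "left"),
              mk(0, 24, "right"), mk(2, 24, "right"))
  sm <- summarize_conditions(sc)
  c1 <- sm[sm$amplitude == 12 & sm$direction == "left", ]
  expect_equal(c1$n_valid, 3)
  expect_equal(c1$mean_error, 1)
  expect_equal(c1$error_sd, 0)
  c2 <- sm[sm$amplitude == 24 & sm$direction == "right", ]
  expect_equal(c2$mean_error, 1)
  expect_equal(c2$error_sd, sqrt(2))
  empty <- sm[sm$amplitude == 24 & sm$direction == "left", ]
  expect_equal(empty$n_valid, 0)
  expect_true(is.na(empty$mean_error))
  expect_false(empty$sd_defined)
})
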