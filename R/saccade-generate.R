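#' Saccade-trial specification
#'
#' One trial of the visually guided saccade task: central fixation for
#' 1.5-2 s, then a peripheral target at +/-12 or +/-24 degrees shown for
#' 1.5 s while gaze is sampled at 500 Hz. The simulated response is a
#' symmetric smoothstep position profile whose duration follows a
#' main-sequence rule (`duration = 2.2 * amplitude + 21` ms), launched at
#' `latency_ms` after target onset and landing at `gain * target`.
#'
#' @param target_amplitude Signed target eccentricity, degrees; magnitude must
#'   be 12 or 24 (negative = leftward).
#' @param fixation_duration Fixation period, s (the task draws 1.5-2 s).
#' @param target_duration Target presentation, s.
#' @param sample_rate Hz.
#' @param latency_ms Saccade latency (target onset to movement onset), ms.
#' @param gain Primary-saccade amplitude divided by target distance (> 0).
#' @param main_sequence `c(slope, intercept)`: duration in ms as a linear
#'   function of amplitude in degrees.
#' @param position_noise_sd Additive white position noise, degrees (0 =
#'   noiseless).
#' @param corrective Optional `list(delay_ms=, gain=)`: a second saccade,
#'   launched `delay_ms` after the primary ends, covering `gain` of the
#'   remaining distance to the target.
#' @param blink Optional `list(start_ms=, duration_ms=)` relative to trial
#'   start; samples in the span are recorded as missing (`NA`), as an eye
#'   tracker reports during a blink.
#' @return Object of class `saccade_trial_spec`.
#' @export
saccade_trial_spec <- function(target_amplitude = 12,
                               fixation_duration = 1.75,
                               target_duration = 1.5, sample_rate = 500,
                               latency_ms = 200, gain = 1,
                               main_sequence = c(slope = 2.2, intercept = 21),
                               position_noise_sd = 0,
                               corrective = NULL, blink = NULL) {
  if (!abs(target_amplitude) %in% c(12, 24)) {
    stop("|target_amplitude| must be 12 or 24 degrees")
  }
  stopifnot(gain > 0, latency_ms >= 0, sample_rate > 0,
            fixation_duration > 0, position_noise_sd >= 0)
  dur <- main_sequence[[1]] * abs(gain * target_amplitude) +
    main_sequence[[2]]
  if (latency_ms + dur > target_duration * 1000) {
    stop("latency + saccade duration exceeds the target presentation window")
  }
  structure(as.list(environment()), class = "saccade_trial_spec")
}

#' Construct a gaze time series
#'
#' Container for one trial's sampled eye position plus target metadata.
#'
#' @param time_ms Sample times, ms (strictly increasing, uniform).
#' @param x,y Horizontal / vertical eye position, degrees (`NA` = missing
#'   sample, e.g. during a blink).
#' @param target_amplitude Signed target location, degrees.
#' @param target_onset_time Target onset, ms.
#' @param participant_id,trial_id,block Optional identifiers.
#' @param truth Optional generator ground-truth annotations.
#' @return Object of class `gaze_trial`.
#' @export
gaze_trial <- function(time_ms, x, y = rep(0, length(x)), target_amplitude,
                       target_onset_time, participant_id = NA_character_,
                       trial_id = NA_integer_, block = NA_integer_,
                       truth = NULL) {
  stopifnot(length(time_ms) == length(x), length(x) == length(y),
            all(diff(time_ms) > 0))
  if (!abs(target_amplitude) %in% c(12, 24)) {
    stop("|target_amplitude| must be 12 or 24 degrees")
  }
  structure(list(data = data.frame(time_ms = time_ms, x = x, y = y),
                 target_amplitude = target_amplitude,
                 target_onset_time = target_onset_time,
                 sample_rate = 1000 / stats::median(diff(time_ms)),
                 participant_id = participant_id, trial_id = trial_id,
                 block = block, truth = truth),
            class = "gaze_trial")
}

.smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  3 * u^2 - 2 * u^3
}

#' Generate a synthetic visually guided saccade trial
#'
#' Fixation at 0 degrees, then a smoothstep saccade launched `latency_ms`
#' after target onset with amplitude `gain * target`, holding at the landing
#' position afterwards (plus optional corrective saccade and blink). Ground
#' truth (`onset`, `offset`, `landing`, `latency_ms`, `peak_velocity`) is
#' annotated in `$truth`.
#'
#' @param spec A [saccade_trial_spec()].
#' @param seed Integer seed (only used when noise is present).
#' @inheritParams gaze_trial
#' @return A [gaze_trial()].
#' @export
generate_saccade_trial <- function(spec = saccade_trial_spec(), seed = 1L,
                                   participant_id = NA_character_,
                                   trial_id = NA_integer_,
                                   block = NA_integer_) {
  stopifnot(inherits(spec, "saccade_trial_spec"))
  set.seed(seed)
  dt <- 1000 / spec$sample_rate
  total_ms <- (spec$fixation_duration + spec$target_duration) * 1000
  t <- seq(0, total_ms - dt, by = dt)
  onset_target <- spec$fixation_duration * 1000
  amp <- spec$gain * spec$target_amplitude
  dur <- spec$main_sequence[[1]] * abs(amp) + spec$main_sequence[[2]]
  t0 <- onset_target + spec$latency_ms
  x <- amp * .smoothstep((t - t0) / dur)
  landing <- amp
  truth <- list(onset = t0, offset = t0 + dur, landing = amp,
                latency_ms = spec$latency_ms,
                peak_velocity = 1.5 * abs(amp) / dur * 1000)
  if (!is.null(spec$corrective)) {
    amp2 <- (spec$target_amplitude - amp) * spec$corrective$gain
    dur2 <- spec$main_sequence[[1]] * abs(amp2) + spec$main_sequence[[2]]
    t2 <- t0 + dur + spec$corrective$delay_ms
    x <- x + amp2 * .smoothstep((t - t2) / dur2)
    landing <- amp + amp2
    truth$corrective <- list(onset = t2, offset = t2 + dur2,
                             landing = landing)
  }
  if (spec$position_noise_sd > 0) {
    x <- x + stats::rnorm(length(t), sd = spec$position_noise_sd)
  }
  y <- if (spec$position_noise_sd > 0) {
    stats::rnorm(length(t), sd = spec$position_noise_sd)
  } else {
    rep(0, length(t))
  }
  if (!is.null(spec$blink)) {
    bl <- t >= spec$blink$start_ms &
      t < spec$blink$start_ms + spec$blink$duration_ms
    x[bl] <- NA_real_
    y[bl] <- NA_real_
  }
  gaze_trial(t, x, y, target_amplitude = spec$target_amplitude,
             target_onset_time = onset_target,
             participant_id = participant_id, trial_id = trial_id,
             block = block, truth = truth)
}

#' Generate a full saccade session for one participant
#'
#' The default session mirrors the task design: 60 trials in 2 blocks, with
#' targets at +/-12 and +/-24 degrees balanced across the four
#' amplitude-by-direction cells and presented in pseudorandom order. Per-trial
#' latency and gain are drawn from truncated normal distributions.
#'
#' @param participant_id Identifier carried into each trial.
#' @param n_trials,n_blocks Session size (trials must divide evenly into the
#'   four cells and the blocks).
#' @param gain_mean,gain_sd Per-trial saccade gain distribution (truncated
#'   below at 0.2).
#' @param latency_mean,latency_sd Per-trial latency distribution, ms
#'   (truncated below at `latency_min`).
#' @param latency_min Lower truncation for latency draws, ms.
#' @param position_noise_sd Degrees of white position noise per trial.
#' @param seed Integer seed.
#' @return List with `trials` (list of [gaze_trial()]s) and `manifest`
#'   (data.frame of per-trial conditions and ground truth).
#' @export
generate_saccade_session <- function(participant_id = "S0001",
                                     n_trials = 60, n_blocks = 2,
                                     gain_mean = 0.95, gain_sd = 0.06,
                                     latency_mean = 200, latency_sd = 30,
                                     latency_min = 80,
                                     position_noise_sd = 0.05,
                                     seed = 1L) {
  stopifnot(n_trials %% 4 == 0, n_trials %% n_blocks == 0)
  set.seed(seed)
  cells <- rep(c(-24, -12, 12, 24), each = n_trials / 4)
  ord <- sample.int(n_trials)
  targets <- cells[ord]
  fix <- stats::runif(n_trials, 1.5, 2)
  gains <- pmax(stats::rnorm(n_trials, gain_mean, gain_sd), 0.2)
  lats <- pmax(stats::rnorm(n_trials, latency_mean, latency_sd), latency_min)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    spec <- saccade_trial_spec(target_amplitude = targets[i],
                               fixation_duration = fix[i],
                               latency_ms = lats[i], gain = gains[i],
                               position_noise_sd = position_noise_sd)
    trials[[i]] <- generate_saccade_trial(
      spec, seed = trial_seeds[i], participant_id = participant_id,
      trial_id = i, block = ceiling(i / (n_trials / n_blocks)))
  }
  manifest <- data.frame(participant_id = participant_id,
                         trial_id = seq_len(n_trials),
                         block = ceiling(seq_len(n_trials) /
                                           (n_trials / n_blocks)),
                         target_amplitude = targets,
                         gain = gains, latency_ms = lats,
                         true_error = abs(gains - 1) * abs(targets))
  list(trials = trials, manifest = manifest)
}
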