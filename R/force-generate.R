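#' Band-limited 1/f-mixture noise
#'
#' FFT-shaped noise used by the force-trace generator: a configurable mixture
#' of pink (1/f power) and white components, band-limited so that the scoring
#' pipeline's 15 Hz low-pass filter does not remove variance and bias the
#' recovered coefficient of variation.
#'
#' @param n Number of samples.
#' @param sample_rate Hz.
#' @param mix `c(pink, white)` weights.
#' @param band `c(lo, hi)` passband in Hz.
#' @return Numeric vector (unnormalized; callers standardize).
#' @keywords internal
band_noise <- function(n, sample_rate, mix = c(pink = 0.5, white = 0.5),
                       band = c(0, 12)) {
  shape <- function(gain_fun) {
    f <- seq_len(n) - 1
    f <- pmin(f, n - f) * sample_rate / n # folded (two-sided) frequencies
    g <- gain_fun(f)
    g[f < band[1] | f > band[2]] <- 0
    g[1] <- 0 # no DC component
    x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * g, inverse = TRUE)) / n
    s <- stats::sd(x)
    if (s > 0) x / s else x
  }
  f0 <- sample_rate / n
  pink <- shape(function(f) 1 / sqrt(pmax(f, f0)))
  white <- shape(function(f) rep(1, length(f)))
  mix[[1]] * pink + mix[[2]] * white
}

#' Force-trial specification
#'
#' Parameters of one synthetic precision-grip trial: a 15 s trace sampled at
#' 200 Hz in which force rises from baseline after a reaction time and is then
#' held at `target_fraction * mvc` (the task instructs holding a force bar at
#' 15% of the participant's maximum voluntary contraction). Plateau noise is
#' multiplicative with true coefficient of variation `latent_cov`;
#' `release_events` inject forced zero-force drops used to exercise the
#' exclusion rules.
#'
#' @param mvc Maximum voluntary contraction, N.
#' @param target_fraction Plateau level as a fraction of MVC (0 < f < 1).
#' @param trial_duration Trial length in s; the stop cue appears at its end.
#' @param sample_rate Hz.
#' @param reaction_time Seconds from trial start to force onset.
#' @param rise_time Seconds from force onset to plateau.
#' @param latent_cov Ground-truth CoV of the sustained phase (>= 0; 0 gives a
#'   noiseless plateau).
#' @param noise_mix,noise_band Passed to the plateau noise generator; the
#'   default 0.5 pink + 0.5 white mixture band-limited to 0-12 Hz survives the
#'   scoring filter intact.
#' @param release_events Optional list of `c(start, duration)` (s) spans in
#'   which force is forced to zero.
#' @return Object of class `force_trial_spec`.
#' @export
force_trial_spec <- function(mvc = 60, target_fraction = 0.15,
                             trial_duration = 15, sample_rate = 200,
                             reaction_time = 0.3, rise_time = 0.25,
                             latent_cov = 0.05,
                             noise_mix = c(pink = 0.5, white = 0.5),
                             noise_band = c(0, 12),
                             release_events = NULL) {
  stopifnot(mvc > 0, target_fraction > 0, target_fraction < 1,
            latent_cov >= 0, sample_rate > 0,
            reaction_time >= 0, rise_time > 0)
  if (trial_duration < reaction_time + rise_time + 8) {
    stop("trial too short: need >= 8 s of plateau after the rise")
  }
  if (!is.null(release_events)) {
    for (ev in release_events) {
      stopifnot(length(ev) == 2, ev[2] >= 0)
    }
  }
  structure(as.list(environment()), class = "force_trial_spec")
}

#' Construct a force time series
#'
#' Container for one grip trial's sampled force trace plus the metadata the
#' scoring functions need (stop-cue time, hand, ids). Times must be strictly
#' increasing and uniformly sampled.
#'
#' @param time Sample times, s.
#' @param force Force, N.
#' @param stop_cue_time Stop-cue time, s (defaults to the last sample).
#' @param hand `"left"` or `"right"` (optional).
#' @param participant_id,trial_id Optional identifiers.
#' @param truth Optional list of generator ground-truth annotations.
#' @return Object of class `force_trial`.
#' @export
force_trial <- function(time, force, stop_cue_time = max(time) + mean(diff(time)),
                        hand = NA_character_, participant_id = NA_character_,
                        trial_id = NA_integer_, truth = NULL) {
  stopifnot(length(time) == length(force), length(time) >= 2,
            all(diff(time) > 0), all(is.finite(force)))
  if (stop_cue_time < time[1] ||
      stop_cue_time > time[length(time)] + mean(diff(time)) + 1e-9) {
    stop("stop_cue_time must lie within the trace")
  }
  structure(list(data = data.frame(time = time, force = force),
                 stop_cue_time = stop_cue_time,
                 sample_rate = 1 / stats::median(diff(time)),
                 hand = hand, participant_id = participant_id,
                 trial_id = trial_id, truth = truth),
            class = "force_trial")
}

#' Generate a synthetic precision-grip trial
#'
#' Produces a `force_trial`: baseline at 0 N, a smoothstep rise beginning at
#' `reaction_time` and reaching the plateau at `reaction_time + rise_time`,
#' then a sustained plateau at `target_fraction * mvc` carrying multiplicative
#' noise standardized per realization so the plateau's sample CoV equals
#' `latent_cov` exactly. Release events zero the trace over their spans.
#' Ground truth (`onset_offset`, `target_force`, `cov`) is annotated in
#' `$truth`.
#'
#' @param spec A [force_trial_spec()].
#' @param seed Integer seed.
#' @param hand,participant_id,trial_id Metadata carried into the trial.
#' @return A [force_trial()].
#' @export
generate_force_trial <- function(spec = force_trial_spec(), seed = 1L,
                                 hand = NA_character_,
                                 participant_id = NA_character_,
                                 trial_id = NA_integer_) {
  stopifnot(inherits(spec, "force_trial_spec"))
  set.seed(seed)
  fs <- spec$sample_rate
  n <- round(spec$trial_duration * fs)
  t <- (seq_len(n) - 1) / fs
  f0 <- spec$target_fraction * spec$mvc
  t_on <- spec$reaction_time
  t_off <- spec$reaction_time + spec$rise_time
  u <- pmin(pmax((t - t_on) / spec$rise_time, 0), 1)
  force <- f0 * (3 * u^2 - 2 * u^3)
  plateau <- t >= t_off
  if (spec$latent_cov > 0) {
    z <- band_noise(n, fs, spec$noise_mix, spec$noise_band)
    zp <- z[plateau]
    zp <- (zp - mean(zp)) / stats::sd(zp)
    force[plateau] <- f0 * (1 + spec$latent_cov * zp)
  }
  if (!is.null(spec$release_events)) {
    for (ev in spec$release_events) {
      force[t >= ev[1] & t < ev[1] + ev[2]] <- 0
    }
  }
  force_trial(t, force, stop_cue_time = spec$trial_duration,
              hand = hand, participant_id = participant_id,
              trial_id = trial_id,
              truth = list(onset_offset = t_off, target_force = f0,
                           cov = spec$latent_cov))
}

#' Generate a maximal-effort (MVC) trial
#'
#' Three-second maximal press: force ramps up to the participant's maximum and
#' is held with small fluctuations. The realized peak is annotated in
#' `$truth$peak`, so MVC computation can be checked against ground truth.
#'
#' @param max_force Peak force the participant can produce, N.
#' @param duration Trial length, s.
#' @param sample_rate Hz.
#' @param seed Integer seed.
#' @inheritParams generate_force_trial
#' @return A [force_trial()] with `truth$peak`.
#' @export
generate_mvc_trial <- function(max_force, duration = 3, sample_rate = 200,
                               seed = 1L, hand = NA_character_,
                               participant_id = NA_character_,
                               trial_id = NA_integer_) {
  stopifnot(max_force > 0, duration > 1)
  set.seed(seed)
  fs <- sample_rate
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  u <- pmin(t / 0.8, 1)
  force <- max_force * (3 * u^2 - 2 * u^3)
  hold <- t >= 0.8
  force[hold] <- force[hold] *
    (1 - 0.03 * abs(cumsum(stats::rnorm(sum(hold), sd = 0.05)) /
                      sqrt(seq_len(sum(hold)))))
  force <- pmax(force, 0)
  force_trial(t, force, stop_cue_time = duration, hand = hand,
              participant_id = participant_id, trial_id = trial_id,
              truth = list(peak = max(force)))
}
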