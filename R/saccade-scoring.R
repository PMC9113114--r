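#' Saccade-scoring configuration
#'
#' Thresholds of the saccade scoring pipeline. The published rules fix the
#' offset velocity threshold (eye velocity falling below 30 deg/s), the
#' anticipatory-latency cutoff (latency <= 70 ms excluded), and the
#' primary-saccade rule (first saccade covering at least 20% of the distance
#' to the target). The remaining parameters are field-standard defaults
#' exposed here: a symmetric 30 deg/s onset threshold with a minimum
#' above-threshold duration of 8 ms; a linear-phase FIR low-pass (31 taps,
#' 50 Hz cutoff at 500 Hz) for position smoothing; and automated blink/artifact
#' handling (missing samples or velocity above 1000 deg/s, padded by 50 ms,
#' with trials excluded when an artifact overlaps the first second after
#' target onset) replacing manual visual inspection.
#'
#' @param onset_velocity_threshold deg/s (must be >= the offset threshold).
#' @param offset_velocity_threshold deg/s.
#' @param min_saccade_duration ms above the onset threshold.
#' @param anticipatory_max_latency ms; latencies at or below this are
#'   anticipatory.
#' @param primary_fraction Fraction of target distance a saccade must cover
#'   to qualify as primary.
#' @param require_direction If `TRUE` (default), a primary-saccade candidate
#'   must move toward the target.
#' @param fir_cutoff,fir_taps Position-filter design (cutoff Hz, odd tap
#'   count).
#' @param blink_velocity_ceiling deg/s above which samples are artifact.
#' @param blink_pad ms of padding around artifact spans.
#' @param blink_window ms after target onset within which an artifact
#'   excludes the trial.
#' @return Object of class `saccade_config`.
#' @export
saccade_config <- function(onset_velocity_threshold = 30,
                           offset_velocity_threshold = 30,
                           min_saccade_duration = 8,
                           anticipatory_max_latency = 70,
                           primary_fraction = 0.20,
                           require_direction = TRUE,
                           fir_cutoff = 50, fir_taps = 31,
                           blink_velocity_ceiling = 1000,
                           blink_pad = 50, blink_window = 1000) {
  stopifnot(onset_velocity_threshold >= offset_velocity_threshold,
            primary_fraction > 0, primary_fraction < 1,
            fir_taps %% 2 == 1, min_saccade_duration > 0)
  structure(as.list(environment()), class = "saccade_config")
}

.conv_same <- function(x, h) {
  k <- (length(h) - 1) / 2
  xp <- c(rep(x[1], k), x, rep(x[length(x)], k))
  as.numeric(stats::filter(xp, h, sides = 2))[(k + 1):(k + length(x))]
}

#' Smooth gaze position with a linear-phase FIR low-pass
#'
#' Symmetric (zero-phase by construction) FIR smoothing of the horizontal and
#' vertical position channels; timestamps are unchanged, DC is preserved
#' (taps normalized to unit sum), and edges are handled by replicating the
#' end samples. Missing samples are linearly interpolated for filtering and
#' restored to `NA` afterwards.
#'
#' @param series A [gaze_trial()].
#' @param config A [saccade_config()].
#' @return The series with smoothed `x` and `y`.
#' @export
filter_gaze <- function(series, config = saccade_config()) {
  stopifnot(inherits(series, "gaze_trial"))
  fs <- 1000 / stats::median(diff(series$data$time_ms))
  if (config$fir_cutoff >= fs / 2) {
    stop("FIR cutoff must be below the Nyquist frequency")
  }
  h <- signal::fir1(config$fir_taps - 1, config$fir_cutoff / (fs / 2))
  h <- h / sum(h)
  smooth1 <- function(v) {
    na <- is.na(v)
    if (all(na)) return(v)
    if (any(na)) {
      v <- stats::approx(which(!na), v[!na], xout = seq_along(v),
                         rule = 2)$y
    }
    out <- .conv_same(v, h)
    out[na] <- NA_real_
    out
  }
  series$data$x <- smooth1(series$data$x)
  series$data$y <- smooth1(series$data$y)
  series
}

#' Horizontal eye velocity
#'
#' Central-difference derivative of horizontal position with one-sided
#' differences at the endpoints, in deg/s.
#'
#' @param series A [gaze_trial()].
#' @return Numeric vector of velocities (deg/s), one per sample.
#' @export
compute_velocity <- function(series) {
  stopifnot(inherits(series, "gaze_trial"))
  x <- series$data$x
  t <- series$data$time_ms / 1000
  n <- length(x)
  if (n < 3) stop("need at least 3 samples")
  c(x[2] - x[1],
    (x[3:n] - x[1:(n - 2)]) / 2,
    x[n] - x[n - 1]) / c(t[2] - t[1],
                         (t[3:n] - t[1:(n - 2)]) / 2,
                         t[n] - t[n - 1])
}

#' Detect blink/artifact spans
#'
#' Automated surrogate for manual inspection: spans of missing samples or of
#' implausible velocity (above `blink_velocity_ceiling`), padded by
#' `blink_pad` ms and merged.
#'
#' @param series A raw [gaze_trial()].
#' @param config A [saccade_config()].
#' @param velocity Optional velocity trace (computed when omitted).
#' @return data.frame with `start_ms`, `end_ms` (possibly zero rows).
#' @export
detect_blinks <- function(series, config = saccade_config(),
                          velocity = NULL) {
  stopifnot(inherits(series, "gaze_trial"))
  t <- series$data$time_ms
  bad <- is.na(series$data$x) | is.na(series$data$y)
  if (is.null(velocity) && !all(bad)) {
    tmp <- series
    if (any(bad)) {
      tmp$data$x <- stats::approx(t[!bad], series$data$x[!bad], xout = t,
                                  rule = 2)$y
    }
    velocity <- compute_velocity(tmp)
  }
  if (!is.null(velocity)) {
    bad <- bad | (!is.na(velocity) &
                    abs(velocity) > config$blink_velocity_ceiling & !bad)
  }
  if (!any(bad)) {
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0)))
  }
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  spans <- data.frame(start_ms = t[starts[r$values]] - config$blink_pad,
                      end_ms = t[ends[r$values]] + config$blink_pad)
  # merge overlapping padded spans
  if (nrow(spans) > 1) {
    keep <- list(spans[1, ])
    for (i in 2:nrow(spans)) {
      last <- keep[[length(keep)]]
      if (spans$start_ms[i] <= last$end_ms) {
        keep[[length(keep)]]$end_ms <- max(last$end_ms, spans$end_ms[i])
      } else {
        keep[[length(keep) + 1]] <- spans[i, ]
      }
    }
    spans <- do.call(rbind, keep)
  }
  rownames(spans) <- NULL
  spans
}

.blink_in_window <- function(spans, target_onset, window) {
  nrow(spans) > 0 && any(spans$start_ms < target_onset + window &
                           spans$end_ms > target_onset)
}

#' Detect saccades from a velocity trace
#'
#' Maximal spans in which absolute velocity stays at or above the onset
#' threshold for at least `min_saccade_duration` ms; each span is extended
#' forward to the first sample at which velocity falls below the offset
#' threshold (30 deg/s), which defines the saccade offset. Amplitude is the
#' position change from onset to offset.
#'
#' @param series A (filtered) [gaze_trial()].
#' @param velocity Velocity from [compute_velocity()] (computed when
#'   omitted).
#' @param config A [saccade_config()].
#' @return data.frame of events ordered in time: `onset_time`, `offset_time`
#'   (ms), `amplitude` (deg, signed), `peak_velocity` (deg/s, signed).
#' @export
detect_saccades <- function(series, velocity = NULL,
                            config = saccade_config()) {
  stopifnot(inherits(series, "gaze_trial"))
  if (is.null(velocity)) velocity <- compute_velocity(series)
  t <- series$data$time_ms
  x <- series$data$x
  n <- length(t)
  fs <- 1000 / stats::median(diff(t))
  av <- abs(velocity)
  av[is.na(av)] <- 0
  above <- av >= config$onset_velocity_threshold
  min_len <- max(1L, round(config$min_saccade_duration * fs / 1000))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- NULL
  last_offset <- -Inf
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] || r$lengths[k] < min_len) next
    i_on <- starts[k]
    if (i_on <= last_offset) next # merged into the previous event
    j <- ends[k]
    while (j < n && av[j] >= config$offset_velocity_threshold) j <- j + 1
    # j is now the first sample at which velocity fell below the offset
    # threshold (or the last sample of the trace)
    i_off <- j
    seg <- i_on:i_off
    pk <- seg[which.max(av[seg])]
    out <- rbind(out, data.frame(onset_time = t[i_on],
                                 offset_time = t[i_off],
                                 amplitude = x[i_off] - x[i_on],
                                 peak_velocity = velocity[pk]))
    last_offset <- i_off
  }
  if (is.null(out)) {
    out <- data.frame(onset_time = numeric(0), offset_time = numeric(0),
                      amplitude = numeric(0), peak_velocity = numeric(0))
  }
  out
}

#' Select the primary saccade and score the trial
#'
#' The primary saccade is the first detected saccade, after target onset,
#' whose amplitude covers at least `primary_fraction` (20%) of the distance
#' from fixation to the target (and, by default, moves toward it). Trials
#' whose primary saccade has latency at or below the anticipatory cutoff
#' (70 ms) are excluded; trials with no qualifying saccade are scored
#' `no_primary`. Error is the absolute horizontal distance between the eye
#' position at the primary saccade's offset and the target.
#'
#' @param events Event table from [detect_saccades()].
#' @param series The (filtered) [gaze_trial()] the events came from.
#' @param config A [saccade_config()].
#' @return One-row data.frame: ids, condition (`amplitude`, `direction`),
#'   `valid`, `exclusion_reason`, primary-saccade onset/offset/amplitude/
#'   peak velocity, `latency_ms`, `landing_x`, `error`.
#' @export
select_primary <- function(events, series, config = saccade_config()) {
  stopifnot(inherits(series, "gaze_trial"))
  target <- series$target_amplitude
  onset0 <- series$target_onset_time
  score <- data.frame(participant_id = series$participant_id,
                      trial_id = series$trial_id, block = series$block,
                      amplitude = abs(target),
                      direction = if (target < 0) "left" else "right",
                      valid = FALSE, exclusion_reason = "no_primary",
                      onset_time = NA_real_, offset_time = NA_real_,
                      saccade_amplitude = NA_real_,
                      peak_velocity = NA_real_, latency_ms = NA_real_,
                      landing_x = NA_real_, error = NA_real_,
                      stringsAsFactors = FALSE)
  if (nrow(events) == 0) return(score)
  ev <- events[events$onset_time > onset0, , drop = FALSE]
  if (nrow(ev) == 0) return(score)
  # ">= 20% of the distance", with numeric tolerance at the exact boundary
  qualifies <- abs(ev$amplitude) >=
    config$primary_fraction * abs(target) - 1e-9
  if (config$require_direction) {
    qualifies <- qualifies & (sign(ev$amplitude) == sign(target))
  }
  if (!any(qualifies)) return(score)
  pr <- ev[which(qualifies)[1], ]
  latency <- pr$onset_time - onset0
  x_off <- series$data$x[match(pr$offset_time, series$data$time_ms)]
  score$onset_time <- pr$onset_time
  score$offset_time <- pr$offset_time
  score$saccade_amplitude <- pr$amplitude
  score$peak_velocity <- pr$peak_velocity
  score$latency_ms <- latency
  score$landing_x <- x_off
  score$error <- abs(x_off - target)
  if (latency <= config$anticipatory_max_latency) {
    score$exclusion_reason <- "anticipatory"
  } else {
    score$valid <- TRUE
    score$exclusion_reason <- "none"
  }
  score
}

#' Score one visually guided saccade trial
#'
#' Full per-trial pipeline: blink/artifact detection on the raw trace (a
#' trial is excluded when an artifact overlaps the first `blink_window` ms
#' after target onset), FIR position smoothing, velocity computation, saccade
#' detection, and primary-saccade selection/scoring.
#'
#' @param series A raw [gaze_trial()].
#' @param config A [saccade_config()].
#' @return One-row data.frame (see [select_primary()]).
#' @export
score_saccade_trial <- function(series, config = saccade_config()) {
  stopifnot(inherits(series, "gaze_trial"))
  spans <- detect_blinks(series, config)
  if (.blink_in_window(spans, series$target_onset_time,
                       config$blink_window)) {
    empty <- data.frame(onset_time = numeric(0), offset_time = numeric(0),
                        amplitude = numeric(0), peak_velocity = numeric(0))
    out <- select_primary(empty, series, config)
    out$exclusion_reason <- "blink"
    return(out)
  }
  filtered <- filter_gaze(series, config)
  na <- is.na(filtered$data$x)
  if (any(na)) { # fixation-period blink: interpolate through it for scoring
    t <- filtered$data$time_ms
    filtered$data$x <- stats::approx(t[!na], filtered$data$x[!na], xout = t,
                                     rule = 2)$y
    nay <- is.na(filtered$data$y)
    filtered$data$y <- stats::approx(t[!nay], filtered$data$y[!nay],
                                     xout = t, rule = 2)$y
  }
  v <- compute_velocity(filtered)
  events <- detect_saccades(filtered, v, config)
  select_primary(events, filtered, config)
}

#' Score a list of saccade trials
#'
#' @param trials List of [gaze_trial()]s.
#' @param config A [saccade_config()].
#' @return data.frame with one row per trial.
#' @export
score_saccade_trials <- function(trials, config = saccade_config()) {
  do.call(rbind, lapply(trials, score_saccade_trial, config = config))
}

#' Per-condition saccade summaries
#'
#' Mean saccade error and trial-to-trial error variability (sample SD of
#' error across valid trials) per participant and amplitude-by-direction
#' cell. Cells with fewer than two valid trials get `NA` variability and are
#' flagged; empty cells are kept with `n_valid = 0`.
#'
#' @param scores Trial-score table from [score_saccade_trials()].
#' @return data.frame: `participant_id`, `amplitude` (12/24), `direction`
#'   (left/right), `n_valid`, `mean_error`, `error_sd`, `sd_defined`.
#' @export
summarize_conditions <- function(scores) {
  cells <- expand.grid(participant_id = unique(scores$participant_id),
                       amplitude = c(12, 24),
                       direction = c("left", "right"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    s <- scores[scores$participant_id == cell$participant_id &
                  scores$amplitude == cell$amplitude &
                  scores$direction == cell$direction & scores$valid, ,
                drop = FALSE]
    n <- nrow(s)
    data.frame(cell,
               n_valid = n,
               mean_error = if (n > 0) mean(s$error) else NA_real_,
               error_sd = if (n > 1) stats::sd(s$error) else NA_real_,
               sd_defined = n > 1)
  }))
  out[order(out$participant_id, out$amplitude, out$direction), ,
      drop = FALSE]
}
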