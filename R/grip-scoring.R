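#' Grip-scoring configuration
#'
#' Thresholds of the precision-grip scoring pipeline. Defaults implement the
#' published processing rules: fourth-order Butterworth low-pass at 15 Hz
#' (applied forward-backward, i.e. zero-phase), a sustained phase defined as
#' the 12 s preceding the stop cue, removal of zero-force releases longer
#' than 1 s, trial exclusion below 8 s of retained sustained output, and a
#' rise offset located where the rate of force increase falls below 5% of its
#' peak while force sits within 90-110% of the sustained-phase mean.
#' `zero_force_epsilon` is the force-transducer resolution (0.0016 N).
#'
#' @param filter_order Butterworth order.
#' @param filter_cutoff Low-pass cutoff, Hz.
#' @param sustained_window Sustained-phase length before the stop cue, s.
#' @param zero_release_max Zero-force spans strictly longer than this (s) are
#'   removed; a span of exactly this length is retained.
#' @param min_sustained Minimum retained sustained duration, s (exactly this
#'   much is valid; "less than" is excluded).
#' @param rate_threshold_fraction Offset rule: rate below this fraction of the
#'   peak rate of force increase.
#' @param force_band Offset rule: force within this band around the
#'   sustained-phase mean.
#' @param zero_force_epsilon Forces below this (N) count as zero.
#' @return Object of class `grip_config`.
#' @export
grip_config <- function(filter_order = 4, filter_cutoff = 15,
                        sustained_window = 12, zero_release_max = 1,
                        min_sustained = 8, rate_threshold_fraction = 0.05,
                        force_band = c(0.90, 1.10),
                        zero_force_epsilon = 0.0016) {
  stopifnot(rate_threshold_fraction > 0, rate_threshold_fraction < 1,
            force_band[1] < 1, force_band[2] > 1,
            min_sustained > 0, min_sustained <= sustained_window,
            zero_force_epsilon >= 0)
  structure(as.list(environment()), class = "grip_config")
}

.check_uniform <- function(time, tol = 1e-6) {
  dt <- diff(time)
  if (max(abs(dt - stats::median(dt))) > tol * stats::median(dt) + 1e-12) {
    stop("non-uniform sampling beyond tolerance")
  }
  1 / stats::median(dt)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters the force trace with an order-`filter_order` Butterworth low-pass
#' at `filter_cutoff` Hz, applied forward and backward (two passes) so that
#' the result is phase-free and the rise onset is not delayed. The two-pass
#' magnitude response is the squared one-pass response, so attenuation at the
#' cutoff is 1/2 rather than 1/sqrt(2). DC is preserved exactly.
#'
#' @param series A [force_trial()].
#' @param config A [grip_config()].
#' @return The series with filtered force (timestamps unchanged).
#' @export
lowpass_filter <- function(series, config = grip_config()) {
  stopifnot(inherits(series, "force_trial"))
  fs <- .check_uniform(series$data$time)
  if (config$filter_cutoff >= fs / 2) {
    stop("filter cutoff must be below the Nyquist frequency")
  }
  bf <- signal::butter(config$filter_order, config$filter_cutoff / (fs / 2))
  x <- series$data$force
  n <- length(x)
  # odd-reflection padding so the forward/backward startup transients decay
  # inside the pad instead of corrupting the trace ends
  k <- min(n - 1, 10 * ceiling(fs / config$filter_cutoff))
  xp <- c(2 * x[1] - x[(k + 1):2], x, 2 * x[n] - x[(n - 1):(n - k)])
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  series$data$force <- y[(k + 1):(k + n)]
  series
}

#' Maximum voluntary contraction from three maximal trials
#'
#' MVC is the arithmetic mean of the per-trial force maxima over exactly
#' three maximal-effort trials for one hand.
#'
#' @param trials List of exactly 3 [force_trial()]s.
#' @param hand Hand label used in error messages (taken from the trials when
#'   not supplied).
#' @return List with `mvc` (N) and `trial_maxima` (the 3 per-trial maxima).
#' @export
compute_mvc <- function(trials, hand = NULL) {
  if (is.null(hand)) {
    hands <- unique(stats::na.omit(vapply(trials, `[[`, "", "hand")))
    hand <- if (length(hands) == 1) hands else "unknown"
  }
  if (length(trials) != 3) {
    stop(sprintf("MVC for the %s hand requires exactly 3 trials (got %d)",
                 hand, length(trials)))
  }
  maxima <- vapply(trials, function(tr) max(tr$data$force), 0)
  list(mvc = mean(maxima), trial_maxima = maxima, hand = hand)
}

#' Locate the offset of the initial force rise
#'
#' The rise offset is the earliest time point, at or after the peak rate of
#' force increase, where (a) the rate of force increase has fallen below
#' `rate_threshold_fraction` of its peak and (b) force lies within
#' `force_band` of the sustained-phase mean. The rate is the central-difference
#' first derivative of the (filtered) trace. Because the sustained-phase mean
#' itself depends on where the rise ends, it is resolved iteratively: it is
#' initialized from the full pre-cue window, the offset is located, the mean
#' is recomputed from the post-offset window, and the offset is located once
#' more.
#'
#' @param series A (filtered) [force_trial()].
#' @param config A [grip_config()].
#' @return List with `offset_time` (s) and `sustained_mean` (N), or `NULL`
#'   when no sample satisfies both criteria (a `no_onset` exclusion).
#' @export
locate_rise_offset <- function(series, config = grip_config()) {
  stopifnot(inherits(series, "force_trial"))
  f <- series$data$force
  t <- series$data$time
  n <- length(f)
  dt <- stats::median(diff(t))
  cue <- series$stop_cue_time
  rate <- c(f[2] - f[1],
            (f[3:n] - f[1:(n - 2)]) / 2,
            f[n] - f[n - 1]) / dt
  win <- t >= cue - config$sustained_window & t < cue
  if (!any(win)) return(NULL)
  # the sustained-phase mean excludes released (zero-force) samples, which
  # are excluded from the sustained phase by definition
  held <- f >= config$zero_force_epsilon
  m <- mean(f[win & held])
  res <- NULL
  for (iter in 1:2) {
    if (!is.finite(m) || m <= 0) return(NULL)
    in_band <- f >= config$force_band[1] * m &
      f <= config$force_band[2] * m
    first_band <- which(in_band)[1]
    if (is.na(first_band)) return(NULL)
    # the peak rate of the *initial* force increase: restrict the search to
    # the epoch before force first reaches the sustained band, so later
    # re-grips after a release are not mistaken for the initial rise
    peak_i <- which.max(rate[seq_len(first_band)])
    peak <- rate[peak_i]
    if (!is.finite(peak) || peak <= 0) return(NULL)
    ok <- seq_len(n) >= peak_i &
      rate < config$rate_threshold_fraction * peak & in_band
    i0 <- which(ok)[1]
    if (is.na(i0)) return(NULL)
    res <- list(offset_time = t[i0], sustained_mean = m)
    m2 <- mean(f[win & held & t >= t[i0]])
    if (is.finite(m2) && m2 > 0) m <- m2
  }
  res$sustained_mean <- m
  res
}

#' Extract the sustained phase of a grip trial
#'
#' The sustained phase is the intersection of the `sustained_window` seconds
#' preceding the stop cue with the post-rise-offset portion of the trace,
#' minus any zero-force span (force below `zero_force_epsilon`) strictly
#' longer than `zero_release_max` seconds. The trial is valid when the
#' retained duration is at least `min_sustained` seconds; invalidity is a
#' scored outcome, not an error.
#'
#' @param series A (filtered) [force_trial()].
#' @param offset_time Rise-offset time from [locate_rise_offset()], or `NULL`.
#' @param config A [grip_config()].
#' @return List with `time`, `force` (retained samples), `retained_duration`
#'   (s), `valid` and `exclusion_reason`.
#' @export
extract_sustained <- function(series, offset_time, config = grip_config()) {
  stopifnot(inherits(series, "force_trial"))
  if (is.null(offset_time) || is.na(offset_time)) {
    return(list(time = numeric(0), force = numeric(0),
                retained_duration = 0, valid = FALSE,
                exclusion_reason = "no_onset"))
  }
  t <- series$data$time
  f <- series$data$force
  fs <- 1 / stats::median(diff(t))
  if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)
  cue <- series$stop_cue_time
  keep <- t >= cue - config$sustained_window & t < cue & t >= offset_time
  tt <- t[keep]
  ff <- f[keep]
  zero <- ff < config$zero_force_epsilon
  if (any(zero)) {
    r <- rle(zero)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    drop <- logical(length(ff))
    for (k in seq_along(r$lengths)) {
      # strictly "greater than": a span of exactly the limit is retained
      if (r$values[k] &&
          r$lengths[k] / fs > config$zero_release_max + 1e-9) {
        drop[starts[k]:ends[k]] <- TRUE
      }
    }
    tt <- tt[!drop]
    ff <- ff[!drop]
  }
  retained <- length(ff) / fs
  # "less than" is excluded: exactly the minimum is valid
  valid <- retained >= config$min_sustained - 1e-9
  list(time = tt, force = ff, retained_duration = retained, valid = valid,
       exclusion_reason = if (valid) "none" else "short_sustained")
}

#' Coefficient of variation of a sustained segment
#'
#' CoV is the sample standard deviation of the retained sustained force
#' divided by its mean; `log_cov` is the natural log of the CoV (the scale on
#' which force variability is analyzed).
#'
#' @param force Retained sustained-phase force samples, N.
#' @return List with `mean`, `sd`, `cov`, `log_cov`, `valid`.
#' @export
compute_cov <- function(force) {
  m <- mean(force)
  if (!is.finite(m) || m <= 0) {
    return(list(mean = m, sd = NA_real_, cov = NA_real_,
                log_cov = NA_real_, valid = FALSE))
  }
  s <- stats::sd(force)
  cv <- s / m
  list(mean = m, sd = s, cov = cv,
       log_cov = if (cv > 0) log(cv) else NA_real_, valid = TRUE)
}

#' Score one precision-grip trial
#'
#' Full per-trial pipeline: zero-phase low-pass filtering, rise-offset
#' location, sustained-phase extraction with release exclusion, and CoV
#' computation.
#'
#' @param series A raw [force_trial()].
#' @param config A [grip_config()].
#' @param filter Set `FALSE` if the trace is already filtered.
#' @return One-row data.frame with ids, `valid`, `exclusion_reason`,
#'   `onset_offset_time`, `retained_duration`, `sustained_mean`,
#'   `sustained_sd`, `cov`, `log_cov`.
#' @export
score_grip_trial <- function(series, config = grip_config(), filter = TRUE) {
  stopifnot(inherits(series, "force_trial"))
  if (filter) series <- lowpass_filter(series, config)
  off <- locate_rise_offset(series, config)
  seg <- extract_sustained(series, off$offset_time, config)
  res <- data.frame(participant_id = series$participant_id,
                    trial_id = series$trial_id, hand = series$hand,
                    valid = FALSE, exclusion_reason = seg$exclusion_reason,
                    onset_offset_time = if (is.null(off)) NA_real_ else
                      off$offset_time,
                    retained_duration = seg$retained_duration,
                    sustained_mean = NA_real_, sustained_sd = NA_real_,
                    cov = NA_real_, log_cov = NA_real_,
                    stringsAsFactors = FALSE)
  if (seg$valid) {
    cv <- compute_cov(seg$force)
    res$valid <- cv$valid
    res$exclusion_reason <- if (cv$valid) "none" else "other"
    res$sustained_mean <- cv$mean
    res$sustained_sd <- cv$sd
    res$cov <- cv$cov
    res$log_cov <- cv$log_cov
  }
  res
}

#' Score a set of grip trials
#'
#' @param trials List of [force_trial()]s.
#' @param config A [grip_config()].
#' @return data.frame with one row per trial (see [score_grip_trial()]).
#' @export
score_grip_trials <- function(trials, config = grip_config()) {
  do.call(rbind, lapply(trials, score_grip_trial, config = config))
}
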