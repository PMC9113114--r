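#' Write / read force-trial sample files
#'
#' Force trials are stored as delimited text with one row per sample and a
#' `time,force` header (seconds, Newtons). Trial metadata (participant, hand,
#' trial, stop-cue time, file path) lives in a separate manifest CSV.
#'
#' @param series A [force_trial()].
#' @param path Output file.
#' @export
write_force_trial <- function(series, path) {
  stopifnot(inherits(series, "force_trial"))
  utils::write.csv(series$data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_trial
#' @param stop_cue_time,hand,participant_id,trial_id Metadata (from the
#'   trial manifest) attached on read.
#' @export
read_force_trial <- function(path, stop_cue_time = NULL,
                             hand = NA_character_,
                             participant_id = NA_character_,
                             trial_id = NA_integer_) {
  d <- utils::read.csv(path)
  if (!all(c("time", "force") %in% names(d))) {
    stop("expected a time,force sample file: ", path)
  }
  if (is.null(stop_cue_time)) {
    stop_cue_time <- max(d$time) + stats::median(diff(d$time))
  }
  force_trial(d$time, d$force, stop_cue_time = stop_cue_time, hand = hand,
              participant_id = participant_id, trial_id = trial_id)
}

#' Write / read gaze-trial sample files
#'
#' Gaze trials are stored as delimited text with one row per sample and a
#' `time_ms,x,y` header (milliseconds, degrees; empty fields for missing
#' samples). Target metadata lives in the trial manifest.
#'
#' @param series A [gaze_trial()].
#' @param path Output file.
#' @export
write_gaze_trial <- function(series, path) {
  stopifnot(inherits(series, "gaze_trial"))
  utils::write.csv(series$data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_trial
#' @param target_amplitude,target_onset_time,participant_id,trial_id,block
#'   Metadata (from the trial manifest) attached on read.
#' @export
read_gaze_trial <- function(path, target_amplitude, target_onset_time,
                            participant_id = NA_character_,
                            trial_id = NA_integer_, block = NA_integer_) {
  d <- utils::read.csv(path)
  if (!all(c("time_ms", "x", "y") %in% names(d))) {
    stop("expected a time_ms,x,y sample file: ", path)
  }
  gaze_trial(d$time_ms, d$x, d$y, target_amplitude = target_amplitude,
             target_onset_time = target_onset_time,
             participant_id = participant_id, trial_id = trial_id,
             block = block)
}

#' Parse EyeLink ASC sample lines
#'
#' Minimal reader for the EyeLink ASC sample-line dialect (`time xpos ypos
#' pupil ...`, with `.` for missing fields). Positions are converted from
#' screen pixels to degrees of visual angle from the screen center using the
#' viewing geometry.
#'
#' @param path ASC file path.
#' @param screen_width_px,screen_height_px Screen resolution.
#' @param screen_width_cm Physical screen width, cm.
#' @param distance_cm Viewing distance, cm.
#' @return data.frame: `time_ms`, `x`, `y` (degrees), `pupil`.
#' @export
read_asc_samples <- function(path, screen_width_px = 2560,
                             screen_height_px = 1440,
                             screen_width_cm = 59.8, distance_cm = 61) {
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^\\s*\\d+\\s", lines)
  if (!any(keep)) stop("no sample lines found in ", path)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  num <- function(i) {
    vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[i]))
      if (length(v) == 0 || is.na(v)) NA_real_ else v
    }, 0)
  }
  px_per_cm <- screen_width_px / screen_width_cm
  to_deg <- function(px, center) {
    atan2((px - center) / px_per_cm, distance_cm) * 180 / pi
  }
  data.frame(time_ms = num(1),
             x = to_deg(num(2), screen_width_px / 2),
             y = to_deg(num(3), screen_height_px / 2),
             pupil = num(4))
}

#' Write a reproducibility manifest
#'
#' Records the seed and every configuration list of a run as YAML, so a run
#' can be reproduced bit-for-bit.
#'
#' @param config Named list of parameters.
#' @param path Output YAML path.
#' @export
write_manifest <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  yaml::read_yaml(path)
}
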