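#' Grip-outcome coupling configuration
#'
#' Generative model for trial-level force variability on the log scale:
#' `log_cov = intercept + group_shift*ASD + sex_shift*female + hand_shift*left
#'  + age_slope*age_c + volume term + participant effect + trial noise`,
#' where `age_c` is group-mean-centered age and the volume term couples a
#' chosen ROI's (group-centered) volume to log-CoV with an optional per-group
#' slope. Defaults emulate the published pattern qualitatively: a typical
#' sustained-grip CoV around 0.05, elevated force variability in ASD, and
#' lower variability with age.
#'
#' @param intercept TD mean log-CoV.
#' @param group_shift Additive ASD shift on log-CoV.
#' @param sex_shift,hand_shift Additive shifts (female, left hand).
#' @param age_slope Per-year slope on group-centered age.
#' @param volume_roi Canonical ROI name coupled to the outcome (or `NULL`).
#' @param volume_slope Named `c(TD=, ASD=)` slopes per cm^3 of group-centered
#'   volume (a single unnamed value applies to both groups).
#' @param sd_between,sd_within Participant and trial SDs of log-CoV.
#' @param trials_per_hand Trials per hand (the task uses 3).
#' @return Object of class `grip_coupling`.
#' @export
grip_coupling <- function(intercept = log(0.05), group_shift = 0.35,
                          sex_shift = 0, hand_shift = 0,
                          age_slope = -0.025, volume_roi = NULL,
                          volume_slope = c(TD = 0, ASD = 0),
                          sd_between = 0.35, sd_within = 0.15,
                          trials_per_hand = 3) {
  if (length(volume_slope) == 1 && is.null(names(volume_slope))) {
    volume_slope <- c(TD = volume_slope, ASD = volume_slope)
  }
  stopifnot(sd_between >= 0, sd_within >= 0, trials_per_hand >= 1,
            all(c("TD", "ASD") %in% names(volume_slope)))
  structure(as.list(environment()), class = "grip_coupling")
}

.volume_term <- function(coupling, participants, volumes) {
  if (is.null(coupling$volume_roi)) return(list(term = 0, volume = NULL))
  stopifnot(!is.null(volumes))
  v <- volumes[[coupling$volume_roi]][
    match(participants$participant_id, volumes$participant_id)]
  v_c <- v - mean(v)
  grp <- as.character(participants$group)
  list(term = unname(coupling$volume_slope[grp]) * v_c, volume = v)
}

#' Generate trial-level grip outcomes
#'
#' Draws per-trial true log-CoV values (and the implied CoV) for every
#' participant, under a [grip_coupling()]. These are the latent trial
#' variabilities that the trace generator can turn into full force traces,
#' and that the association stage should recover when fed directly.
#'
#' @param participants Cohort from [generate_cohort()].
#' @param volumes Optional volume table (required when the coupling names a
#'   `volume_roi`).
#' @param coupling A [grip_coupling()].
#' @param seed Integer seed.
#' @return data.frame: `participant_id`, `group`, `sex`, `age`, `hand`,
#'   `trial`, `volume` (when coupled), `log_cov_true`, `cov_true`.
#' @export
generate_grip_outcomes <- function(participants, volumes = NULL,
                                   coupling = grip_coupling(), seed = 1L) {
  stopifnot(inherits(coupling, "grip_coupling"))
  set.seed(seed)
  n <- nrow(participants)
  grp <- as.character(participants$group)
  age_c <- participants$age - stats::ave(participants$age, grp, FUN = mean)
  vt <- .volume_term(coupling, participants, volumes)
  latent <- coupling$intercept +
    coupling$group_shift * (grp == "ASD") +
    coupling$sex_shift * (participants$sex == "female") +
    coupling$age_slope * age_c + vt$term +
    stats::rnorm(n, sd = coupling$sd_between)
  k <- coupling$trials_per_hand
  idx <- rep(seq_len(n), each = 2 * k)
  hand <- rep(rep(c("left", "right"), each = k), n)
  out <- data.frame(participant_id = participants$participant_id[idx],
                    group = participants$group[idx],
                    sex = participants$sex[idx],
                    age = participants$age[idx],
                    hand = factor(hand, levels = c("left", "right")),
                    trial = rep(seq_len(k), 2 * n),
                    stringsAsFactors = FALSE)
  if (!is.null(vt$volume)) out$volume <- vt$volume[idx]
  out$log_cov_true <- latent[idx] +
    coupling$hand_shift * (out$hand == "left") +
    stats::rnorm(nrow(out), sd = coupling$sd_within)
  out$cov_true <- exp(out$log_cov_true)
  # duplicate under the scored-outcome name so the table can feed the
  # association stage directly (bypassing trace simulation)
  out$log_cov <- out$log_cov_true
  out
}

#' Saccade-outcome coupling configuration
#'
#' Generative model for trial-level saccade error (degrees):
#' `error = b0 + amplitude_shift*(24 deg) + direction_shift*left +
#'  group_shift*ASD + age_slope*age_c + volume term + participant effect +
#'  trial noise`, truncated at zero. The volume term uses group-centered ROI
#' volume with per-group slopes, which is how a coupling present in TD
#' controls but absent in ASD is expressed.
#'
#' @param b0 Baseline mean error at 12 degrees, rightward, TD.
#' @param amplitude_shift Added error for 24-degree targets.
#' @param direction_shift Added error for leftward targets.
#' @param group_shift Additive ASD shift.
#' @param age_slope Per-year slope on group-centered age.
#' @param volume_roi,volume_slope As in [grip_coupling()].
#' @param sd_between,sd_within Participant and trial error SDs.
#' @param trials_per_cell Trials per amplitude-by-direction cell (15 in the
#'   60-trial task).
#' @return Object of class `saccade_coupling`.
#' @export
saccade_coupling <- function(b0 = 1.0, amplitude_shift = 0.8,
                             direction_shift = 0.1, group_shift = 0,
                             age_slope = -0.01, volume_roi = NULL,
                             volume_slope = c(TD = 0, ASD = 0),
                             sd_between = 0.3, sd_within = 0.4,
                             trials_per_cell = 15) {
  if (length(volume_slope) == 1 && is.null(names(volume_slope))) {
    volume_slope <- c(TD = volume_slope, ASD = volume_slope)
  }
  stopifnot(sd_between >= 0, sd_within >= 0, trials_per_cell >= 1,
            all(c("TD", "ASD") %in% names(volume_slope)))
  structure(as.list(environment()), class = "saccade_coupling")
}

#' Generate trial-level saccade outcomes
#'
#' Draws per-trial saccade errors for every participant across the four
#' amplitude-by-direction cells, under a [saccade_coupling()].
#'
#' @inheritParams generate_grip_outcomes
#' @param coupling A [saccade_coupling()].
#' @return data.frame: ids and covariates plus `amplitude` (factor 12/24),
#'   `direction` (factor right/left), `trial`, `volume` (when coupled),
#'   `error`.
#' @export
generate_saccade_outcomes <- function(participants, volumes = NULL,
                                      coupling = saccade_coupling(),
                                      seed = 1L) {
  stopifnot(inherits(coupling, "saccade_coupling"))
  set.seed(seed)
  n <- nrow(participants)
  grp <- as.character(participants$group)
  age_c <- participants$age - stats::ave(participants$age, grp, FUN = mean)
  vt <- .volume_term(coupling, participants, volumes)
  latent <- coupling$b0 +
    coupling$group_shift * (grp == "ASD") +
    coupling$age_slope * age_c + vt$term +
    stats::rnorm(n, sd = coupling$sd_between)
  k <- coupling$trials_per_cell
  cells <- expand.grid(amplitude = c(12, 24),
                       direction = c("right", "left"),
                       trial = seq_len(k), stringsAsFactors = FALSE)
  m <- nrow(cells)
  idx <- rep(seq_len(n), each = m)
  out <- data.frame(participant_id = participants$participant_id[idx],
                    group = participants$group[idx],
                    sex = participants$sex[idx],
                    age = participants$age[idx],
                    amplitude = factor(cells$amplitude[rep(seq_len(m), n)],
                                       levels = c(12, 24)),
                    direction = factor(cells$direction[rep(seq_len(m), n)],
                                       levels = c("right", "left")),
                    trial = cells$trial[rep(seq_len(m), n)],
                    stringsAsFactors = FALSE)
  if (!is.null(vt$volume)) out$volume <- vt$volume[idx]
  out$error <- pmax(0,
                    latent[idx] +
                      coupling$amplitude_shift * (out$amplitude == "24") +
                      coupling$direction_shift * (out$direction == "left") +
                      stats::rnorm(nrow(out), sd = coupling$sd_within))
  out
}
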