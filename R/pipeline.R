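#' Study configuration
#'
#' Bundles every stage's configuration for an end-to-end synthetic study
#' run: cohort, volume effects, behavioral couplings, scoring configs, and
#' whether behavior is simulated at the trace level (full force/gaze traces
#' scored by the scoring pipelines) or taken directly from the trial-level
#' outcome generators.
#'
#' @param cohort A [cohort_config()].
#' @param volume_effects A [volume_effects_config()].
#' @param grip A [grip_coupling()].
#' @param saccade A [saccade_coupling()].
#' @param grip_scoring A [grip_config()].
#' @param saccade_scoring A [saccade_config()].
#' @param simulate_traces Generate and score raw traces (slower, exercises
#'   the whole pipeline) instead of using trial-level outcomes directly.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_config(),
                         volume_effects = volume_effects_config(),
                         grip = grip_coupling(),
                         saccade = saccade_coupling(),
                         grip_scoring = grip_config(),
                         saccade_scoring = saccade_config(),
                         simulate_traces = TRUE, seed = 1L) {
  structure(list(cohort = cohort, volume_effects = volume_effects,
                 grip = grip, saccade = saccade,
                 grip_scoring = grip_scoring,
                 saccade_scoring = saccade_scoring,
                 simulate_traces = simulate_traces,
                 seed = as.integer(seed)),
            class = "study_config")
}

.stage_seed <- function(seed, k) (seed * 7L + k * 104729L) %% 2147483647L

.simulate_grip_traces <- function(outcomes, cohort, config) {
  res <- NULL
  seeds <- .stage_seed(config$seed, 11L) + seq_len(nrow(outcomes))
  for (i in seq_len(nrow(outcomes))) {
    o <- outcomes[i, ]
    mvc <- cohort[[paste0("mvc_", o$hand)]][
      match(o$participant_id, cohort$participant_id)]
    spec <- force_trial_spec(mvc = mvc, latent_cov = o$cov_true)
    tr <- generate_force_trial(spec, seed = seeds[i] %% 2147483647L,
                               hand = as.character(o$hand),
                               participant_id = o$participant_id,
                               trial_id = o$trial)
    res <- rbind(res, score_grip_trial(tr, config$grip_scoring))
  }
  res
}

.simulate_saccade_sessions <- function(participants, coupling, config) {
  scores <- NULL
  for (i in seq_len(nrow(participants))) {
    pid <- participants$participant_id[i]
    sess <- generate_saccade_session(
      participant_id = pid,
      n_trials = coupling$trials_per_cell * 4,
      seed = (.stage_seed(config$seed, 13L) + i) %% 2147483647L)
    scores <- rbind(scores,
                    score_saccade_trials(sess$trials,
                                         config$saccade_scoring))
  }
  scores
}

#' Run an end-to-end synthetic study
#'
#' Generation, scoring, association, and reporting in one call: draws a
#' cohort and ROI volume table, simulates grip and saccade behavior (at the
#' trace level by default, scored by the scoring pipelines), fits the
#' group-difference and brain-behavior model families with interaction
#' pruning and BH correction, and (optionally) writes all stage artifacts —
#' tidy CSVs, a plain-text report and a YAML manifest — to `output_dir`.
#' Identical config and seed reproduce every artifact byte-for-byte.
#'
#' @param config A [study_config()].
#' @param output_dir Directory for artifacts (created if needed), or `NULL`
#'   to skip writing.
#' @return List: `cohort`, `volumes`, `grip_results`, `saccade_scores`,
#'   `condition_summaries`, `behavior_groups`, `volume_groups`,
#'   `brain_behavior`, `clinical`, `report` (character lines).
#' @export
run_study <- function(config = study_config(), output_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  cohort <- generate_cohort(config$cohort,
                            seed = .stage_seed(config$seed, 1L))
  volumes <- generate_volume_table(cohort, config$volume_effects,
                                   seed = .stage_seed(config$seed, 2L))
  grip_out <- generate_grip_outcomes(cohort, volumes, config$grip,
                                     seed = .stage_seed(config$seed, 3L))
  if (config$simulate_traces) {
    grip_results <- .simulate_grip_traces(grip_out, cohort, config)
    grip_results$hand <- factor(grip_results$hand,
                                levels = c("left", "right"))
    sac_scores <- .simulate_saccade_sessions(cohort, config$saccade,
                                             config)
  } else {
    grip_results <- grip_out
    grip_results$valid <- TRUE
    grip_results$cov <- grip_results$cov_true
    grip_results$log_cov <- grip_results$log_cov_true
    sac_out <- generate_saccade_outcomes(
      cohort, volumes, config$saccade,
      seed = .stage_seed(config$seed, 4L))
    sac_scores <- sac_out
    sac_scores$valid <- TRUE
    sac_scores$amplitude <- as.numeric(as.character(sac_scores$amplitude))
    sac_scores$direction <- as.character(sac_scores$direction)
  }
  summaries <- summarize_conditions(sac_scores[sac_scores$valid, ])
  grip_valid <- grip_results[grip_results$valid, ]
  sac_trials <- sac_scores[sac_scores$valid, ]
  sac_trials$amplitude <- factor(sac_trials$amplitude,
                                 levels = c(12, 24))
  sac_trials$direction <- factor(sac_trials$direction,
                                 levels = c("right", "left"))
  sac_cells <- summaries[summaries$sd_defined, ]
  sac_cells$amplitude <- factor(sac_cells$amplitude, levels = c(12, 24))
  sac_cells$direction <- factor(sac_cells$direction,
                                levels = c("right", "left"))
  both_arms <- all(c("TD", "ASD") %in% as.character(unique(cohort$group)))
  behavior_groups <- NULL
  volume_groups <- NULL
  brain_behavior <- NULL
  if (both_arms) { # group-contrast models need both arms
    behavior_groups <- analyze_behavior_groups(
      grip = grip_valid, saccade = sac_trials, saccade_sd = sac_cells,
      cohort = cohort)
    volume_groups <- analyze_volume_groups(volumes, cohort)
    brain_behavior <- list(
      grip = analyze_brain_behavior(grip_valid, volumes, cohort, "grip"),
      saccade_error = analyze_brain_behavior(sac_trials, volumes, cohort,
                                             "saccade-error"))
  }
  clinical <- NULL
  if (any(cohort$group == "ASD" & !is.na(cohort$ados_css))) {
    clinical <- list(
      ados_css = analyze_brain_clinical(volumes, cohort, "ados_css"),
      rbsr_total = analyze_brain_clinical(volumes, cohort, "rbsr_total"))
  }
  results <- list(cohort = cohort, volumes = volumes,
                  grip_results = grip_results,
                  saccade_scores = sac_scores,
                  condition_summaries = summaries,
                  behavior_groups = behavior_groups,
                  volume_groups = volume_groups,
                  brain_behavior = brain_behavior, clinical = clinical,
                  config = config)
  results$report <- write_report(results)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      utils::write.csv(x, file.path(output_dir, name), row.names = FALSE)
    }
    wr(cohort, "cohort.csv")
    wr(volumes, "volumes.csv")
    wr(grip_results, "grip_results.csv")
    wr(sac_scores, "saccade_scores.csv")
    wr(summaries, "condition_summaries.csv")
    if (!is.null(volume_groups)) {
      wr(volume_groups$lateral$results, "volume_group_lateral.csv")
      wr(volume_groups$midline$results, "volume_group_midline.csv")
    }
    if (!is.null(brain_behavior)) {
      wr(brain_behavior$grip$results, "brain_behavior_grip.csv")
      wr(brain_behavior$saccade_error$results,
         "brain_behavior_saccade_error.csv")
    }
    writeLines(results$report, file.path(output_dir, "report.txt"))
    write_manifest(list(seed = config$seed,
                        n_asd = config$cohort$n_asd,
                        n_td = config$cohort$n_td,
                        simulate_traces = config$simulate_traces),
                   file.path(output_dir, "manifest.yaml"))
  }
  invisible(results)
}

.msd <- function(x) sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE),
                            stats::sd(x, na.rm = TRUE))

.fmt_family <- function(fr) {
  r <- fr$results
  c(sprintf("  %-22s %-13s F(%g, %.2f) = %8.3f  p = %.4f%s",
            r$member, r$term, r$df1, r$df2, r$F, r$p,
            ifelse(r$significant & !r$exploratory, " *", "")),
    if (!r$exploratory[1] && is.finite(r$p_crit[1])) {
      sprintf("  [BH at q = %.2f: p_crit = %.4f]", fr$bh$q, r$p_crit[1])
    } else if (r$exploratory[1]) {
      "  [exploratory: uncorrected]"
    })
}

#' Write the study report
#'
#' Formats the cohort-characteristics table, the per-ROI volume table
#' (mean (SD) by group and hemisphere), and the association family tables as
#' plain text. Clinical sections are omitted with a notice when the cohort
#' has no ASD arm.
#'
#' @param results A [run_study()] result list.
#' @param path Optional file to write the lines to.
#' @return Character vector of report lines, invisibly.
#' @export
write_report <- function(results, path = NULL) {
  cohort <- results$cohort
  volumes <- results$volumes
  lines <- c("Cerebellar volumetrics and sensorimotor behavior: study report",
             "", "== Cohort characteristics ==")
  for (g in levels(cohort$group)) {
    cg <- cohort[cohort$group == g, ]
    if (nrow(cg) == 0) next
    lines <- c(lines, sprintf(
      "%s: n = %d (%d F), age %s, left MVC %s, right MVC %s",
      g, nrow(cg), sum(cg$sex == "female"), .msd(cg$age),
      .msd(cg$mvc_left), .msd(cg$mvc_right)))
  }
  asd <- cohort[cohort$group == "ASD", ]
  if (nrow(asd) > 0) {
    lines <- c(lines, sprintf("ASD clinical: ADOS CSS %s, RBS-R total %s",
                              .msd(asd$ados_css), .msd(asd$rbsr_total)))
  }
  lines <- c(lines, "", "== ROI volumes, cm^3, mean (SD) by group ==")
  for (roi in cerebellar_rois()) {
    cells <- vapply(levels(cohort$group), function(g) {
      idx <- cohort$group[match(volumes$participant_id,
                                cohort$participant_id)] == g
      if (!any(idx)) "-" else .msd(volumes[[roi]][idx])
    }, "")
    lines <- c(lines, sprintf("  %-22s TD %s   ASD %s", roi,
                              cells["TD"], cells["ASD"]))
  }
  fmt_fit <- function(label, fit) {
    tt <- fit$terms
    c(sprintf("-- %s --", label),
      sprintf("  %-28s F(%g, %.2f) = %8.3f  p = %.4f", tt$term, tt$df1,
              tt$df2, tt$F, tt$p))
  }
  if (!is.null(results$behavior_groups)) {
    lines <- c(lines, "", "== Group differences in behavior ==")
    for (nm in names(results$behavior_groups)) {
      lines <- c(lines, fmt_fit(nm, results$behavior_groups[[nm]]))
    }
  }
  if (!is.null(results$volume_groups)) {
    lines <- c(lines, "", "== Group differences in ROI volumes ==",
               "Lateralized ROIs (group term):",
               .fmt_family(results$volume_groups$lateral),
               "Midline ROIs (group term):",
               .fmt_family(results$volume_groups$midline))
  }
  if (!is.null(results$brain_behavior)) {
    lines <- c(lines, "", "== Brain-behavior associations ==",
               "Grip force variability (volume term):",
               .fmt_family(results$brain_behavior$grip),
               "Saccade error (volume term):",
               .fmt_family(results$brain_behavior$saccade_error))
  }
  if (!is.null(results$clinical)) {
    lines <- c(lines, "", "== Clinical associations (ASD arm) ==")
    for (nm in names(results$clinical)) {
      lines <- c(lines, sprintf("%s (volume term, exploratory):", nm),
                 .fmt_family(results$clinical[[nm]]$lateral),
                 .fmt_family(results$clinical[[nm]]$midline))
    }
  } else {
    lines <- c(lines, "",
               "[clinical sections omitted: no ASD participants]")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
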