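#' Reshape a volume table to long format for one lateralized ROI pair
#'
#' @param volumes Volume table (canonical schema).
#' @param cohort Cohort table (provides group, sex, age).
#' @param roi_pair Base pair name, e.g. `"crus_II_VIIB"`.
#' @return Long data.frame: one row per participant x hemisphere with
#'   `volume`, `hemisphere` (factor left/right) and cohort covariates
#'   including `age_c`.
#' @export
volumes_to_long <- function(volumes, cohort, roi_pair) {
  stopifnot(roi_pair %in% cerebellar_rois("pairs"))
  j <- match(volumes$participant_id, cohort$participant_id)
  base <- data.frame(participant_id = volumes$participant_id,
                     group = cohort$group[j], sex = cohort$sex[j],
                     age = cohort$age[j], stringsAsFactors = FALSE)
  out <- rbind(
    cbind(base, hemisphere = "left",
          volume = volumes[[paste0("left_", roi_pair)]]),
    cbind(base, hemisphere = "right",
          volume = volumes[[paste0("right_", roi_pair)]]))
  out$hemisphere <- factor(out$hemisphere, levels = c("left", "right"))
  center_age(out)
}

.join_cohort <- function(data, cohort,
                         cols = c("group", "sex", "age")) {
  j <- match(data$participant_id, cohort$participant_id)
  if (anyNA(j)) {
    stop("participants missing from the cohort table: ",
         paste(unique(data$participant_id[is.na(j)]), collapse = ", "))
  }
  for (cl in cols) if (!cl %in% names(data)) data[[cl]] <- cohort[[cl]][j]
  center_age(data)
}

.join_volume <- function(data, volumes, roi) {
  stopifnot(roi %in% names(volumes))
  j <- match(data$participant_id, volumes$participant_id)
  if (anyNA(j)) {
    stop("participants missing from the volume table: ",
         paste(unique(data$participant_id[is.na(j)]), collapse = ", "))
  }
  data$volume <- volumes[[roi]][j]
  data
}

#' Run a family of ROI models
#'
#' Fits one (pruned) association model per ROI, collects each model's focal
#' term p-value, and — for confirmatory families — applies Benjamini-Hochberg
#' FDR control across the family's models; exploratory families are returned
#' uncorrected and flagged.
#'
#' @param family Analysis family id (see [build_model_spec()]).
#' @param data_list Named list of long data.frames, one per member model
#'   (names are the member/ROI labels).
#' @param outcome Outcome column (defaults per family).
#' @param focal_term Term(s) whose p-values enter the BH family (default
#'   `"group"` for group-difference families, `"volume"` for association
#'   families, and the two hemispheric volume terms for lateralized clinical
#'   regressions).
#' @param correct Apply BH correction (`FALSE` marks the family exploratory).
#' @param q False-discovery rate.
#' @param prune Iteratively prune interactions before reporting.
#' @return List of class `family_result`: `results` (per-member focal-term
#'   table with BH decision), `terms` (all per-term F tests), `fits`, `bh`.
#' @export
run_family <- function(family, data_list, outcome = NULL,
                       focal_term = NULL, correct = TRUE, q = 0.05,
                       prune = TRUE) {
  stopifnot(length(data_list) > 0, !is.null(names(data_list)))
  focal_term <- focal_term %||%
    if (family == "brain-clinical-lateral") {
      c("volume_left", "volume_right")
    } else if (grepl("^brain-", family)) "volume" else "group"
  fits <- lapply(names(data_list), function(member) {
    spec <- build_model_spec(
      family, outcome = outcome,
      roi = if (member %in% c(cerebellar_rois(),
                              cerebellar_rois("pairs"))) member)
    data <- data_list[[member]]
    if (prune) {
      prune_interactions(spec, data)
    } else {
      fit_association(spec, data)
    }
  })
  names(fits) <- names(data_list)
  terms_all <- do.call(rbind, lapply(names(fits), function(m) {
    cbind(member = m, fits[[m]]$terms)
  }))
  results <- do.call(rbind, lapply(names(fits), function(m) {
    tt <- fits[[m]]$terms
    do.call(rbind, lapply(focal_term, function(term) {
      i <- match(term, tt$term)
      data.frame(member = m, term = term,
                 F = if (is.na(i)) NA_real_ else tt$F[i],
                 df1 = if (is.na(i)) NA_real_ else tt$df1[i],
                 df2 = if (is.na(i)) NA_real_ else tt$df2[i],
                 p = if (is.na(i)) NA_real_ else tt$p[i],
                 stringsAsFactors = FALSE)
    }))
  }))
  bh <- NULL
  if (correct && all(is.finite(results$p))) {
    bh <- bh_adjust(results$p, q)
    results$significant <- bh$reject
    results$p_crit <- bh$p_crit
    results$exploratory <- FALSE
  } else {
    results$significant <- results$p < 0.05
    results$exploratory <- TRUE
  }
  structure(list(family = family, focal_term = focal_term,
                 results = results, terms = terms_all, fits = fits,
                 bh = bh, correct = correct),
            class = "family_result")
}

#' @export
print.family_result <- function(x, ...) {
  cat("Family:", x$family,
      if (x$correct) "(BH-corrected)" else "(exploratory)", "\n")
  print(x$results, digits = 4)
  invisible(x)
}

#' Group differences in cerebellar volumes
#'
#' Runs the lateralized volume family (7 ROI pairs, hemisphere as level-1
#' predictor) and the midline family (3 vermal composites + white matter,
#' ordinary regression) and corrects each family's group-term p-values by BH.
#'
#' @param volumes Volume table.
#' @param cohort Cohort table.
#' @param q False-discovery rate.
#' @return List with `lateral` and `midline` [run_family()] results.
#' @export
analyze_volume_groups <- function(volumes, cohort, q = 0.05) {
  lat <- lapply(stats::setNames(nm = cerebellar_rois("pairs")),
                function(r) volumes_to_long(volumes, cohort, r))
  mid <- lapply(stats::setNames(nm = cerebellar_rois("midline")),
                function(r) {
                  d <- data.frame(participant_id = volumes$participant_id,
                                  volume = volumes[[r]],
                                  stringsAsFactors = FALSE)
                  .join_cohort(d, cohort)
                })
  list(lateral = run_family("volume-group-lateral", lat, q = q),
       midline = run_family("volume-group-midline", mid, q = q))
}

#' Brain-behavior association families
#'
#' Associates ROI volumes with grip force variability (`log_cov`), saccade
#' error, or saccade error variability. The confirmatory (BH-corrected)
#' ROI set defaults to the behavior's primary regions — the six hemispheric
#' skeletomotor ROIs (left/right lobules I-V, lobule VI, Crus I) for grip,
#' and the oculomotor vermis (vermal VI-VII) for saccade error — while all
#' remaining ROIs can be analyzed as an exploratory (uncorrected) family.
#'
#' @param behavior Trial-level behavior table (from the scoring modules or
#'   the outcome generators): grip needs `participant_id`, `hand`,
#'   `log_cov`; saccade error needs `participant_id`, `amplitude`,
#'   `direction`, `error` (or `error_sd` at the cell level).
#' @param volumes Volume table.
#' @param cohort Cohort table.
#' @param behavior_type `"grip"`, `"saccade-error"` or `"saccade-sd"`.
#' @param rois ROI volume columns to analyze (defaults to the behavior's
#'   primary set).
#' @param correct BH-correct the family (set `FALSE` for exploratory sets).
#' @param q False-discovery rate.
#' @param prune Prune interactions.
#' @return A [run_family()] result.
#' @export
analyze_brain_behavior <- function(behavior, volumes, cohort,
                                   behavior_type = c("grip",
                                                     "saccade-error",
                                                     "saccade-sd"),
                                   rois = NULL, correct = TRUE, q = 0.05,
                                   prune = TRUE) {
  behavior_type <- match.arg(behavior_type)
  family <- switch(behavior_type,
                   grip = "brain-behavior-grip",
                   `saccade-error` = "brain-behavior-saccade-error",
                   `saccade-sd` = "brain-behavior-saccade-sd")
  if (is.null(rois)) {
    rois <- if (behavior_type == "grip") {
      as.vector(outer(c("left_", "right_"),
                      c("lobules_I_V", "lobule_VI", "crus_I"), paste0))
    } else {
      "vermis_VI_VII"
    }
  }
  behavior <- .join_cohort(behavior, cohort)
  data_list <- lapply(stats::setNames(nm = rois), function(r) {
    .join_volume(behavior, volumes, r)
  })
  run_family(family, data_list, correct = correct, q = q, prune = prune)
}

#' Clinical-severity association families (ASD arm)
#'
#' Associates ROI volumes with ADOS calibrated severity or RBS-R total in the
#' ASD arm only, with sex-by-volume interactions. Homologous ROI pairs enter
#' one regression with separate left- and right-hemisphere volume
#' predictors; midline ROIs get separate single-volume regressions. These
#' analyses are exploratory (uncorrected).
#'
#' @param volumes Volume table.
#' @param cohort Cohort table.
#' @param outcome `"ados_css"` or `"rbsr_total"`.
#' @param prune Prune the sex:volume interaction when uninformative.
#' @return List with `lateral` and `midline` [run_family()] results.
#' @export
analyze_brain_clinical <- function(volumes, cohort,
                                   outcome = c("ados_css", "rbsr_total"),
                                   prune = TRUE) {
  outcome <- match.arg(outcome)
  asd <- cohort[cohort$group == "ASD" & !is.na(cohort[[outcome]]), ]
  if (nrow(asd) == 0) stop("no ASD participants with ", outcome)
  vol_asd <- volumes[volumes$participant_id %in% asd$participant_id, ]
  j <- match(vol_asd$participant_id, asd$participant_id)
  base <- data.frame(participant_id = vol_asd$participant_id,
                     sex = asd$sex[j],
                     stats::setNames(list(asd[[outcome]][j]), outcome),
                     stringsAsFactors = FALSE)
  lat <- lapply(stats::setNames(nm = cerebellar_rois("pairs")),
                function(r) {
                  d <- base
                  d$volume_left <- vol_asd[[paste0("left_", r)]]
                  d$volume_right <- vol_asd[[paste0("right_", r)]]
                  d
                })
  mid <- lapply(stats::setNames(nm = cerebellar_rois("midline")),
                function(r) {
                  d <- base
                  d$volume <- vol_asd[[r]]
                  d
                })
  list(lateral = run_family("brain-clinical-lateral", lat,
                            outcome = outcome, correct = FALSE,
                            prune = prune),
       midline = run_family("brain-clinical-midline", mid,
                            outcome = outcome, correct = FALSE,
                            prune = prune))
}

#' Group differences in sensorimotor behavior
#'
#' Fits the behavior-group models: log force variability with hand as the
#' level-1 predictor, and saccade error / error variability with amplitude
#' and direction as level-1 predictors; group, sex and group-centered age as
#' level-2 predictors throughout.
#'
#' @param grip Trial-level grip table (`participant_id`, `hand`, `log_cov`),
#'   or `NULL` to skip.
#' @param saccade Trial-level saccade table (`participant_id`, `amplitude`,
#'   `direction`, `error`), or `NULL`.
#' @param saccade_sd Cell-level error-variability table (`participant_id`,
#'   `amplitude`, `direction`, `error_sd`), or `NULL`.
#' @param cohort Cohort table.
#' @param prune Prune interactions.
#' @return Named list of [fit_association()] results.
#' @export
analyze_behavior_groups <- function(grip = NULL, saccade = NULL,
                                    saccade_sd = NULL, cohort,
                                    prune = TRUE) {
  fit1 <- function(family, data, outcome = NULL) {
    spec <- build_model_spec(family, outcome = outcome)
    data <- .join_cohort(data, cohort)
    if (prune) prune_interactions(spec, data) else
      fit_association(spec, data)
  }
  out <- list()
  if (!is.null(grip)) {
    out$grip <- fit1("behavior-group-grip", grip)
  }
  if (!is.null(saccade)) {
    out$saccade_error <- fit1("behavior-group-saccade", saccade)
  }
  if (!is.null(saccade_sd)) {
    out$saccade_sd <- fit1("behavior-group-saccade", saccade_sd,
                           outcome = "error_sd")
  }
  out
}
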