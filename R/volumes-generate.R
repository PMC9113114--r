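.lateral_rois <- c("lobules_I_V", "lobule_VI", "crus_I", "crus_II_VIIB",
                   "lobule_VIII", "lobule_IX", "lobule_X")
.midline_rois <- c("vermis_I_V", "vermis_VI_VII", "vermis_VIII_X",
                   "white_matter")

#' Canonical cerebellar ROI names
#'
#' The 18-region schema used throughout the package: 7 left/right lobule pairs
#' (lobules I-V, lobule VI, Crus I, Crus II/lobule VIIB, lobule VIII, lobule
#' IX, lobule X), 3 vermal composites (I-V, VI-VII, VIII-X), and cerebellar
#' white matter. Crus II and lobule VIIB are a single composite ROI, and
#' vermal lobules are grouped, following the reporting convention of
#' cerebellar parcellation pipelines.
#'
#' @param which `"all"` (default), `"lateral"` (14 hemispheric ROIs),
#'   `"midline"` (4), or `"pairs"` (the 7 base names without hemisphere).
#' @return Character vector of ROI column names.
#' @export
cerebellar_rois <- function(which = c("all", "lateral", "midline", "pairs")) {
  which <- match.arg(which)
  lateral <- as.vector(t(outer(c("left_", "right_"), .lateral_rois, paste0)))
  switch(which,
         all = c(lateral, .midline_rois),
         lateral = lateral,
         midline = .midline_rois,
         pairs = .lateral_rois)
}

#' Default per-ROI volume calibration
#'
#' Group- and hemisphere-specific means and SDs (cm^3) for the 18 cerebellar
#' ROIs, taken from published cohort volumetry of 8-30 year-old TD and ASD
#' participants (e.g., TD vermal VI-VII 1.65 (0.20) cm^3, ASD 1.54 (0.18);
#' TD right Crus II/VIIB 14.35 (2.07)). These are the baselines the volume
#' generator draws around.
#'
#' @return data.frame with columns `roi`, `group`, `mean`, `sd`.
#' @export
default_volume_params <- function() {
  lat <- function(group, hemi, means, sds) {
    data.frame(roi = paste0(hemi, "_", .lateral_rois), group = group,
               mean = means, sd = sds, stringsAsFactors = FALSE)
  }
  mid <- function(group, means, sds) {
    data.frame(roi = .midline_rois, group = group, mean = means, sd = sds,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    lat("TD", "left",
        c(6.57, 10.85, 15.53, 15.45, 12.32, 3.72, 0.61),
        c(0.93, 1.44, 1.96, 2.18, 1.74, 0.67, 0.11)),
    lat("TD", "right",
        c(6.47, 10.45, 15.95, 14.35, 12.70, 3.64, 0.60),
        c(0.98, 1.48, 2.04, 2.07, 1.63, 0.67, 0.09)),
    lat("ASD", "left",
        c(6.48, 10.82, 15.85, 15.34, 12.38, 3.71, 0.59),
        c(0.99, 1.18, 2.05, 2.03, 1.51, 0.66, 0.10)),
    lat("ASD", "right",
        c(6.33, 10.68, 15.92, 14.02, 13.21, 3.68, 0.62),
        c(0.93, 1.20, 2.34, 2.34, 1.94, 0.66, 0.09)),
    mid("TD", c(2.53, 1.65, 2.53, 13.49), c(0.30, 0.20, 0.32, 1.41)),
    mid("ASD", c(2.41, 1.54, 2.46, 13.25), c(0.33, 0.18, 0.31, 1.25)))
  rownames(out) <- NULL
  out
}

#' Structured volume-effect configuration
#'
#' Couplings layered on top of the per-ROI baselines: additive sex shift
#' (male minus female), an extra shift for ASD females (mirroring reported
#' sex-dependent group differences in Crus II/lobule VIIB), per-group linear
#' age slopes (around the group age mean, so group means are unchanged), and
#' a global residual-noise scale. All default to "off" so that the generator's
#' large-sample group means equal the printed baselines exactly.
#'
#' @param params Baseline calibration, see [default_volume_params()].
#' @param sex_shift Named numeric (by ROI), cm^3 added for males.
#' @param group_sex_shift Named numeric (by ROI), cm^3 added for ASD females.
#' @param age_slope List with elements `TD` and `ASD`, each a named numeric
#'   of cm^3/year slopes by ROI (age centered within group).
#' @param noise_scale Multiplier on every baseline SD (0 = deterministic).
#' @param hemisphere_cor Correlation between the left and right members of a
#'   paired ROI within participant (shared participant component; marginal
#'   means and SDs are unchanged). Real hemispheric volumes correlate
#'   strongly, and the hemisphere-as-level-1 mixed models rely on a
#'   non-trivial participant random intercept.
#' @param lower_fraction Volumes are redrawn (truncated) below
#'   `lower_fraction * baseline mean`, guaranteeing positivity.
#' @return Object of class `volume_effects`.
#' @export
volume_effects_config <- function(params = default_volume_params(),
                                  sex_shift = NULL, group_sex_shift = NULL,
                                  age_slope = NULL, noise_scale = 1,
                                  hemisphere_cor = 0.8,
                                  lower_fraction = 0.1) {
  stopifnot(all(params$mean > 0), all(params$sd >= 0), noise_scale >= 0,
            hemisphere_cor >= 0, hemisphere_cor < 1,
            lower_fraction >= 0, lower_fraction < 1)
  stopifnot(setequal(unique(params$roi), cerebellar_rois()))
  expand <- function(shift) {
    if (is.null(shift)) return(NULL)
    out <- numeric(0)
    for (nm in names(shift)) {
      if (nm %in% cerebellar_rois("pairs")) {
        out[paste0(c("left_", "right_"), nm)] <- shift[[nm]]
      } else if (nm %in% cerebellar_rois()) {
        out[nm] <- shift[[nm]]
      } else {
        stop("effect names must be canonical ROI (or pair) names: ", nm)
      }
    }
    out
  }
  sex_shift <- expand(sex_shift)
  group_sex_shift <- expand(group_sex_shift)
  if (!is.null(age_slope)) age_slope <- lapply(age_slope, expand)
  structure(list(params = params, sex_shift = sex_shift,
                 group_sex_shift = group_sex_shift, age_slope = age_slope,
                 noise_scale = noise_scale, hemisphere_cor = hemisphere_cor,
                 lower_fraction = lower_fraction),
            class = "volume_effects")
}

.effect_for <- function(shift, roi) {
  if (is.null(shift) || is.na(match(roi, names(shift)))) 0 else shift[[roi]]
}

#' Generate a synthetic ROI volume table
#'
#' Draws one row per participant with all 18 cerebellar ROI volumes in cm^3.
#' Each volume is `baseline(group, roi) + effects + truncated-normal noise`;
#' with `noise_scale = 0` and no effects every volume equals its baseline.
#'
#' @param participants Cohort data.frame from [generate_cohort()]; requires
#'   `participant_id`, `group`, `sex`, `age`.
#' @param effects A [volume_effects_config()].
#' @param seed Integer seed.
#' @return data.frame: `participant_id` plus the 18 columns of
#'   [cerebellar_rois()], all positive.
#' @export
generate_volume_table <- function(participants,
                                  effects = volume_effects_config(),
                                  seed = 1L) {
  stopifnot(inherits(effects, "volume_effects"))
  need <- c("participant_id", "group", "sex", "age")
  missing_f <- setdiff(need, names(participants))
  if (length(missing_f)) {
    stop("participants table is missing fields: ",
         paste(missing_f, collapse = ", "))
  }
  if (nrow(participants) == 0) stop("participants table is empty")
  set.seed(seed)
  grp <- as.character(participants$group)
  age_c <- participants$age -
    stats::ave(participants$age, grp, FUN = mean)
  n <- nrow(participants)
  out <- data.frame(participant_id = participants$participant_id,
                    stringsAsFactors = FALSE)
  par <- effects$params
  roi_mean <- function(roi) {
    p <- par[par$roi == roi, ]
    mu0 <- p$mean[match(grp, p$group)]
    mu <- mu0 +
      .effect_for(effects$sex_shift, roi) *
        (participants$sex == "male") +
      .effect_for(effects$group_sex_shift, roi) *
        (grp == "ASD" & participants$sex == "female")
    for (g in c("TD", "ASD")) {
      sl <- .effect_for(effects$age_slope[[g]], roi)
      if (sl != 0) mu <- mu + sl * age_c * (grp == g)
    }
    list(mu = mu, sd = p$sd[match(grp, p$group)] * effects$noise_scale,
         lb = effects$lower_fraction * mu0)
  }
  draw <- function(roi, z) {
    pm <- roi_mean(roi)
    v <- pm$mu + pm$sd * z
    # positivity guarantee: redraw the (independent part of the) deviate for
    # the rare draw below lower_fraction * baseline
    bad <- which(v < pm$lb & pm$sd > 0)
    tries <- 0
    while (length(bad) && tries < 50) {
      v[bad] <- pm$mu[bad] + pm$sd[bad] * stats::rnorm(length(bad))
      bad <- which(v < pm$lb & pm$sd > 0)
      tries <- tries + 1
    }
    if (length(bad)) v[bad] <- pm$lb[bad]
    v
  }
  rho <- effects$hemisphere_cor
  for (pair in cerebellar_rois("pairs")) {
    z_shared <- stats::rnorm(n)
    for (h in c("left", "right")) {
      z <- sqrt(rho) * z_shared + sqrt(1 - rho) * stats::rnorm(n)
      out[[paste0(h, "_", pair)]] <- draw(paste0(h, "_", pair), z)
    }
  }
  for (roi in cerebellar_rois("midline")) {
    out[[roi]] <- draw(roi, stats::rnorm(n))
  }
  out[, c("participant_id", cerebellar_rois())]
}
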