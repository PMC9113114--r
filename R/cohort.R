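#' Moment-calibrated truncated-normal draws
#'
#' Samples from a normal distribution truncated to `[lower, upper]`, with the
#' parent mean solved numerically so that the *truncated* distribution has the
#' requested mean. This keeps large-sample means of bounded quantities (ages,
#' grip strength, questionnaire totals) on their configured values instead of
#' drifting upward/downward with the truncation.
#'
#' @param n Number of draws.
#' @param mean Target mean of the truncated distribution.
#' @param sd Parent standard deviation (must be >= 0; `sd = 0` returns a
#'   constant).
#' @param lower,upper Truncation bounds.
#' @param calibrate If `FALSE`, `mean` is used as the parent mean directly.
#' @return Numeric vector of length `n`.
#' @export
rtruncnorm_cal <- function(n, mean, sd, lower = -Inf, upper = Inf,
                           calibrate = TRUE) {
  stopifnot(sd >= 0, lower < upper, n >= 0)
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    stopifnot(mean >= lower, mean <= upper)
    return(rep(mean, n))
  }
  mu <- mean
  if (calibrate && (is.finite(lower) || is.finite(upper))) {
    trunc_mean <- function(m) {
      a <- (lower - m) / sd
      b <- (upper - m) / sd
      z <- stats::pnorm(b) - stats::pnorm(a)
      m + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
    }
    mu <- stats::uniroot(function(m) trunc_mean(m) - mean,
                         interval = c(mean - 8 * sd, mean + 8 * sd),
                         tol = 1e-10)$root
  }
  pa <- stats::pnorm((lower - mu) / sd)
  pb <- stats::pnorm((upper - mu) / sd)
  mu + sd * stats::qnorm(stats::runif(n, pa, pb))
}

#' Cohort configuration
#'
#' Parameters of the synthetic cohort: arm sizes, age distributions, sex and
#' handedness ratios, per-hand maximum voluntary contraction (MVC), and
#' clinical scores for the ASD arm. Defaults reproduce the published cohort
#' characteristics of the study this pipeline targets: 58 ASD (21 F) and
#' 34 TD (18 F) participants aged 8-30 years, with TD mean age 17.1 (SD 5.6)
#' and ASD 15.7 (4.9) years, TD left/right MVC 71.3 (26.8) / 70.8 (27.4) N and
#' ASD 57.8 (22.0) / 55.0 (20.7) N, ADOS calibrated severity 5.9 (2.3) and
#' RBS-R total 29.5 (19.0).
#'
#' @param n_asd,n_td Arm sizes (non-negative; at least one positive).
#' @param age_range Permissible age range in years.
#' @param age_params Per-group list of `c(mean, sd)` in years.
#' @param sex_female Named proportion of females per group.
#' @param right_handed Named proportion of right-handed participants per group.
#' @param mvc_params Per-group, per-hand `c(mean, sd)` of MVC in Newtons.
#' @param clinical_params ASD-only clinical scores: ADOS CSS (bounded to
#'   `[1, 10]`) and RBS-R total (bounded below by 0), each `c(mean, sd)`.
#' @param seed Default seed used by [generate_cohort()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_asd = 58L, n_td = 34L,
                          age_range = c(8, 30),
                          age_params = list(TD  = c(mean = 17.1, sd = 5.6),
                                            ASD = c(mean = 15.7, sd = 4.9)),
                          sex_female = c(TD = 18 / 34, ASD = 21 / 58),
                          right_handed = c(TD = 0.912, ASD = 0.793),
                          mvc_params = list(
                            TD  = list(left  = c(mean = 71.3, sd = 26.8),
                                       right = c(mean = 70.8, sd = 27.4)),
                            ASD = list(left  = c(mean = 57.8, sd = 22.0),
                                       right = c(mean = 55.0, sd = 20.7))),
                          clinical_params = list(
                            ados_css   = c(mean = 5.9, sd = 2.3),
                            rbsr_total = c(mean = 29.5, sd = 19.0)),
                          seed = 1L) {
  if (n_asd < 0 || n_td < 0) stop("arm sizes must be non-negative")
  if (n_asd + n_td == 0) stop("cohort must contain at least one participant")
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2])
  sds <- c(vapply(age_params, `[[`, 0, "sd"),
           vapply(clinical_params, `[[`, 0, "sd"),
           unlist(lapply(mvc_params, vapply, `[[`, 0, "sd")))
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (any(sex_female < 0 | sex_female > 1)) stop("sex_female must be in [0,1]")
  structure(list(n_asd = as.integer(n_asd), n_td = as.integer(n_td),
                 age_range = age_range, age_params = age_params,
                 sex_female = sex_female, right_handed = right_handed,
                 mvc_params = mvc_params, clinical_params = clinical_params,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic participant cohort
#'
#' Draws one record per participant: group, sex, age, handedness, per-hand MVC
#' and (for the ASD arm only) ADOS calibrated severity score and RBS-R total.
#' Sex counts are deterministic (`round(n * proportion)` females per arm) so
#' the default configuration reproduces the published 18/34 and 21/58 female
#' counts exactly; ages, MVC and clinical scores are moment-calibrated
#' truncated normals (see [rtruncnorm_cal()]), so sample means converge on the
#' configured table cells as n grows.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (defaults to the one in `config`); identical
#'   seed and config give a bit-identical cohort.
#' @return A data.frame with columns `participant_id`, `group` (factor,
#'   TD/ASD), `sex` (factor, male/female), `age`, `handedness` (factor,
#'   right/left), `mvc_left`, `mvc_right`, `ados_css`, `rbsr_total`
#'   (clinical columns are `NA` for TD).
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  arm <- function(group, n) {
    if (n == 0L) return(NULL)
    p_f <- config$sex_female[[group]]
    sex <- rep("male", n)
    n_f <- round(n * p_f)
    if (n_f > 0) sex[sample.int(n, n_f)] <- "female"
    ap <- config$age_params[[group]]
    age <- rtruncnorm_cal(n, ap[["mean"]], ap[["sd"]],
                          config$age_range[1], config$age_range[2])
    hand <- ifelse(stats::runif(n) < config$right_handed[[group]],
                   "right", "left")
    mvc <- lapply(c(left = "left", right = "right"), function(h) {
      mp <- config$mvc_params[[group]][[h]]
      rtruncnorm_cal(n, mp[["mean"]], mp[["sd"]], lower = 0)
    })
    if (group == "ASD") {
      cp <- config$clinical_params
      ados <- rtruncnorm_cal(n, cp$ados_css[["mean"]], cp$ados_css[["sd"]],
                             lower = 1, upper = 10)
      rbsr <- rtruncnorm_cal(n, cp$rbsr_total[["mean"]], cp$rbsr_total[["sd"]],
                             lower = 0)
    } else {
      ados <- rep(NA_real_, n)
      rbsr <- rep(NA_real_, n)
    }
    data.frame(group = group, sex = sex, age = age, handedness = hand,
               mvc_left = mvc$left, mvc_right = mvc$right,
               ados_css = ados, rbsr_total = rbsr,
               stringsAsFactors = FALSE)
  }
  out <- rbind(arm("TD", config$n_td), arm("ASD", config$n_asd))
  out$participant_id <- sprintf("S%04d", seq_len(nrow(out)))
  out$group <- factor(out$group, levels = c("TD", "ASD"))
  out$sex <- factor(out$sex, levels = c("male", "female"))
  out$handedness <- factor(out$handedness, levels = c("right", "left"))
  out[, c("participant_id", "group", "sex", "age", "handedness",
          "mvc_left", "mvc_right", "ados_css", "rbsr_total")]
}
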