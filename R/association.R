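#' Group-mean center age
#'
#' Subtracts each group's mean age so that level-2 coefficients are
#' interpretable within group; the per-group mean of the centered column is 0.
#'
#' @param data data.frame containing age and group columns.
#' @param age_col,group_col Column names.
#' @param out_col Name of the centered column added.
#' @return `data` with `out_col` appended.
#' @export
center_age <- function(data, age_col = "age", group_col = "group",
                       out_col = "age_c") {
  stopifnot(age_col %in% names(data), group_col %in% names(data))
  if (nrow(data) == 0) stop("empty group")
  g <- data[[group_col]]
  if (is.factor(g)) g <- droplevels(g)
  data[[out_col]] <- data[[age_col]] -
    stats::ave(data[[age_col]], g, FUN = mean)
  data
}

.term_parts <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]
.term_order <- function(term) length(.term_parts(term))
.contains_term <- function(a, b) {
  pa <- .term_parts(a)
  pb <- .term_parts(b)
  length(pa) > length(pb) && all(pb %in% pa)
}

#' Build a model specification
#'
#' Assembles the predictor and interaction sets of each analysis family:
#'
#' * `behavior-group-grip`: log force variability; hand as level-1 predictor;
#'   group, sex, group-centered age as level-2; interactions group:hand,
#'   group:sex, group:age.
#' * `behavior-group-saccade`: saccade error (or error SD); amplitude and
#'   direction as level-1; group, sex, age as level-2; interactions
#'   amplitude:direction, group:amplitude, group:direction,
#'   group:amplitude:direction.
#' * `volume-group-lateral`: ROI volume with hemisphere as level-1 predictor;
#'   interactions group:hemisphere, group:sex, group:age.
#' * `volume-group-midline`: as above without a hemisphere term (one row per
#'   participant, so an ordinary linear model).
#' * `brain-behavior-grip`: log force variability on group, ROI volume, age
#'   (level-2) and hand (level-1), sex as a covariate of no interest;
#'   interactions group:hand, group:volume, hand:volume, group:hand:volume.
#' * `brain-behavior-saccade-error` / `brain-behavior-saccade-sd`: the
#'   oculomotor analogue with amplitude/direction level-1 terms and the
#'   group:amplitude:volume and group:direction:volume three-way sets.
#' * `brain-clinical-lateral`: ASD-only clinical outcome regressed on the
#'   left and right volumes of a homologous ROI pair as separate hemispheric
#'   predictors, plus sex and the sex:volume interactions (the outcome is
#'   participant-level, so this is an ordinary regression).
#' * `brain-clinical-midline`: plain linear regression of the clinical
#'   outcome on volume, sex and sex:volume.
#'
#' @param family Analysis family id (see above).
#' @param outcome Outcome column (defaults per family).
#' @param roi ROI being analyzed, where relevant: the base pair name for
#'   lateralized families (e.g. `"crus_I"`), a midline name for midline
#'   families, or any single volume column for brain-behavior families.
#' @return Object of class `model_spec`.
#' @export
build_model_spec <- function(family, outcome = NULL, roi = NULL) {
  random <- "(1 | participant_id)"
  spec <- switch(
    family,
    "behavior-group-grip" = list(
      outcome = outcome %||% "log_cov",
      fixed = c("hand", "group", "sex", "age_c"),
      interactions = c("group:hand", "group:sex", "group:age_c"),
      random = random),
    "behavior-group-saccade" = list(
      outcome = outcome %||% "error",
      fixed = c("amplitude", "direction", "group", "sex", "age_c"),
      interactions = c("amplitude:direction", "group:amplitude",
                       "group:direction", "group:amplitude:direction"),
      random = random),
    "volume-group-lateral" = {
      if (!is.null(roi) && !roi %in% cerebellar_rois("pairs")) {
        stop("'", roi, "' is not a lateralized ROI pair; ",
             "use family 'volume-group-midline' for midline ROIs")
      }
      list(outcome = outcome %||% "volume",
           fixed = c("hemisphere", "group", "sex", "age_c"),
           interactions = c("group:hemisphere", "group:sex", "group:age_c"),
           random = random)
    },
    "volume-group-midline" = {
      if (!is.null(roi) && !roi %in% cerebellar_rois("midline")) {
        stop("'", roi, "' is not a midline ROI")
      }
      list(outcome = outcome %||% "volume",
           fixed = c("group", "sex", "age_c"),
           interactions = c("group:sex", "group:age_c"),
           random = NULL)
    },
    "brain-behavior-grip" = list(
      outcome = outcome %||% "log_cov",
      fixed = c("hand", "group", "volume", "age_c", "sex"),
      interactions = c("group:hand", "group:volume", "hand:volume",
                       "group:hand:volume"),
      random = random),
    "brain-behavior-saccade-error" = ,
    "brain-behavior-saccade-sd" = list(
      outcome = outcome %||%
        if (family == "brain-behavior-saccade-sd") "error_sd" else "error",
      fixed = c("amplitude", "direction", "group", "volume", "age_c",
                "sex"),
      interactions = c("group:amplitude", "group:direction",
                       "amplitude:volume", "direction:volume",
                       "group:volume", "group:amplitude:volume",
                       "group:direction:volume"),
      random = random),
    "brain-clinical-lateral" = {
      if (!is.null(roi) && !roi %in% cerebellar_rois("pairs")) {
        stop("'", roi, "' is not a lateralized ROI pair; ",
             "use family 'brain-clinical-midline' for midline ROIs")
      }
      list(outcome = outcome %||% "ados_css",
           fixed = c("volume_left", "volume_right", "sex"),
           interactions = c("sex:volume_left", "sex:volume_right"),
           random = NULL)
    },
    "brain-clinical-midline" = {
      if (!is.null(roi) && !roi %in% cerebellar_rois("midline")) {
        stop("'", roi, "' is not a midline ROI")
      }
      list(outcome = outcome %||% "ados_css",
           fixed = c("volume", "sex"),
           interactions = "sex:volume",
           random = NULL)
    },
    stop("unknown analysis family: ", family))
  for (term in spec$interactions) {
    stopifnot(all(.term_parts(term) %in% spec$fixed))
  }
  structure(c(spec, list(family = family, roi = roi)),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.spec_formula <- function(spec, interactions = spec$interactions,
                          random = TRUE) {
  rhs <- paste(c(spec$fixed, interactions), collapse = " + ")
  if (random && !is.null(spec$random)) {
    rhs <- paste(rhs, "+", spec$random)
  }
  stats::as.formula(paste(spec$outcome, "~", rhs))
}

.lm_type3 <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  fac <- names(mf)[vapply(mf, is.factor, TRUE)]
  ctr <- stats::setNames(as.list(rep("contr.sum", length(fac))), fac)
  m <- stats::lm(formula, data, contrasts = if (length(ctr)) ctr)
  if (stats::df.residual(m) < 1) {
    labs <- attr(stats::terms(formula), "term.labels")
    return(data.frame(term = labs, F = NA_real_, df1 = NA_real_,
                      df2 = 0, p = NA_real_, stringsAsFactors = FALSE))
  }
  a <- car::Anova(m, type = 3)
  a <- a[!rownames(a) %in% c("(Intercept)", "Residuals"), , drop = FALSE]
  data.frame(term = rownames(a), F = a$`F value`, df1 = a$Df,
             df2 = stats::df.residual(m), p = a$`Pr(>F)`,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit an association model
#'
#' Fits the specification with `lmerTest` (participant random intercept,
#' REML by default) and extracts per-term omnibus F tests with Satterthwaite
#' (fractional) denominator degrees of freedom; specifications without a
#' random term, and singular random-intercept fits, are estimated by ordinary
#' least squares with type-III F tests instead (the singular fallback is
#' flagged).
#'
#' @param spec A [build_model_spec()].
#' @param data Long-format data with the spec's columns.
#' @param interactions Interaction terms to include (defaults to the full
#'   set; [prune_interactions()] passes the retained set).
#' @param reml Use REML for the reported mixed-model fit.
#' @return Object of class `assoc_fit`: the fitted `model`, the `terms`
#'   table (`term`, `F`, `df1`, `df2`, `p`), formulas, flags, and a slot for
#'   the pruning trace.
#' @export
fit_association <- function(spec, data, interactions = spec$interactions,
                            reml = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  miss <- setdiff(c(spec$outcome, spec$fixed,
                    if (!is.null(spec$random)) "participant_id"),
                  names(data))
  if (length(miss)) {
    stop("data is missing columns: ", paste(miss, collapse = ", "))
  }
  fm <- .spec_formula(spec, interactions)
  fixed_fm <- .spec_formula(spec, interactions, random = FALSE)
  singular <- FALSE
  if (!is.null(spec$random)) {
    model <- suppressMessages(lmerTest::lmer(fm, data = data, REML = reml))
    singular <- lme4::isSingular(model)
    if (singular) {
      warning("singular random-intercept fit; falling back to OLS")
    }
  }
  if (is.null(spec$random) || singular) {
    model <- stats::lm(fixed_fm, data = data)
    terms_tab <- .lm_type3(fixed_fm, data)
  } else {
    a <- stats::anova(model, type = 3)
    terms_tab <- data.frame(term = rownames(a), F = a$`F value`,
                            df1 = a$NumDF, df2 = a$DenDF, p = a$`Pr(>F)`,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(model = model, spec = spec, interactions = interactions,
                 formula = fm, fixed_formula = fixed_fm,
                 terms = terms_tab, reml = reml, singular = singular,
                 data = data, pruning_trace = NULL),
            class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat("Association model [", x$spec$family, "]: ",
      deparse(x$formula), "\n", sep = "")
  if (x$singular) cat("(singular mixed fit; OLS fallback)\n")
  print(x$terms, digits = 4)
  if (!is.null(x$pruning_trace) && nrow(x$pruning_trace)) {
    cat("pruned:",
        paste(x$pruning_trace$term[x$pruning_trace$action == "removed"],
              collapse = ", "), "\n")
  }
  invisible(x)
}

.loglik_fit <- function(spec, data, interactions) {
  fm <- .spec_formula(spec, interactions)
  if (!is.null(spec$random)) {
    suppressMessages(lme4::lmer(fm, data = data, REML = FALSE))
  } else {
    stats::lm(fm, data = data)
  }
}

#' Iteratively prune interaction terms
#'
#' Interaction terms are removed one at a time when their inclusion does not
#' improve model fit, assessed by a maximum-likelihood likelihood-ratio test
#' at `alpha`. Highest-order interactions are tested first (a lower-order
#' term is never tested while a retained higher-order term contains it, and
#' main effects are never removed); at each step the removable term with the
#' largest LRT p-value is dropped if that p-value is at or above `alpha`.
#' The final model is refit by REML with the retained terms, and the full
#' trace of tests is recorded.
#'
#' @param spec A [build_model_spec()].
#' @param data Long-format data.
#' @param alpha Retention threshold for the LRT p-value.
#' @param reml Use REML for the final reported fit.
#' @return An [fit_association()] result with `pruning_trace`.
#' @export
prune_interactions <- function(spec, data, alpha = 0.05, reml = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  retained <- spec$interactions
  locked <- character(0)
  trace <- NULL
  while (TRUE) {
    removable <- retained[!vapply(retained, function(t) {
      any(vapply(retained, .contains_term, TRUE, b = t))
    }, TRUE)]
    cands <- setdiff(removable, locked)
    if (!length(cands)) break
    ords <- vapply(cands, .term_order, 0L)
    cands <- cands[ords == max(ords)]
    full <- .loglik_fit(spec, data, retained)
    tests <- lapply(cands, function(term) {
      red <- .loglik_fit(spec, data, setdiff(retained, term))
      chi <- 2 * (as.numeric(stats::logLik(full)) -
                    as.numeric(stats::logLik(red)))
      df <- attr(stats::logLik(full), "df") -
        attr(stats::logLik(red), "df")
      p <- if (is.finite(chi) && df >= 1) {
        stats::pchisq(max(chi, 0), df, lower.tail = FALSE)
      } else {
        1 # inestimable term (e.g. rank deficiency): cannot improve the fit
      }
      data.frame(term = term, chisq = max(chi, 0), df = df, p = p,
                 stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, tests)
    worst <- tests[which.max(tests$p), ]
    if (worst$p >= alpha) {
      retained <- setdiff(retained, worst$term)
      worst$action <- "removed"
      trace <- rbind(trace, worst)
    } else {
      tests$action <- "kept"
      trace <- rbind(trace, tests)
      locked <- union(locked, tests$term)
    }
  }
  fit <- fit_association(spec, data, interactions = retained, reml = reml)
  fit$pruning_trace <- trace %||%
    data.frame(term = character(0), chisq = numeric(0), df = numeric(0),
               p = numeric(0), action = character(0))
  fit
}

#' Simple slopes of a focal predictor at each moderator level
#'
#' Probes a focal-by-moderator interaction by estimating the slope of the
#' focal predictor (or, for a two-level factor, its level contrast) at each
#' level of a categorical moderator, as a linear combination of the fixed
#' effects with standard errors from the coefficient covariance. For mixed
#' models the t test uses Satterthwaite degrees of freedom; other covariates
#' are held at 0 / their reference level.
#'
#' @param fit An [fit_association()] result.
#' @param focal Name of the focal predictor (numeric, or a two-level
#'   factor).
#' @param moderator Name of a categorical moderator in the model.
#' @return data.frame with one row per moderator level: `moderator`,
#'   `level`, `estimate`, `se`, `df`, `t`, `p`.
#' @export
simple_slopes <- function(fit, focal, moderator) {
  stopifnot(inherits(fit, "assoc_fit"))
  model <- fit$model
  is_mixed <- inherits(model, "lmerMod")
  b <- if (is_mixed) lme4::fixef(model) else stats::coef(model)
  V <- as.matrix(stats::vcov(model))
  mf <- stats::model.frame(model)
  if (!moderator %in% names(mf) || !is.factor(mf[[moderator]])) {
    stop("moderator must be a categorical predictor in the model")
  }
  if (focal %in% names(mf) && is.factor(mf[[focal]]) &&
      nlevels(mf[[focal]]) != 2) {
    stop("a factor focal predictor must have exactly two levels")
  }
  rhs <- stats::as.formula(paste("~", paste(
    c(fit$spec$fixed, fit$interactions), collapse = " + ")))
  vars <- setdiff(all.vars(rhs), "participant_id")
  base_row <- function(level, focal_val) {
    row <- lapply(vars, function(v) {
      if (v == moderator) {
        factor(level, levels = levels(mf[[moderator]]))
      } else if (v == focal) {
        focal_val
      } else if (v %in% names(mf) && is.factor(mf[[v]])) {
        factor(levels(mf[[v]])[1], levels = levels(mf[[v]]))
      } else {
        0
      }
    })
    stats::setNames(as.data.frame(row), vars)
  }
  focal_vals <- if (focal %in% names(mf) && is.factor(mf[[focal]])) {
    lv <- levels(mf[[focal]])
    list(factor(lv[1], levels = lv), factor(lv[2], levels = lv))
  } else {
    list(0, 1)
  }
  out <- lapply(levels(mf[[moderator]]), function(level) {
    nd <- rbind(base_row(level, focal_vals[[1]]),
                base_row(level, focal_vals[[2]]))
    X <- stats::model.matrix(rhs, nd)
    stopifnot(setequal(colnames(X), names(b)))
    L <- (X[2, ] - X[1, ])[names(b)]
    est <- sum(L * b)
    se <- sqrt(drop(t(L) %*% V %*% L))
    if (inherits(model, "lmerModLmerTest")) {
      ct <- lmerTest::contest1D(model, L)
      data.frame(moderator = moderator, level = level,
                 estimate = ct$Estimate, se = ct$`Std. Error`,
                 df = ct$df, t = ct$`t value`, p = ct$`Pr(>|t|)`,
                 stringsAsFactors = FALSE)
    } else {
      df <- stats::df.residual(model)
      tval <- est / se
      data.frame(moderator = moderator, level = level, estimate = est,
                 se = se, df = df, t = tval,
                 p = 2 * stats::pt(-abs(tval), df),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Applies the step-up rule at false-discovery rate `q`: with ordered
#' p-values `p(1) <= ... <= p(m)`, find the largest `k` with
#' `p(k) <= k q / m` and reject hypotheses `1..k`. `p_crit = k q / m` is the
#' largest passing threshold (reported alongside results as the effective
#' significance cut).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q False-discovery rate (default 0.05).
#' @return Object of class `bh_family`: `p`, `reject` (logical, input
#'   order), `k`, `p_crit` (`NA` when nothing is rejected), `q`, `m`.
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value family")
  stopifnot(all(p >= 0 & p <= 1), q > 0, q < 1)
  m <- length(p)
  o <- order(p)
  s <- p[o]
  passing <- which(s <= seq_len(m) * q / m)
  k <- if (length(passing)) max(passing) else 0L
  reject <- rep(FALSE, m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  structure(list(p = p, reject = reject, k = k,
                 p_crit = if (k > 0) k * q / m else NA_real_,
                 q = q, m = m),
            class = "bh_family")
}

#' @export
print.bh_family <- function(x, ...) {
  cat("Benjamini-Hochberg family: m =", x$m, " q =", x$q,
      " rejected =", sum(x$reject),
      " p_crit =", format(x$p_crit, digits = 3), "\n")
  invisible(x)
}
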