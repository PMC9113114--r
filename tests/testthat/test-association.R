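test_that("age is centered within group", {
  d <- data.frame(age = c(10, 20, 30, 10), group = c("a", "a", "b", "b"))
  out <- center_age(d)
  expect_equal(out$age_c, c(-5, 5, 10, -10))
  expect_equal(as.numeric(tapply(out$age_c, out$group, mean)), c(0, 0))
  single <- center_age(data.frame(age = 12, group = "a"))
  expect_equal(single$age_c, 0)
  expect_error(center_age(d[0, ]), "empty group")
})

test_that("model specifications carry the families' predictor sets", {
  grip <- build_model_spec("behavior-group-grip")
  expect_setequal(grip$fixed, c("hand", "group", "sex", "age_c"))
  expect_setequal(grip$interactions,
                  c("group:hand", "group:sex", "group:age_c"))
  mid <- build_model_spec("volume-group-midline", roi = "vermis_VI_VII")
  expect_false("hemisphere" %in% mid$fixed)
  expect_null(mid$random)
  expect_error(build_model_spec("volume-group-lateral",
                                roi = "vermis_VI_VII"), "lateralized")
  clin <- build_model_spec("brain-clinical-midline", roi = "white_matter")
  expect_null(clin$random)
  sac <- build_model_spec("brain-behavior-saccade-error")
  expect_true(all(c("group:amplitude:volume", "group:direction:volume")
                  %in% sac$interactions))
  expect_error(build_model_spec("nonsense"), "unknown analysis family")
})

test_that("Benjamini-Hochberg step-up matches hand computation", {
  b <- bh_adjust(c(0.01, 0.02, 0.04, 0.20), q = 0.05)
  expect_equal(b$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(b$p_crit, 0.025)
  expect_equal(bh_adjust(rep(1, 6))$reject, rep(FALSE, 6))
  one <- bh_adjust(0.01)
  expect_true(one$reject)
  expect_equal(one$p_crit, 0.05)
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.1, 1.2)))
})

test_that("BH equals a brute-force threshold search and p.adjust", {
  set.seed(99)
  for (i in 1:1000) {
    m <- sample(1:10, 1)
    p <- round(runif(m)^sample(1:3, 1), 4)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    got <- bh_adjust(p, q)
    oracle <- bh_brute(p, q)
    expect_identical(got$reject, oracle$reject)
    expect_identical(unname(stats::p.adjust(p, "BH") <= q), got$reject)
  }
})

test_that("a generated group effect is recovered by the mixed model", {
  co <- generate_cohort(cohort_config(n_asd = 100, n_td = 100), seed = 51)
  g <- generate_grip_outcomes(co, coupling = grip_coupling(
    group_shift = 0.35), seed = 52)
  fit <- quiet_fit(prune_interactions(build_model_spec(
    "behavior-group-grip"), center_age(g)))
  beta <- lme4::fixef(fit$model)[["groupASD"]]
  se <- sqrt(diag(as.matrix(vcov(fit$model))))[["groupASD"]]
  expect_lt(abs(beta - 0.35), 2 * se)
  expect_true(all(c("hand", "group", "sex", "age_c") %in% fit$terms$term))
  expect_true(all(is.finite(fit$terms$df2)))
  # Satterthwaite denominator df are fractional, not forced integers
  expect_true(is.numeric(fit$terms$df2))
})

test_that("pruning never removes main effects and respects hierarchy", {
  co <- generate_cohort(cohort_config(n_asd = 150, n_td = 150), seed = 53)
  so <- generate_saccade_outcomes(co, coupling = saccade_coupling(),
                                  seed = 54)
  spec <- build_model_spec("behavior-group-saccade")
  fit <- quiet_fit(prune_interactions(spec, center_age(so)))
  expect_true(all(spec$fixed %in% fit$terms$term))
  retained <- fit$interactions
  if ("group:amplitude:direction" %in% retained) {
    expect_true(all(c("group:amplitude", "group:direction",
                      "amplitude:direction") %in% retained))
  }
  tr <- fit$pruning_trace
  expect_true(all(tr$p[tr$action == "removed"] >= 0.05))
  # a spec with no interactions passes through unchanged
  spec0 <- spec
  spec0$interactions <- character(0)
  fit0 <- quiet_fit(prune_interactions(spec0, center_age(so)))
  expect_length(fit0$interactions, 0)
  expect_equal(nrow(fit0$pruning_trace), 0)
})

test_that("a true group-by-sex volume shift is retained and estimated", {
  # shift sized for adequate LRT power given the ~2.2 cm^3 baseline SDs
  co <- generate_cohort(cohort_config(n_asd = 200, n_td = 200), seed = 55)
  eff <- volume_effects_config(group_sex_shift = c(crus_II_VIIB = -1.5))
  v <- generate_volume_table(co, eff, seed = 56)
  d <- volumes_to_long(v, co, "crus_II_VIIB")
  fit <- quiet_fit(prune_interactions(
    build_model_spec("volume-group-lateral", roi = "crus_II_VIIB"), d))
  expect_true("group:sex" %in% fit$interactions)
  beta <- lme4::fixef(fit$model)[["groupASD:sexfemale"]]
  se <- sqrt(diag(as.matrix(vcov(fit$model))))[["groupASD:sexfemale"]]
  expect_lt(abs(beta - (-1.5)), 2 * se)
})

test_that("simple slopes reconstruct the interaction exactly", {
  co <- generate_cohort(cohort_config(n_asd = 150, n_td = 150), seed = 57)
  v <- generate_volume_table(co, seed = 58)
  so <- generate_saccade_outcomes(co, v, saccade_coupling(
    volume_roi = "vermis_VI_VII", volume_slope = c(TD = -1, ASD = 0)),
    seed = 59)
  spec <- build_model_spec("brain-behavior-saccade-error")
  # algebraic identity on the full model: slope(B) - slope(A) equals the
  # interaction coefficient exactly
  fit <- quiet_fit(fit_association(spec, center_age(so)))
  ss <- simple_slopes(fit, focal = "volume", moderator = "group")
  b <- lme4::fixef(fit$model)
  expect_equal(ss$estimate[2] - ss$estimate[1],
               unname(b[["groupASD:volume"]]), tolerance = 1e-9)
  # recovery of the per-group truths on the pruned (reported) model; a
  # single simulated draw gets a 3 SE bound (~0.3% false-alarm rate)
  fitp <- quiet_fit(prune_interactions(spec, center_age(so)))
  ssp <- simple_slopes(fitp, focal = "volume", moderator = "group")
  expect_lt(abs(ssp$estimate[ssp$level == "TD"] - (-1)),
            3 * ssp$se[ssp$level == "TD"])
  expect_lt(abs(ssp$estimate[ssp$level == "ASD"] - 0),
            3 * ssp$se[ssp$level == "ASD"])
  # without the interaction the slopes are equal at both levels
  fit0 <- quiet_fit(fit_association(spec, center_age(so),
                                    interactions = character(0)))
  ss0 <- simple_slopes(fit0, focal = "volume", moderator = "group")
  expect_equal(ss0$estimate[1], ss0$estimate[2], tolerance = 1e-9)
  expect_error(simple_slopes(fit, focal = "volume", moderator = "age_c"),
               "categorical")
})

test_that("specs without a random term fit by OLS with type-III F tests", {
  co <- generate_cohort(cohort_config(n_asd = 80, n_td = 60), seed = 61)
  v <- generate_volume_table(co, seed = 62)
  d <- center_age(data.frame(participant_id = co$participant_id,
                             volume = v$vermis_VI_VII, group = co$group,
                             sex = co$sex, age = co$age))
  fit <- quiet_fit(prune_interactions(
    build_model_spec("volume-group-midline", roi = "vermis_VI_VII"), d))
  expect_s3_class(fit$model, "lm")
  expect_true(all(fit$terms$df2 == stats::df.residual(fit$model)))
  expect_true("group" %in% fit$terms$term)
})

test_that("run_family corrects confirmatory sets and flags exploratory", {
  co <- generate_cohort(cohort_config(n_asd = 60, n_td = 60), seed = 63)
  v <- generate_volume_table(co, seed = 64)
  vg <- quiet_fit(analyze_volume_groups(v, co))
  expect_equal(nrow(vg$lateral$results), 7)
  expect_false(any(vg$lateral$results$exploratory))
  expect_s3_class(vg$lateral$fits[[1]], "assoc_fit")
  g <- generate_grip_outcomes(co, v, grip_coupling(
    volume_roi = "left_crus_I", volume_slope = 0.12), seed = 65)
  bb <- quiet_fit(analyze_brain_behavior(g, v, co, "grip"))
  expect_equal(sort(bb$results$member),
               sort(as.vector(outer(c("left_", "right_"),
                                    c("lobules_I_V", "lobule_VI", "crus_I"),
                                    paste0))))
  expect_true("p_crit" %in% names(bb$results))
  expl <- quiet_fit(analyze_brain_behavior(g, v, co, "grip",
                                           rois = "white_matter",
                                           correct = FALSE))
  expect_true(all(expl$results$exploratory))
})

test_that("clinical regressions use separate hemispheric predictors", {
  co <- generate_cohort(cohort_config(n_asd = 80, n_td = 20), seed = 66)
  v <- generate_volume_table(co, seed = 67)
  cl <- quiet_fit(analyze_brain_clinical(v, co, "ados_css"))
  expect_setequal(unique(cl$lateral$results$term),
                  c("volume_left", "volume_right"))
  expect_s3_class(cl$lateral$fits$crus_II_VIIB$model, "lm")
  ss <- simple_slopes(cl$lateral$fits$crus_II_VIIB,
                      focal = "volume_right", moderator = "sex")
  expect_equal(nrow(ss), 2)
  td_only <- co[co$group == "TD", ]
  expect_error(analyze_brain_clinical(v, td_only, "ados_css"), "no ASD")
})
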