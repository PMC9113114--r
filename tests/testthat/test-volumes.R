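test_that("zero-noise, zero-effect volumes equal their baselines exactly", {
  co <- generate_cohort(cohort_config(n_td = 5, n_asd = 5), seed = 1)
  v <- generate_volume_table(co, volume_effects_config(noise_scale = 0),
                             seed = 1)
  expect_equal(unique(v$vermis_VI_VII[co$group == "TD"]), 1.65)
  expect_equal(unique(v$vermis_VI_VII[co$group == "ASD"]), 1.54)
  expect_equal(unique(v$right_crus_II_VIIB[co$group == "TD"]), 14.35)
  expect_equal(unique(v$left_lobule_X[co$group == "ASD"]), 0.59)
})

test_that("the table has the canonical 18-ROI schema and positive volumes", {
  co <- generate_cohort(cohort_config(n_td = 40, n_asd = 40), seed = 2)
  v <- generate_volume_table(co, seed = 2)
  expect_identical(setdiff(names(v), "participant_id"), cerebellar_rois())
  expect_length(cerebellar_rois(), 18)
  expect_true(all(as.matrix(v[, cerebellar_rois()]) > 0))
  expect_identical(v, generate_volume_table(co, seed = 2))
})

test_that("large-sample ROI means match the configured baselines", {
  td <- generate_cohort(cohort_config(n_td = 10000, n_asd = 0), seed = 3)
  v <- generate_volume_table(td, seed = 3)
  expect_lt(abs(mean(v$vermis_VI_VII) - 1.65), 0.01)
  expect_lt(abs(mean(v$right_crus_II_VIIB) - 14.35), 0.06)
  expect_lt(abs(sd(v$vermis_VI_VII) - 0.20), 0.01)
})

test_that("hemispheres of a paired ROI correlate within participant", {
  co <- generate_cohort(cohort_config(n_td = 500, n_asd = 0), seed = 4)
  v <- generate_volume_table(co, seed = 4)
  expect_gt(cor(v$left_crus_I, v$right_crus_I), 0.6)
})

test_that("a configured ASD-female shift is recovered from cell means", {
  shift <- -0.8
  co <- generate_cohort(cohort_config(n_td = 400, n_asd = 400), seed = 5)
  eff <- volume_effects_config(group_sex_shift = c(crus_II_VIIB = shift))
  v <- generate_volume_table(co, eff, seed = 5)
  fem <- co$sex == "female"
  asd <- co$group == "ASD"
  # female ASD-TD difference, net of the baseline group difference
  d_obs <- (mean(v$right_crus_II_VIIB[fem & asd]) -
              mean(v$right_crus_II_VIIB[fem & !asd])) - (14.02 - 14.35)
  n1 <- sum(fem & asd)
  n2 <- sum(fem & !asd)
  se <- sqrt(2.34^2 / n1 + 2.07^2 / n2)
  expect_lt(abs(d_obs - shift), 2 * se)
})

test_that("missing participant fields and empty tables are errors", {
  co <- generate_cohort(cohort_config(n_td = 3, n_asd = 0), seed = 6)
  expect_error(generate_volume_table(co[, c("participant_id", "group")]),
               "missing fields")
  expect_error(generate_volume_table(co[0, ]), "empty")
  expect_error(volume_effects_config(sex_shift = c(nonsense = 1)),
               "canonical")
})
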