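test_that("default cohort reproduces the study's arm sizes and sex counts", {
  co <- generate_cohort()
  expect_equal(sum(co$group == "TD"), 34)
  expect_equal(sum(co$group == "ASD"), 58)
  expect_equal(sum(co$group == "TD" & co$sex == "female"), 18)
  expect_equal(sum(co$group == "ASD" & co$sex == "female"), 21)
  expect_true(all(is.na(co$ados_css[co$group == "TD"])))
  expect_true(all(is.na(co$rbsr_total[co$group == "TD"])))
  expect_true(all(!is.na(co$ados_css[co$group == "ASD"])))
  expect_true(all(co$age >= 8 & co$age <= 30))
  expect_true(all(co$mvc_left > 0 & co$mvc_right > 0))
})

test_that("a one-participant arm works and clinical fields stay absent", {
  co <- generate_cohort(cohort_config(n_td = 1, n_asd = 0))
  expect_equal(nrow(co), 1)
  expect_equal(as.character(co$group), "TD")
  expect_true(is.na(co$ados_css))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(n_td = -1), "non-negative")
  expect_error(cohort_config(n_td = 0, n_asd = 0), "at least one")
  expect_error(cohort_config(age_params = list(
    TD = c(mean = 17, sd = -1), ASD = c(mean = 15, sd = 5))), "SD")
})

test_that("identical seed and config give a bit-identical cohort", {
  a <- generate_cohort(cohort_config(), seed = 7)
  b <- generate_cohort(cohort_config(), seed = 7)
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(), seed = 8)
  expect_false(identical(a, c))
})

test_that("large-sample moments converge on the configured table cells", {
  td <- generate_cohort(cohort_config(n_td = 10000, n_asd = 0), seed = 31)
  # law-of-large-numbers check against the configured TD left-hand MVC
  expect_lt(abs(mean(td$mvc_left) - 71.3) / 71.3, 0.01)
  expect_lt(abs(sd(td$mvc_left) - 26.8), 1)
  asd <- generate_cohort(cohort_config(n_td = 0, n_asd = 10000), seed = 32)
  expect_lt(abs(mean(asd$ados_css) - 5.9), 0.1)
  expect_true(all(asd$ados_css >= 1 & asd$ados_css <= 10))
  expect_true(all(asd$rbsr_total >= 0))
})

test_that("the moment-calibrated truncated-normal sampler hits its mean", {
  set.seed(1)
  x <- rtruncnorm_cal(200000, mean = 29.5, sd = 19, lower = 0)
  expect_lt(abs(mean(x) - 29.5), 0.15)
  expect_true(all(x >= 0))
  expect_equal(rtruncnorm_cal(5, 3, 0, 0, 10), rep(3, 5))
})
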