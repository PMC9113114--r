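test_that("zero-phase Butterworth filtering matches its analytic response", {
  t <- seq(0, 20 - dt_force, by = dt_force)
  amp_after <- function(freq, level = 5) {
    tr <- force_trial(t, level + sin(2 * pi * freq * t))
    x <- lowpass_filter(tr)$data$force
    mid <- x[(5 * fs_force):(15 * fs_force)]
    (max(mid) - min(mid)) / 2
  }
  # constant traces are fixed points (DC gain exactly 1)
  dc <- lowpass_filter(force_trial(t, rep(5, length(t))))$data$force
  expect_equal(dc, rep(5, length(t)), tolerance = 1e-9)
  # two passes square the magnitude response: |H(fc)|^2 = 1/2
  expect_equal(amp_after(15), 0.5, tolerance = 0.02)
  # |H(60)|^2 = 1 / (1 + (60/15)^8) ~ 1.5e-5
  expect_lt(amp_after(60), 1e-4)
})

test_that("MVC is the mean of the three per-trial maxima", {
  mk <- function(peak) {
    t <- seq(0, 3 - dt_force, by = dt_force)
    force_trial(t, peak * pmin(t, 1), hand = "left")
  }
  expect_equal(compute_mvc(list(mk(10), mk(12), mk(11)))$mvc, 11)
  zero <- force_trial(seq(0, 3 - dt_force, by = dt_force),
                      rep(0, 3 * fs_force), hand = "left")
  expect_equal(compute_mvc(list(zero, zero, zero))$mvc, 0)
  expect_error(compute_mvc(list(mk(10), mk(12))), "left")
  trs <- lapply(1:3, function(i) generate_mvc_trial(60 + i, seed = i))
  res <- compute_mvc(trs)
  expect_equal(res$mvc, mean(vapply(trs, function(x) x$truth$peak, 0)))
})

test_that("the rise offset satisfies the rate and force-band criteria", {
  # linear 0->6 N over [0,1] s then constant: rate drops from 6 to 0 N/s at
  # t = 1 and 6 N is inside 90-110% of the 6 N sustained mean
  t <- seq(0, 15 - dt_force, by = dt_force)
  off <- locate_rise_offset(force_trial(t, pmin(t, 1) * 6,
                                        stop_cue_time = 15))
  expect_lte(abs(off$offset_time - 1), dt_force + 1e-9)
  expect_equal(off$sustained_mean, 6)
  # constant-zero and constant traces contain no rise
  expect_null(locate_rise_offset(force_trial(t, rep(0, length(t)),
                                             stop_cue_time = 15)))
  expect_null(locate_rise_offset(force_trial(t, rep(6, length(t)),
                                             stop_cue_time = 15)))
})

test_that("detected offsets track the generator's annotated rise end", {
  err <- vapply(1:100, function(i) {
    tr <- generate_force_trial(force_trial_spec(latent_cov = 0.05),
                               seed = 1000 + i)
    s <- score_grip_trial(tr)
    abs(s$onset_offset_time - tr$truth$onset_offset)
  }, 0)
  expect_gte(mean(err <= 0.05), 0.9)
  expect_lt(median(err), 0.05)
})

test_that("sustained-phase extraction applies the exclusion boundaries", {
  cfg <- grip_config()
  base <- flat_grip_trial(level = 6, offset_at = 1.2)
  # full window: [3, 15) intersect [1.2, inf) = 12 s
  seg <- extract_sustained(base, 1.2, cfg)
  expect_true(seg$valid)
  expect_equal(seg$retained_duration, 12)
  # a release of exactly 1 s is retained ("greater than 1 s" is excluded)
  seg1 <- extract_sustained(with_release(base, c(5, 6)), 1.2, cfg)
  expect_true(seg1$valid)
  expect_equal(seg1$retained_duration, 12)
  # a 1.5 s release is removed: 10.5 s retained, still valid
  seg2 <- extract_sustained(with_release(base, c(5, 6.5)), 1.2, cfg)
  expect_true(seg2$valid)
  expect_equal(seg2$retained_duration, 10.5)
  # just over the boundary: 1.005 s removed
  seg3 <- extract_sustained(with_release(base, c(5, 6.005)), 1.2, cfg)
  expect_equal(seg3$retained_duration, 12 - 1.005)
  # exactly 8 s retained is valid ("less than 8 s" is excluded)
  seg4 <- extract_sustained(base, 7.0, cfg)
  expect_true(seg4$valid)
  expect_equal(seg4$retained_duration, 8)
  # rise offset at 8.5 s leaves 6.5 s: short_sustained
  seg5 <- extract_sustained(base, 8.5, cfg)
  expect_false(seg5$valid)
  expect_equal(seg5$exclusion_reason, "short_sustained")
  # no offset located
  seg6 <- extract_sustained(base, NULL, cfg)
  expect_equal(seg6$exclusion_reason, "no_onset")
})

test_that("CoV matches closed forms and is scale invariant", {
  expect_equal(compute_cov(rep(6, 1000))$cov, 0)
  t <- seq(0, 100, by = 1 / 200)
  sine <- 6 + sin(2 * pi * 2 * t)
  expect_equal(compute_cov(sine)$cov, 1 / (6 * sqrt(2)), tolerance = 1e-3)
  alt <- rep(c(4, 8), 5000)
  expect_equal(compute_cov(alt)$cov, 2 / 6, tolerance = 1e-3)
  expect_false(compute_cov(c(-1, 1))$valid)
  set.seed(42)
  for (i in 1:10) {
    x <- abs(rnorm(500, 10, 2))
    c_scaled <- compute_cov(x * runif(1, 0.1, 10))$cov
    expect_equal(c_scaled, compute_cov(x)$cov, tolerance = 1e-12)
  }
  expect_equal(compute_cov(sine)$log_cov, log(compute_cov(sine)$cov))
})

test_that("estimated CoV recovers the latent CoV monotonically", {
  est <- vapply(c(0.01, 0.05, 0.1), function(cv) {
    mean(vapply(1:40, function(i) {
      score_grip_trial(generate_force_trial(
        force_trial_spec(latent_cov = cv), seed = 2000 + i))$cov
    }, 0))
  }, 0)
  expect_true(all(diff(est) > 0))
  expect_true(all(abs(est - c(0.01, 0.05, 0.1)) / c(0.01, 0.05, 0.1) < 0.1))
})

test_that("full-trial scoring handles noiseless, released and flat trials", {
  s <- score_grip_trial(generate_force_trial(
    force_trial_spec(mvc = 60, latent_cov = 0), seed = 1))
  expect_true(s$valid)
  expect_lt(s$cov, 1e-6)
  expect_equal(s$sustained_mean, 9, tolerance = 1e-6)
  flat <- force_trial(seq(0, 15 - dt_force, by = dt_force),
                      rep(0, 15 * fs_force), stop_cue_time = 15)
  s0 <- score_grip_trial(flat)
  expect_false(s0$valid)
  expect_equal(s0$exclusion_reason, "no_onset")
})
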