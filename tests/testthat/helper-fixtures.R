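# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data.

fs_force <- 200
dt_force <- 1 / fs_force

# A plain sustained-grip trace: rise over [1, 1.2] s, then constant `level`
# until the 15 s stop cue. Unfiltered, noiseless.
flat_grip_trial <- function(level = 6, duration = 15, offset_at = 1.2) {
  t <- (0:(duration * fs_force - 1)) / fs_force
  u <- pmin(pmax((t - (offset_at - 0.2)) / 0.2, 0), 1)
  force_trial(t, level * (3 * u^2 - 2 * u^3), stop_cue_time = duration)
}

# Zero out `release` = c(start, end) (end exclusive) on a trial's force.
with_release <- function(trial, release) {
  tt <- trial$data$time
  trial$data$force[tt >= release[1] & tt < release[2]] <- 0
  trial
}

quiet_fit <- function(expr) suppressWarnings(suppressMessages(expr))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force BH oracle: the largest k whose threshold captures
# at least k p-values defines the rejection threshold.
bh_brute <- function(p, q = 0.05) {
  m <- length(p)
  for (k in m:1) {
    thr <- k * q / m
    if (sum(p <= thr) >= k) {
      return(list(reject = p <= thr, p_crit = thr))
    }
  }
  list(reject = rep(FALSE, m), p_crit = NA_real_)
}
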