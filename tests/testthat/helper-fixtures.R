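# Shared fixture builders and small oracles used across the suite.

# Pure tone as an LFP trace.
tone_trace <- function(freq, duration_s, fs = 2000, amp = 1, phase = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  lfp_trace(amp * cos(2 * pi * freq * t + phase), fs)
}

# RMS over the middle third of a signal (avoids filter edge transients).
mid_rms <- function(x) {
  n <- length(x)
  stats::sd(x[round(n / 3):round(2 * n / 3)])
}

# Smallest circular distance between two angles in degrees.
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# Bin-wise oracle state labels from a generator ground-truth schedule.
schedule_bin_states <- function(schedule, bin_starts) {
  vapply(bin_starts, function(s) {
    schedule$state[which(schedule$start_s <= s & schedule$end_s > s)[1]]
  }, character(1))
}

# Injection schedule for burst-recovery tests: jittered times thinned to a
# minimum separation and snapped to carrier peaks so the envelope centre
# coincides with an amplitude maximum.
burst_schedule <- function(n, duration_s, min_sep_s = 0.25, carrier_hz = 60) {
  times <- sort(stats::runif(n, 1, duration_s - 1))
  keep <- c(TRUE, diff(times) >= min_sep_s)
  while (any(!keep)) {
    times <- times[keep]
    keep <- c(TRUE, diff(times) >= min_sep_s)
  }
  round(times * carrier_hz) / carrier_hz
}

# Brute-force two-sided Mann-Whitney: exact U distribution by enumerating
# all group assignments of the pooled sample (tie-free inputs only).
brute_force_mwu <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2, function(ix) {
    sum(ranks[ix]) - na * (na + 1) / 2
  })
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(u = u_obs, p = min(p, 1))
}

bessel_ratio <- function(kappa) besselI(kappa, 1) / besselI(kappa, 0)
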