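test_that("bandpass preserves passband tones at zero lag and kills stop tones", {
  specs <- default_band_specs()
  fs <- 2000
  tone <- tone_trace(3.5, 30, fs)
  f <- bandpass(tone, specs$theta)
  expect_equal(mid_rms(f$samples) / mid_rms(tone$samples), 1, tolerance = 0.05)
  # zero phase: cross-correlation with the input peaks at lag 0 (+/- 1 sample)
  mid <- 20000:40000
  cc <- stats::ccf(f$samples[mid], tone$samples[mid], lag.max = 5,
                   plot = FALSE)
  expect_lte(abs(cc$lag[which.max(cc$acf)]), 1)

  low_tone <- tone_trace(1.0, 30, fs)
  atten <- 20 * log10(mid_rms(bandpass(low_tone, specs$theta)$samples) /
                        mid_rms(low_tone$samples))
  expect_lt(atten, -40)

  t40 <- tone_trace(40, 30, fs)
  expect_equal(mid_rms(bandpass(t40, specs$slow_gamma)$samples) /
                 mid_rms(t40$samples), 1, tolerance = 0.05)
  fast_out <- 20 * log10(mid_rms(bandpass(t40, specs$fast_gamma)$samples) /
                           mid_rms(t40$samples))
  expect_lt(fast_out, -40)

  # passband idempotence: filtering twice changes the tone by < 10%
  ff <- bandpass(f, specs$theta)
  expect_equal(mid_rms(ff$samples) / mid_rms(f$samples), 1, tolerance = 0.1)

  expect_error(bandpass(tone_trace(3, 10, 150), specs$gamma), "Nyquist")
})

test_that("theta troughs are strict minima at the cycle period", {
  fs <- 2000
  filt <- bandpass(tone_trace(3.5, 10, fs), default_band_specs()$theta)
  ev <- detect_theta_troughs(filt)
  expect_true(nrow(ev) %in% c(34L, 35L)) # 10 s at 3.5 Hz
  # interior cycles (first/last sit on filter edge transients)
  inner <- ev$time_s[ev$time_s > 0.5 & ev$time_s < 9.5]
  expect_true(all(abs(diff(inner) - 1 / 3.5) <= 1 / fs))
  # troughs of a cosine sit half a period after each peak
  analytic <- (0:35) / 3.5 + 1 / 7
  match_err <- vapply(inner, function(t) min(abs(analytic - t)), numeric(1))
  expect_true(all(match_err <= 1.5 / fs))

  # 10 Hz leakage (minima 100 ms apart) is fully rejected
  ten <- lfp_trace(cos(2 * pi * 10 * seq(0, 5 - 1 / fs, by = 1 / fs)), fs)
  expect_identical(nrow(detect_theta_troughs(ten)), 0L)

  # constant signal: no strict minima
  expect_identical(nrow(detect_theta_troughs(lfp_trace(rep(1, 2000), fs))), 0L)

  # retained troughs always respect the separation rule
  set.seed(41)
  noisy <- lfp_trace(cos(2 * pi * 3.5 * seq(0, 20, by = 1 / fs)) +
                       0.3 * rnorm(20 * fs + 1), fs)
  evn <- detect_theta_troughs(bandpass(noisy, default_band_specs()$theta))
  expect_true(all(diff(evn$time_s) >= 0.2 - 1e-9))
})

test_that("instantaneous phase uses the peak-at-zero convention", {
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  ph <- instantaneous_phase(lfp_trace(cos(2 * pi * 3.5 * t), fs))
  peaks <- round(seq(5, 15, by = 1 / 3.5) * 3.5) / 3.5 # interior peak times
  peak_idx <- round(peaks * fs) + 1L
  expect_true(all(circ_diff_deg(ph[peak_idx], 0) <= 2))
  trough_idx <- round((peaks + 1 / 7) * fs) + 1L
  expect_true(all(circ_diff_deg(ph[trough_idx], 180) <= 2))

  ph_neg <- instantaneous_phase(lfp_trace(-cos(2 * pi * 3.5 * t), fs))
  expect_true(all(circ_diff_deg(ph_neg[peak_idx], 180) <= 2))

  # chirp: unwrapped phase strictly increasing in the interior
  f0 <- 2.5; f1 <- 4.5; dur <- 30
  tc <- seq(0, dur - 1 / fs, by = 1 / fs)
  chirp <- cos(2 * pi * (f0 * tc + (f1 - f0) / (2 * dur) * tc^2))
  phc <- instantaneous_phase(lfp_trace(chirp, fs))
  inner <- (2 * fs):((dur - 2) * fs)
  d <- diff(phc[inner])
  d[d < -180] <- d[d < -180] + 360 # unwrap
  expect_true(all(d > 0))

  expect_error(instantaneous_phase(lfp_trace(rep(0, 100), fs)), "undefined")
})

test_that("gamma episodes recover an injected schedule and obey separation", {
  set.seed(42)
  fs <- 1000
  dur <- 60
  x <- pink_noise(dur * fs, fs, 1, 15) + rnorm(dur * fs, 0, 4)
  times <- burst_schedule(20, dur, min_sep_s = 2)
  x <- inject_gamma_bursts(x, fs, times, freq = 60, duration_ms = 80,
                           amplitude = 70)
  ev <- detect_gamma_episodes(lfp_trace(x, fs), "gamma")
  expect_identical(nrow(ev), length(times))
  d <- vapply(times, function(t) min(abs(ev$time_s - t)), numeric(1))
  expect_true(all(d <= 0.010))
  expect_true(all(diff(ev$time_s) >= 0.1 - 1e-9))
  expect_true(all(ev$window_s == 0.4))

  # two bursts 50 ms apart collapse to one episode
  set.seed(43)
  x2 <- pink_noise(20 * fs, fs, 1, 10)
  x2 <- inject_gamma_bursts(x2, fs, c(10, 10.05), freq = 60,
                            duration_ms = 40, amplitude = 80)
  ev2 <- detect_gamma_episodes(lfp_trace(x2, fs), "gamma")
  expect_identical(nrow(ev2), 1L)

  # relative threshold: detection invariant to voltage scaling
  ev_scaled <- detect_gamma_episodes(lfp_trace(1000 * x, fs), "gamma")
  expect_equal(ev_scaled$time_s, ev$time_s)

  expect_error(detect_gamma_episodes(lfp_trace(rnorm(1000), fs), "gamma"),
               "10 s")
})

test_that("episode rates are stable on stationary noise and add linearly", {
  set.seed(44)
  fs <- 500
  dur <- 600
  tr <- lfp_trace(rnorm(dur * fs), fs)
  ev <- detect_gamma_episodes(tr, "gamma")
  first <- sum(ev$time_s < dur / 2)
  second <- nrow(ev) - first
  expect_lt(max(first, second) / max(min(first, second), 1), 1.5)

  expect_equal(episode_rate(ev, dur), nrow(ev) / dur)
  empty <- ev[0, ]
  expect_equal(episode_rate(empty, 100), 0)
  # doubling the events doubles the rate
  expect_equal(episode_rate(rbind(ev, ev), dur), 2 * episode_rate(ev, dur))
  expect_error(episode_rate(ev, 0), "positive")
})
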