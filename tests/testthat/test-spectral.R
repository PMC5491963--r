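test_that("Morlet kernels have unit energy, correct width and peak frequency", {
  k <- morlet_kernel(7, 2000)
  expect_equal(sum(Mod(k)^2) / 2000, 1, tolerance = 1e-9)
  # ratio 7 forces sigma_f = 1 Hz at f = 7, i.e. sigma_t = 1/(2 pi)
  expect_equal(attr(k, "sigma_t"), 1 / (2 * pi), tolerance = 1e-12)
  expect_lt(Mod(mean(k)), 1e-3) # near-zero mean at ratio 7

  for (f in c(2, 3.5, 8, 40, 80)) {
    kf <- morlet_kernel(f, 2000)
    expect_equal(sum(Mod(kf)^2) / 2000, 1, tolerance = 1e-6)
    spec <- Mod(stats::fft(as.vector(kf)))
    grid <- (seq_along(kf) - 1) * 2000 / length(kf)
    peak <- grid[which.max(spec)]
    expect_lte(abs(peak - f), 2000 / length(kf)) # within one FFT grid step
  }
  expect_error(morlet_kernel(1200, 2000), "Nyquist")
})

test_that("wavelet power finds tone peaks where the periodogram does", {
  # zero signal -> all-zero power
  z <- wavelet_power(lfp_trace(rep(0, 4000), 2000), freqs = c(5, 10))
  expect_true(all(z$power == 0))
  expect_error(wavelet_power(lfp_trace(numeric(0), 2000), freqs = 5), "empty")

  fs <- 500
  tr <- tone_trace(8, 60, fs)
  freqs <- seq(2, 20, by = 0.5)
  tfr <- wavelet_power(tr, freqs)
  mean_p <- vapply(seq_along(freqs), function(i) {
    mean(tfr$power[i, thetagamma:::tfr_valid_idx(tfr, i)])
  }, numeric(1))
  # periodogram oracle for the peak frequency
  pg <- Mod(stats::fft(tr$samples))^2
  pg_grid <- (seq_along(pg) - 1) * fs / length(pg)
  half <- pg_grid < fs / 2
  pg_peak <- pg_grid[half][which.max(pg[half])]
  expect_equal(freqs[which.max(mean_p)], freqs[which.min(abs(freqs - pg_peak))])

  # two tones -> two local maxima at the nearest grid points
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  tr2 <- lfp_trace(cos(2 * pi * 3.5 * t) + cos(2 * pi * 40 * t), fs)
  freqs2 <- c(seq(2, 6, 0.5), seq(30, 50, 1))
  tfr2 <- wavelet_power(tr2, freqs2)
  mp2 <- vapply(seq_along(freqs2), function(i) {
    mean(tfr2$power[i, thetagamma:::tfr_valid_idx(tfr2, i)])
  }, numeric(1))
  low <- freqs2 <= 6
  expect_equal(freqs2[low][which.max(mp2[low])], 3.5)
  expect_equal(freqs2[!low][which.max(mp2[!low])], 40)
})

test_that("normalization divides by the reference-band mean exactly once", {
  set.seed(21)
  tr <- lfp_trace(rnorm(20000), 500)
  freqs <- seq(2, 40, by = 1)
  tfr <- wavelet_power(tr, freqs)
  ref <- c(5, 10)
  rows <- which(freqs >= ref[1] & freqs <= ref[2])
  manual <- mean(unlist(lapply(rows, function(i) {
    tfr$power[i, thetagamma:::tfr_valid_idx(tfr, i)]
  })))
  ntfr <- normalize_power(tfr, ref)
  expect_equal(ntfr$power, tfr$power / manual)
  expect_true(ntfr$normalized)
  # self-normalization: reference-band mean of normalized power is 1
  expect_equal(band_power(ntfr, ref), 1, tolerance = 1e-9)
  expect_error(normalize_power(ntfr, ref), "already normalized")
  expect_error(normalize_power(tfr, c(200, 300)), "no frequency rows")
})

test_that("band power averages bands, honors masks, and sees gamma bursts", {
  tfr <- thetagamma:::new_tfr(matrix(1, 5, 100), freqs = 1:5,
                              times = (0:99) / 10, fs = 10,
                              n_edge = rep(0L, 5))
  expect_equal(band_power(tfr, c(2, 4)), 1)
  # time-constant rows: masking half the bins leaves the mean unchanged
  sym <- thetagamma:::new_tfr(matrix(c(1, 3), 2, 100),
                              freqs = 1:2, times = (0:99) / 10, fs = 10,
                              n_edge = rep(0L, 2))
  m <- rep(c(TRUE, FALSE), 50)
  expect_equal(band_power(sym, c(1, 2), m), band_power(sym, c(1, 2)))
  expect_error(band_power(sym, c(1, 2), rep(FALSE, 100)), "no valid samples")

  set.seed(22)
  fs <- 500
  noise <- pink_noise(30 * fs, fs, 1, 10)
  with_bursts <- inject_gamma_bursts(noise, fs, seq(2, 28, by = 0.5),
                                     freq = 60, amplitude = 40)
  freqs <- seq(30, 100, by = 5)
  p0 <- band_power(wavelet_power(lfp_trace(noise, fs), freqs), c(30, 100))
  p1 <- band_power(wavelet_power(lfp_trace(with_bursts, fs), freqs),
                   c(30, 100))
  expect_gt(p1, p0)
  # oracle: bandpass RMS shows the same ordering
  spec <- default_band_specs()$gamma
  expect_gt(mid_rms(bandpass(lfp_trace(with_bursts, fs), spec)$samples),
            mid_rms(bandpass(lfp_trace(noise, fs), spec)$samples))
})

test_that("voltage scaling scales raw power by c^2, normalized power not at all", {
  set.seed(23)
  x <- rnorm(10000)
  freqs <- seq(2, 30, by = 2)
  t1 <- wavelet_power(lfp_trace(x, 500), freqs)
  t3 <- wavelet_power(lfp_trace(3 * x, 500), freqs)
  expect_equal(t3$power, 9 * t1$power, tolerance = 1e-10)
  n1 <- normalize_power(t1, c(5, 10))
  n3 <- normalize_power(t3, c(5, 10))
  expect_equal(n3$power, n1$power, tolerance = 1e-10)
  # stationary-signal proportionality: total power tracks signal variance
  s1 <- sum(t1$power)
  s3 <- sum(t3$power)
  expect_equal(s3 / s1, 9, tolerance = 1e-10)
})

test_that("trigger-averaged spectra localize injected bursts and stay flat on noise", {
  fs <- 1000
  # single trigger: the average equals that window's power
  set.seed(24)
  x <- pink_noise(10 * fs, fs, 1, 5)
  tr <- lfp_trace(x, fs)
  freqs <- seq(30, 100, by = 10)
  one <- theta_triggered_tfr(tr, 5, freqs = freqs, window = c(-0.2, 0.2))
  full <- wavelet_power(tr, freqs)
  j0 <- round(5 * fs) + 1L
  rel <- seq(round(-0.2 * fs), round(0.2 * fs))
  expect_equal(one$power, full$power[, j0 + rel], tolerance = 1e-10)
  expect_equal(one$n_triggers, 1L)

  # bursts injected 60 ms after each trigger show up at that latency
  dur <- 120
  x2 <- 100 * cos(2 * pi * 3.5 * (0:(dur * fs - 1)) / fs) +
    pink_noise(dur * fs, fs, 1, 10)
  troughs <- seq(5, dur - 5, by = 1 / 3.5) + 1 / 7
  x2 <- inject_gamma_bursts(x2, fs, troughs + 0.060, freq = 60,
                            duration_ms = 60, amplitude = 60)
  tfr <- theta_triggered_tfr(lfp_trace(x2, fs), troughs,
                             freqs = seq(30, 100, 2), window = c(-0.25, 0.25))
  gm <- colMeans(tfr$power)
  expect_lte(abs(tfr$times[which.max(gm)] - 0.060), 1 / fs)

  # triggers on pure noise: gamma-row profile flat within 3 SEM
  set.seed(25)
  xg <- pink_noise(60 * fs, fs, 1, 20)
  trg <- seq(2, 58, by = 0.28) # 200 triggers
  trn <- lfp_trace(xg, fs)
  fr <- seq(30, 100, by = 10)
  full_p <- wavelet_power(trn, fr)
  relw <- seq(round(-0.2 * fs), round(0.2 * fs))
  idx0 <- round(trg * fs) + 1L
  per_trig <- vapply(idx0, function(j) {
    colMeans(full_p$power[, j + relw, drop = FALSE])
  }, numeric(length(relw)))
  mu <- rowMeans(per_trig)
  sem <- apply(per_trig, 1, stats::sd) / sqrt(ncol(per_trig))
  probe <- seq(1, length(relw), by = 40) # spaced beyond the wavelet width
  expect_true(all(abs(mu[probe] - mean(mu)) <= 3 * sem[probe]))

  expect_error(theta_triggered_tfr(trn, 1000, freqs = fr), "no trigger")
})
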