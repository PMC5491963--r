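test_that("waveform widths are recovered from constructed spikes", {
  fsw <- 32000
  t_us <- (0:31) / fsw * 1e6
  # triangular spike: peak at 300 us, trough at 600 us
  wf <- pmax(0, 1 - abs(t_us - 300) / 120) -
    pmax(0, 0.6 * (1 - abs(t_us - 600) / 150))
  f <- waveform_features(spike_unit("tri", 0.1, mean_waveform = wf))
  expect_lte(abs(f$peak_trough_width_us - 300), 1e6 / fsw)

  # Gaussian bump: half-max width is the analytic FWHM
  sig <- 120
  bump <- exp(-(t_us - 400)^2 / (2 * sig^2))
  fg <- waveform_features(spike_unit("g", 0.1, mean_waveform = bump))
  expect_lte(abs(fg$half_max_width_us - 2 * sig * sqrt(2 * log(2))),
             1e6 / fsw)

  # upsampled waveform gives the same widths within one original sample
  w0 <- thetagamma:::make_waveform(320, fsw)
  up <- stats::approx(seq_along(w0), w0, n = 4 * length(w0))$y
  f0 <- waveform_features(spike_unit("a", 0.1, mean_waveform = w0,
                                     waveform_fs = fsw))
  f4 <- waveform_features(spike_unit("b", 0.1, mean_waveform = up,
                                     waveform_fs = 4 * fsw))
  expect_lte(abs(f0$peak_trough_width_us - f4$peak_trough_width_us),
             1e6 / fsw)
  expect_lte(abs(f0$half_max_width_us - f4$half_max_width_us), 1e6 / fsw)

  # multi-channel: the largest-amplitude channel is used
  m <- rbind(0.1 * w0, w0, 0.5 * w0, 0.2 * w0)
  fm <- waveform_features(spike_unit("tet", 0.1, mean_waveform = m,
                                     waveform_fs = fsw))
  expect_identical(fm$channel_used, 2L)

  expect_error(waveform_features(spike_unit("flat", 0.1,
                                            mean_waveform = rep(1, 32))),
               "degenerate")
})

test_that("units are classified by the 230 us peak-trough threshold", {
  expect_identical(classify_unit(300), "pyramidal")
  expect_identical(classify_unit(150), "interneuron")
  expect_identical(classify_unit(230), "unclassified")
  f <- waveform_features(spike_unit("w", 0.1,
                                    mean_waveform = thetagamma:::make_waveform(330)))
  expect_identical(classify_unit(f), "pyramidal")
})

test_that("firing rates count masked spikes over masked time", {
  fs <- 1000
  mask <- rep(TRUE, 10 * fs)
  u <- spike_unit("u", seq(0.05, 9.95, length.out = 100))
  expect_equal(firing_rate(u, mask, fs), 10)
  expect_equal(firing_rate(spike_unit("e", numeric(0)), mask, fs), 0)
  half <- c(rep(TRUE, 5 * fs), rep(FALSE, 5 * fs))
  expect_equal(firing_rate(u, half, fs), sum(u$spike_times < 5) / 5)
  expect_error(firing_rate(u, rep(FALSE, 100), fs), "zero duration")

  # Poisson spikes at 6.5 Hz over 600 s recover the rate within 0.5 Hz
  set.seed(61)
  dur <- 600
  n <- rpois(1, 6.5 * dur)
  up <- spike_unit("p", sort(runif(n, 0, dur)))
  expect_lte(abs(firing_rate(up, rep(TRUE, dur * fs), fs) - 6.5), 0.5)
})

test_that("the Rayleigh test is exact at its landmarks", {
  expect_lt(rayleigh_test(rep(10, 20))$p.value, 1e-6)
  expect_equal(rayleigh_test(seq(0, 330, by = 30))$p.value, 1)
  expect_error(rayleigh_test(c(1, 2, 3)), "at least 5")
  rt <- rayleigh_test(rvonmises(200, 90, 2))
  expect_true(rt$p.value > 0 && rt$p.value <= 1)
  expect_s3_class(rt, "htest")
})

test_that("spike locking recovers constructed and null phase preferences", {
  fs <- 1000
  t <- seq(0, 200 - 1 / fs, by = 1 / fs)
  gph <- instantaneous_phase(lfp_trace(cos(2 * pi * 40 * t), fs))

  # spikes planted at every gamma trough lock at 180 degrees
  troughs <- seq(1, 199, by = 1 / 40) + 1 / 80
  u <- spike_unit("locked", troughs)
  row <- spike_phase_locking(u, gph, fs, reference = "gamma")
  expect_gt(row$vector_length, 0.95)
  expect_lte(circ_diff_deg(row$vector_angle_deg, 180), 5)
  expect_true(row$phase_locked)

  # phase-independent Poisson spikes do not lock
  set.seed(62)
  un <- spike_unit("null", sort(runif(5000, 1, 199)))
  row_n <- spike_phase_locking(un, gph, fs, reference = "gamma")
  expect_lt(row_n$vector_length, 0.03)
  expect_false(isTRUE(row_n$rayleigh_p < 1e-4))

  # von Mises modulation at kappa = 1 recovers the Bessel-ratio length
  set.seed(63)
  lam_max <- exp(1) / besselI(1, 0)
  cand <- sort(runif(rpois(1, 25 * lam_max * 198), 1, 199))
  lam <- exp(cos(2 * pi * 40 * cand - pi / 2)) / besselI(1, 0)
  spikes <- cand[runif(length(cand)) < lam / lam_max][1:5000]
  row_v <- spike_phase_locking(spike_unit("vm", spikes), gph, fs,
                               reference = "gamma")
  expect_identical(row_v$n_spikes, 5000L)
  expect_lte(abs(row_v$vector_length - bessel_ratio(1)), 0.03)

  # translation invariance: shifting spikes and phases together
  shift <- 5
  gph_s <- c(gph[(shift * fs + 1):length(gph)], gph[1:(shift * fs)])
  u_s <- spike_unit("shift", troughs[troughs < 194])
  r1 <- spike_phase_locking(spike_unit("o", troughs[troughs < 194] + shift),
                            gph, fs)
  r2 <- spike_phase_locking(u_s, gph_s, fs)
  expect_equal(r1$vector_length, r2$vector_length, tolerance = 1e-3)

  # too few spikes -> skipped with a reason, not an error
  sk <- spike_phase_locking(spike_unit("few", c(1, 2, 3)), gph, fs)
  expect_true(is.na(sk$vector_length))
  expect_match(sk$note, "min_spikes")
})
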