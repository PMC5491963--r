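# Zero-phase bandpass filtering, instantaneous phase, theta-cycle selection,
# and gamma oscillation-episode detection.

new_event_set <- function(kind, time_s, amplitude, band_lo, band_hi, window_s,
                          ...) {
  es <- tibble::tibble(
    kind = kind,
    time_s = time_s,
    amplitude = amplitude,
    band_lo = band_lo,
    band_hi = band_hi,
    window_s = window_s
  )
  es <- tibble::new_tibble(es, class = "tg_event_set")
  extras <- list(...)
  for (nm in names(extras)) attr(es, nm) <- extras[[nm]]
  es
}

#' Zero-phase FIR bandpass filter
#'
#' Acausal (zero phase shift) frequency-domain finite-impulse-response
#' bandpass: the frequency response is zero at and beyond the stopband
#' corners, one across the passband, with raised-cosine transitions between
#' the corner pairs. The real, even response is applied by FFT on a
#' zero-padded copy of the trace, so no phase is introduced at any frequency.
#'
#' @param trace A [lfp_trace()].
#' @param spec A [band_spec()] with `stop_hi` below Nyquist.
#' @return A filtered [lfp_trace()] (same sampling rate and metadata).
#' @export
bandpass <- function(trace, spec) {
  x <- trace$samples
  fs <- trace$fs
  n <- length(x)
  if (n == 0L) stop("empty input trace", call. = FALSE)
  if (spec$stop_hi >= fs / 2) {
    stop(sprintf("stopband edge %g Hz is at or above Nyquist (%g Hz)",
                 spec$stop_hi, fs / 2), call. = FALSE)
  }
  tw <- min(spec$pass_lo - spec$stop_lo, spec$stop_hi - spec$pass_hi)
  nfft <- next_fft_size(n + ceiling(8 * fs / tw))
  f <- (seq_len(nfft) - 1L) * fs / nfft
  fm <- pmin(f, fs - f) # mirrored grid keeps H real and even
  H <- numeric(nfft)
  rise <- fm > spec$stop_lo & fm < spec$pass_lo
  H[rise] <- 0.5 * (1 - cos(pi * (fm[rise] - spec$stop_lo) /
                              (spec$pass_lo - spec$stop_lo)))
  H[fm >= spec$pass_lo & fm <= spec$pass_hi] <- 1
  fall <- fm > spec$pass_hi & fm < spec$stop_hi
  H[fall] <- 0.5 * (1 + cos(pi * (fm[fall] - spec$pass_hi) /
                              (spec$stop_hi - spec$pass_hi)))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  y <- Re(stats::fft(X * H, inverse = TRUE) / nfft)[seq_len(n)]
  out <- trace
  out$samples <- y
  attr(out, "band") <- spec
  out
}

#' Instantaneous phase of a band-limited trace
#'
#' Angle of the Hilbert analytic signal, reported in degrees on `[0, 360)`
#' with the oscillation peak defined as 0 degrees (so a cosine has phase 0 at
#' its peaks and 180 at its troughs).
#'
#' @param filtered A bandpass-filtered [lfp_trace()].
#' @return Numeric vector of phases in degrees.
#' @export
instantaneous_phase <- function(filtered) {
  x <- filtered$samples
  if (length(x) == 0L || max(abs(x)) < .Machine$double.eps) {
    stop("phase is undefined for an all-zero signal", call. = FALSE)
  }
  wrap_deg(rad2deg(Arg(analytic_signal(x))))
}

#' Detect theta troughs and select theta cycles
#'
#' Finds strict local minima of the theta-filtered signal
#' (`x(t-1) > x(t)` and `x(t+1) > x(t)`), keeps minima that bound a cycle
#' whose trough-to-trough period lies in the accepted range for a ~3.5 Hz
#' theta cycle (default `[1/4.5, 1/2.5]` s, the filter passband inverted),
#' and enforces a minimum separation of 200 ms between retained troughs
#' (the deeper trough of a conflicting pair wins).
#'
#' @param filtered_theta Theta-bandpassed [lfp_trace()] (see [bandpass()]).
#' @param cfg An [analysis_config()].
#' @return A `tg_event_set` tibble of kind `"theta_trough"`; empty (zero
#'   rows) when no qualifying minima exist.
#' @export
detect_theta_troughs <- function(filtered_theta, cfg = analysis_config()) {
  x <- filtered_theta$samples
  fs <- filtered_theta$fs
  n <- length(x)
  empty <- function() {
    new_event_set(character(), numeric(), numeric(), numeric(), numeric(),
                  numeric())
  }
  if (n < 3L) return(empty())
  i <- 2L:(n - 1L)
  mins <- which(x[i] < x[i - 1L] & x[i] < x[i + 1L]) + 1L
  if (length(mins) < 2L) return(empty())
  tmin <- (mins - 1L) / fs
  d <- diff(tmin)
  rng <- cfg$theta_cycle_range_s
  cyc <- which(d >= rng[1] & d <= rng[2])
  keep <- sort(unique(c(mins[cyc], mins[cyc + 1L])))
  if (length(keep) == 0L) return(empty())
  # minimum-separation rule: deeper trough (more negative) wins conflicts
  sep <- cfg$theta_trough_separation_ms / 1000 * fs
  ord <- keep[order(x[keep], keep)]
  accepted <- integer(0)
  for (j in ord) {
    if (length(accepted) == 0L || all(abs(j - accepted) >= sep)) {
      accepted <- c(accepted, j)
    }
  }
  accepted <- sort(accepted)
  new_event_set(
    kind = rep("theta_trough", length(accepted)),
    time_s = (accepted - 1L) / fs,
    amplitude = x[accepted],
    band_lo = rep(cfg$theta_band[1], length(accepted)),
    band_hi = rep(cfg$theta_band[2], length(accepted)),
    window_s = rep(NA_real_, length(accepted))
  )
}

#' Detect gamma oscillation episodes
#'
#' Implements threshold-based episode detection on band-averaged wavelet
#' power: (1) time-varying power averaged across the band's frequencies;
#' (2) threshold at mean + `episode_sd_threshold` SD of that series over the
#' whole valid trace; (3) supra-threshold time points collected; (4) 160-ms
#' windows cut (centered) around them; (5) within each window the amplitude
#' maximum of the band-filtered signal located (absolute value; ties go to
#' the earliest sample); (6) identical maxima discarded; (7) retained maxima
#' separated by at least 100 ms, the larger-amplitude of any conflicting pair
#' winning; (8) events outside `restrict_mask` dropped. Each retained event
#' carries a 400-ms analysis window. The threshold is relative, so detection
#' is invariant to overall voltage scaling.
#'
#' @param trace A [lfp_trace()], at least 10 s long.
#' @param band A [band_spec()] or the name of one in `cfg$band_specs`
#'   (default `"gamma"`).
#' @param cfg An [analysis_config()].
#' @param restrict_mask Optional per-sample logical mask (e.g. theta states
#'   from [state_mask()]); events outside it are dropped after detection.
#' @return A `tg_event_set` tibble of kind `"gamma_maximum"` with attributes
#'   `threshold`, `n_supra` and `band_name`. May have zero rows.
#' @export
detect_gamma_episodes <- function(trace, band = "gamma",
                                  cfg = analysis_config(),
                                  restrict_mask = NULL) {
  spec <- resolve_band(band, cfg)
  x <- trace$samples
  fs <- trace$fs
  n <- length(x)
  if (n / fs < 10) {
    stop("trace must be at least 10 s long for episode detection",
         call. = FALSE)
  }
  if (spec$stop_hi >= fs / 2) {
    stop("band exceeds Nyquist", call. = FALSE)
  }
  freqs <- seq(spec$pass_lo, spec$pass_hi, by = cfg$episode_freq_step_hz)
  bs <- wavelet_band_series(x, fs, freqs, cfg$wavelet_ratio)
  p <- bs$power
  e <- bs$n_edge
  valid <- (e + 1L):(n - e)
  mu <- mean(p[valid])
  thr <- mu + cfg$episode_sd_threshold * stats::sd(p[valid])
  half_w <- round(cfg$episode_window_ms / 1000 * fs / 2)
  supra <- valid[p[valid] > thr]
  supra <- supra[supra > half_w & supra <= n - half_w]
  amp <- abs(bandpass(trace, spec)$samples)
  empty <- function() {
    new_event_set(character(), numeric(), numeric(), numeric(), numeric(),
                  numeric(), threshold = thr, n_supra = length(supra),
                  band_name = spec$name)
  }
  if (length(supra) == 0L) return(empty())
  wam <- rolling_argmax(amp, half_w)
  cand <- unique(wam[supra])
  cand <- cand[!is.na(cand)]
  if (length(cand) == 0L) return(empty())
  # non-maximum suppression at the separation rule: larger amplitude first,
  # earliest time breaking amplitude ties, then re-check remaining
  sep <- cfg$episode_separation_ms / 1000 * fs
  cand <- cand[order(-amp[cand], cand)]
  accepted <- integer(0)
  for (j in cand) {
    if (length(accepted) == 0L || all(abs(j - accepted) >= sep)) {
      accepted <- c(accepted, j)
    }
  }
  accepted <- sort(accepted)
  if (!is.null(restrict_mask)) {
    if (length(restrict_mask) < n) {
      restrict_mask <- c(restrict_mask,
                         rep(FALSE, n - length(restrict_mask)))
    }
    accepted <- accepted[restrict_mask[accepted]]
  }
  new_event_set(
    kind = rep("gamma_maximum", length(accepted)),
    time_s = (accepted - 1L) / fs,
    amplitude = amp[accepted],
    band_lo = rep(spec$pass_lo, length(accepted)),
    band_hi = rep(spec$pass_hi, length(accepted)),
    window_s = rep(cfg$episode_crop_ms / 1000, length(accepted)),
    threshold = thr, n_supra = length(supra), band_name = spec$name
  )
}

#' Episode emergence rate
#'
#' Events per second of analyzed (e.g. theta-state) time.
#'
#' @param events A `tg_event_set`.
#' @param mask_duration_s Total analyzed duration in seconds (> 0).
#' @return Rate in events per second.
#' @export
episode_rate <- function(events, mask_duration_s) {
  if (mask_duration_s <= 0) {
    stop("mask_duration_s must be positive", call. = FALSE)
  }
  nrow(events) / mask_duration_s
}
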