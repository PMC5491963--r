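# Complex Morlet wavelet time-frequency decomposition and power summaries.

#' Complex Morlet wavelet kernel
#'
#' Generates the unit-energy complex Morlet wavelet
#' `w(t, f) = A exp(-t^2 / (2 sigma_t^2)) exp(2 i pi f t)` with
#' `sigma_f = 1 / (2 pi sigma_t)` and `A = (sigma_t sqrt(pi))^(-1/2)`, the
#' family being characterized by a constant ratio `f / sigma_f` (default 7).
#' Support is truncated at +/- 4 sigma_t (which carries > 99.99% of the
#' energy) and the discrete energy `sum(|w|^2) / fs` is renormalized to
#' exactly 1 after truncation.
#'
#' @param f Centre frequency (Hz), `0 < f < fs/2`.
#' @param fs Sampling rate (Hz).
#' @param ratio Constant `f / sigma_f`.
#' @return Complex vector of kernel samples with attributes `f`, `fs`,
#'   `sigma_t` (s).
#' @examples
#' k <- morlet_kernel(7, 2000)
#' sum(Mod(k)^2) / 2000 # 1
#' @export
morlet_kernel <- function(f, fs, ratio = 7) {
  if (f <= 0) stop("frequency must be positive", call. = FALSE)
  if (f >= fs / 2) {
    stop(sprintf("frequency %g Hz is at or above Nyquist (%g Hz)", f, fs / 2),
         call. = FALSE)
  }
  sigma_f <- f / ratio
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(4 * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  w <- w * (sigma_t * sqrt(pi))^(-1 / 2)
  w <- w / sqrt(sum(Mod(w)^2) / fs)
  attr(w, "f") <- f
  attr(w, "fs") <- fs
  attr(w, "sigma_t") <- sigma_t
  w
}

# Convolve a real signal with a family of Morlet kernels, calling
# row_fun(power, f_index, n_edge) with the centred |conv|^2 series for each
# frequency. One forward FFT of the signal is shared across frequencies.
wavelet_apply <- function(x, fs, freqs, ratio, row_fun) {
  n <- length(x)
  if (n == 0L) stop("empty input trace", call. = FALSE)
  if (any(freqs >= fs / 2)) {
    stop("all analysis frequencies must be below Nyquist", call. = FALSE)
  }
  kernels <- lapply(freqs, morlet_kernel, fs = fs, ratio = ratio)
  nk_max <- max(lengths(kernels))
  nfft <- next_fft_size(n + nk_max - 1L)
  xf <- stats::fft(c(x, rep(0, nfft - n)))
  for (i in seq_along(kernels)) {
    k <- kernels[[i]]
    nk <- length(k)
    half <- (nk - 1L) %/% 2L
    kf <- stats::fft(c(k, rep(0 + 0i, nfft - nk)))
    y <- stats::fft(xf * kf, inverse = TRUE) / nfft
    p <- Mod(y[(half + 1L):(half + n)])^2
    row_fun(p, i, half)
  }
  invisible(NULL)
}

# Band-averaged time-varying wavelet power: the mean over `freqs` of the
# per-frequency power series, with the common invalid edge (max over
# frequencies of 4 sigma_t in samples).
wavelet_band_series <- function(x, fs, freqs, ratio = 7) {
  acc <- numeric(length(x))
  edge <- 0L
  wavelet_apply(x, fs, freqs, ratio, function(p, i, half) {
    acc <<- acc + p
    edge <<- max(edge, as.integer(half))
  })
  list(power = acc / length(freqs), n_edge = edge)
}

new_tfr <- function(power, freqs, times, fs, n_edge, normalized = FALSE,
                    reference_band = NULL, n_triggers = NULL) {
  structure(
    list(power = power, freqs = freqs, times = times, fs = fs,
         n_edge = n_edge, normalized = normalized,
         reference_band = reference_band, n_triggers = n_triggers),
    class = "tg_tfr"
  )
}

#' @export
print.tg_tfr <- function(x, ...) {
  cat(sprintf(
    "<tg_tfr> %d freqs (%g-%g Hz) x %d times (%.3f-%.3f s)%s%s\n",
    length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
    min(x$times), max(x$times),
    if (x$normalized) sprintf(", normalized to %g-%g Hz",
                              x$reference_band[1], x$reference_band[2]) else "",
    if (!is.null(x$n_triggers)) sprintf(", averaged over %d triggers",
                                        x$n_triggers) else ""))
  invisible(x)
}

# Logical matrix-free validity lookup: valid time indices for frequency row i.
tfr_valid_idx <- function(tfr, i) {
  nt <- length(tfr$times)
  e <- tfr$n_edge[i]
  if (2L * e >= nt) return(integer(0))
  (e + 1L):(nt - e)
}

#' Wavelet time-frequency power of a trace
#'
#' Convolves the trace with a family of complex Morlet wavelets (one per
#' frequency) and returns squared-magnitude power indexed
#' `[frequency, time]`. Convolution uses zero padding; samples within
#' 4 sigma_t of either trace edge are flagged invalid per frequency (the
#' `n_edge` field) and excluded from all downstream statistics.
#'
#' @param trace A [lfp_trace()].
#' @param freqs Increasing Hz grid, all below Nyquist.
#' @param ratio Morlet constant `f / sigma_f`.
#' @param decimate_by Optional integer factor: retain every k-th time sample
#'   (display/memory convenience; compute band statistics before decimating).
#' @return A `tg_tfr` object: `power` (freq x time matrix), `freqs`, `times`,
#'   `fs`, per-frequency invalid-edge sample counts `n_edge`, and
#'   normalization state.
#' @export
wavelet_power <- function(trace, freqs, ratio = 7, decimate_by = 1L) {
  x <- trace$samples
  fs <- trace$fs
  n <- length(x)
  if (n == 0L) stop("empty input trace", call. = FALSE)
  if (is.unsorted(freqs, strictly = TRUE)) {
    stop("freqs must be strictly increasing", call. = FALSE)
  }
  pw <- matrix(0, nrow = length(freqs), ncol = n)
  edges <- integer(length(freqs))
  wavelet_apply(x, fs, freqs, ratio, function(p, i, half) {
    pw[i, ] <<- p
    edges[i] <<- as.integer(half)
  })
  times <- (seq_len(n) - 1L) / fs
  tfr <- new_tfr(pw, freqs, times, fs, edges)
  if (decimate_by > 1L) {
    keep <- seq(1L, n, by = as.integer(decimate_by))
    tfr$power <- tfr$power[, keep, drop = FALSE]
    tfr$times <- tfr$times[keep]
    tfr$n_edge <- pmax(0L, as.integer(ceiling(tfr$n_edge / decimate_by)))
    tfr$fs <- fs / decimate_by
  }
  tfr
}

#' Normalize a time-frequency matrix to a reference band
#'
#' Divides every entry by the scalar mean power over the reference-band
#' frequency rows (valid time points only). Normalizing to the 5-10 Hz band
#' controls for impedance differences between electrodes.
#'
#' @param tfr A `tg_tfr` from [wavelet_power()], not already normalized.
#' @param reference_band Hz pair inside the frequency range of `tfr`.
#' @return The normalized (dimensionless) `tg_tfr`.
#' @export
normalize_power <- function(tfr, reference_band = c(5, 10)) {
  if (isTRUE(tfr$normalized)) {
    stop("time-frequency matrix is already normalized", call. = FALSE)
  }
  rows <- which(tfr$freqs >= reference_band[1] & tfr$freqs <= reference_band[2])
  if (length(rows) == 0L) {
    stop("reference band contains no frequency rows", call. = FALSE)
  }
  tot <- 0
  cnt <- 0
  for (i in rows) {
    v <- tfr_valid_idx(tfr, i)
    tot <- tot + sum(tfr$power[i, v])
    cnt <- cnt + length(v)
  }
  ref <- tot / cnt
  if (!is.finite(ref) || ref <= 0) {
    stop("degenerate reference: mean reference-band power is zero",
         call. = FALSE)
  }
  tfr$power <- tfr$power / ref
  tfr$normalized <- TRUE
  tfr$reference_band <- reference_band
  tfr
}

#' Mean power in a frequency band
#'
#' Mean of the time-frequency power over the band's frequency rows and the
#' unmasked, valid time points.
#'
#' @param tfr A `tg_tfr`.
#' @param band Hz pair inside the frequency range of `tfr`.
#' @param time_mask Optional logical vector over `tfr$times`; `TRUE` samples
#'   are included.
#' @return Scalar mean power.
#' @export
band_power <- function(tfr, band, time_mask = NULL) {
  rows <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  if (length(rows) == 0L) {
    stop("band contains no frequency rows", call. = FALSE)
  }
  if (!is.null(time_mask) && length(time_mask) != length(tfr$times)) {
    stop("time_mask length must match the time grid", call. = FALSE)
  }
  tot <- 0
  cnt <- 0
  for (i in rows) {
    v <- tfr_valid_idx(tfr, i)
    if (!is.null(time_mask)) v <- v[time_mask[v]]
    tot <- tot + sum(tfr$power[i, v])
    cnt <- cnt + length(v)
  }
  if (cnt == 0L) stop("selection contains no valid samples", call. = FALSE)
  tot / cnt
}

#' Theta-trough-triggered time-frequency representation
#'
#' Cuts a window around each theta trough and averages the wavelet power
#' elementwise across triggers, yielding the mean time-resolved spectrum of a
#' theta cycle (trough at t = 0). Power is computed in 2-Hz-wide bands by
#' default (centres every 2 Hz from 3 to 139 Hz). Triggers whose window
#' exceeds the trace bounds are skipped and counted.
#'
#' @param trace A [lfp_trace()].
#' @param trough_times Trigger times in seconds (e.g. from
#'   [detect_theta_troughs()]).
#' @param freqs Band-centre grid in Hz.
#' @param window Length-2 window around each trigger in seconds.
#' @param ratio Morlet constant.
#' @return A `tg_tfr` whose time axis is relative to the trigger; the number
#'   of usable triggers is in `n_triggers` and skipped triggers in the
#'   `n_skipped` attribute.
#' @export
theta_triggered_tfr <- function(trace, trough_times,
                                freqs = seq(3, 139, by = 2),
                                window = c(-0.5, 0.5), ratio = 7) {
  x <- trace$samples
  fs <- trace$fs
  n <- length(x)
  rel <- seq(round(window[1] * fs), round(window[2] * fs))
  idx0 <- round(trough_times * fs) + 1L
  usable <- idx0 + rel[1] >= 1L & idx0 + rel[length(rel)] <= n
  n_skipped <- sum(!usable)
  idx0 <- idx0[usable]
  if (length(idx0) == 0L) {
    stop("no trigger has a full window inside the trace", call. = FALSE)
  }
  out <- matrix(0, nrow = length(freqs), ncol = length(rel))
  edges <- integer(length(freqs))
  wavelet_apply(x, fs, freqs, ratio, function(p, i, half) {
    win <- vapply(idx0, function(j) p[j + rel], numeric(length(rel)))
    out[i, ] <<- rowMeans(win)
    edges[i] <<- 0L
  })
  tfr <- new_tfr(out, freqs, rel / fs, fs, edges,
                 n_triggers = length(idx0))
  attr(tfr, "n_skipped") <- n_skipped
  tfr
}
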