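# Theta / slow-wave brain-state segmentation of anesthetized recordings.

#' Segment a recording into theta and slow-wave states
#'
#' Divides the trace into contiguous 10-s bins (final partial bin dropped)
#' and, for each bin, computes the ratio of mean raw wavelet power in the
#' theta band (2.5-4.5 Hz) to that in the slow-wave band (0.5-1.5 Hz). Bins
#' with ratio >= 1 are theta states; bins with ratio < 1 are slow-wave
#' states. Per-bin band power is the mean over band frequencies (spaced
#' `cfg$state_freq_step_hz`) of valid (non-edge) samples in the bin; labels
#' depend only on the ratio, so they are invariant to voltage scaling and to
#' power normalization.
#'
#' @param trace A [lfp_trace()] of duration at least `3 * cfg$state_bin_s`.
#' @param cfg An [analysis_config()].
#' @return A `tg_state_segmentation` tibble with one row per bin: `bin`,
#'   `bin_start_s`, `bin_end_s`, `theta_power`, `slow_power`, `ratio`,
#'   `label`. Attributes carry the trace sampling rate and length so that
#'   [state_mask()] can align sample-level masks.
#' @export
segment_states <- function(trace, cfg = analysis_config()) {
  x <- trace$samples
  fs <- trace$fs
  n <- length(x)
  bin_len <- round(cfg$state_bin_s * fs)
  nbins <- n %/% bin_len
  if (nbins < 3L) {
    stop(sprintf(
      "insufficient duration: %.1f s < %g s (3 state bins) required",
      n / fs, 3 * cfg$state_bin_s), call. = FALSE)
  }
  used <- nbins * bin_len
  bin_of <- rep(seq_len(nbins), each = bin_len)

  bin_mean <- function(band) {
    freqs <- seq(band[1], band[2], by = cfg$state_freq_step_hz)
    bs <- wavelet_band_series(x, fs, freqs, cfg$wavelet_ratio)
    e <- bs$n_edge
    ok <- rep(FALSE, n)
    ok[(e + 1L):(n - e)] <- TRUE
    ok <- ok[seq_len(used)]
    sums <- rowsum(bs$power[seq_len(used)][ok], bin_of[ok])
    cnts <- tabulate(bin_of[ok], nbins)
    out <- rep(NA_real_, nbins)
    out[as.integer(rownames(sums))] <- sums[, 1]
    out / cnts
  }

  theta_p <- bin_mean(cfg$theta_band)
  slow_p <- bin_mean(cfg$slow_band)
  ratio <- theta_p / slow_p
  seg <- tibble::tibble(
    bin = seq_len(nbins),
    bin_start_s = (seq_len(nbins) - 1L) * cfg$state_bin_s,
    bin_end_s = seq_len(nbins) * cfg$state_bin_s,
    theta_power = theta_p,
    slow_power = slow_p,
    ratio = ratio,
    label = ifelse(ratio >= 1, "theta", "slow")
  )
  seg <- tibble::new_tibble(seg, class = "tg_state_segmentation")
  attr(seg, "fs") <- fs
  attr(seg, "n_samples") <- n
  attr(seg, "bin_len") <- bin_len
  seg
}

#' Emergence rate of a state
#'
#' Fraction of 10-s bins labeled with the given state.
#'
#' @param seg A segmentation from [segment_states()].
#' @param state `"theta"` or `"slow"`.
#' @return Fraction in `[0, 1]`.
#' @export
emergence_rate <- function(seg, state = "theta") {
  if (nrow(seg) == 0L) stop("empty segmentation", call. = FALSE)
  mean(seg$label == state)
}

#' Sample-level mask for a state
#'
#' Expands bin labels to a per-sample logical mask aligned with the
#' originating trace; samples of the dropped partial final bin are `FALSE`.
#'
#' @param seg A segmentation from [segment_states()].
#' @param state `"theta"` or `"slow"`.
#' @param fs Sampling rate; must match the trace the segmentation came from.
#' @return Logical vector of the original trace length.
#' @export
state_mask <- function(seg, state = "theta", fs = attr(seg, "fs")) {
  if (!isTRUE(all.equal(fs, attr(seg, "fs")))) {
    stop("fs does not match the segmented trace", call. = FALSE)
  }
  n <- attr(seg, "n_samples")
  bin_len <- attr(seg, "bin_len")
  mask <- rep(FALSE, n)
  hit <- rep(seg$label == state, each = bin_len)
  mask[seq_along(hit)] <- hit
  mask
}
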