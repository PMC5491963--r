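# Theta-gamma cross-frequency coupling: theta phases of gamma maxima, phase
# histograms, and resultant-vector coupling strength.

#' Sample a phase series at event times
#'
#' Looks up the instantaneous phase at the LFP sample nearest each event
#' time. Events outside the phase-series support are dropped and counted in
#' the `n_dropped` attribute.
#'
#' @param phase_series Numeric vector of phases in degrees (from
#'   [instantaneous_phase()]).
#' @param fs Sampling rate of the phase series (Hz).
#' @param event_times Event times in seconds.
#' @param event_kind Label stored with each sample (`"gamma_maximum"` or
#'   `"spike"`).
#' @return A tibble with columns `time_s`, `phase_deg`, `event_kind`.
#' @export
phases_at_events <- function(phase_series, fs, event_times,
                             event_kind = "gamma_maximum") {
  idx <- round(event_times * fs) + 1L
  ok <- idx >= 1L & idx <= length(phase_series)
  out <- tibble::tibble(
    time_s = event_times[ok],
    phase_deg = phase_series[idx[ok]],
    event_kind = rep(event_kind, sum(ok))
  )
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Phase histogram in 30-degree bins
#'
#' Sorts phases into bins of `bin_deg` degrees (12 bins of 30 degrees by
#' default) and normalizes counts by the total number of events, so the
#' fractions sum to one.
#'
#' @param phases Numeric vector of phases in degrees, or a tibble with a
#'   `phase_deg` column (as returned by [phases_at_events()]).
#' @param bin_deg Bin width in degrees; must divide 360.
#' @return A `tg_phase_histogram` tibble with columns `bin_lo`, `bin_hi`,
#'   `fraction` and attribute `n_events`.
#' @export
phase_histogram <- function(phases, bin_deg = 30) {
  if (is.data.frame(phases)) phases <- phases$phase_deg
  if (length(phases) == 0L) {
    stop("cannot build a phase histogram from zero events", call. = FALSE)
  }
  if (360 %% bin_deg != 0) stop("bin_deg must divide 360", call. = FALSE)
  edges <- seq(0, 360, by = bin_deg)
  nb <- length(edges) - 1L
  ph <- wrap_deg(phases)
  counts <- tabulate(findInterval(ph, edges), nbins = nb) # [lo, hi) bins
  out <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    fraction = counts / length(ph)
  )
  out <- tibble::new_tibble(out, class = "tg_phase_histogram")
  attr(out, "n_events") <- length(ph)
  attr(out, "bin_deg") <- bin_deg
  out
}

#' Circular resultant vector
#'
#' Mean resultant vector of a sample of phases: the length (in `[0, 1]`) is
#' the standard index of coupling or phase-locking strength, and the angle is
#' the circular mean. Computed from the raw phases, never from a binned
#' histogram.
#'
#' @param phases Numeric vector of phases in degrees (n >= 1).
#' @return A list with `length`, `angle_deg` (on `[0, 360)`) and `n`.
#' @examples
#' resultant_vector(c(0, 90, 180, 270))$length # 0
#' @export
resultant_vector <- function(phases) {
  if (length(phases) < 1L) stop("need at least one phase", call. = FALSE)
  z <- mean(exp(1i * deg2rad(phases)))
  list(length = Mod(z), angle_deg = wrap_deg(rad2deg(Arg(z))),
       n = length(phases))
}

#' Session-level theta-gamma cross-frequency coupling
#'
#' Chains the full pipeline for one session: theta/slow state segmentation,
#' theta-state masking, gamma-episode detection in the requested band, theta
#' bandpass + Hilbert phase, phase lookup at the episode maxima, and the
#' resultant vector over those phases. The resultant length is the coupling
#' strength; the angle is the preferred theta phase of gamma.
#'
#' @param session A [lfp_session()] with at least one theta-state bin.
#' @param band Gamma band name or [band_spec()] (default `"gamma"`).
#' @param cfg An [analysis_config()].
#' @param channel LFP channel index to analyze (default first).
#' @return A one-row `coupling result` tibble: `session_id`, `animal_id`,
#'   `genotype`, `band`, `n_events`, `vector_length`, `vector_angle_deg`,
#'   `low_n` (fewer events than `cfg$min_episodes`).
#' @export
session_cfc <- function(session, band = "gamma", cfg = analysis_config(),
                        channel = 1L) {
  trace <- session$lfp[[channel]]
  seg <- segment_states(trace, cfg)
  if (!any(seg$label == "theta")) {
    stop("session has no theta-state bins", call. = FALSE)
  }
  mask <- state_mask(seg, "theta")
  spec <- resolve_band(band, cfg)
  events <- detect_gamma_episodes(trace, spec, cfg, restrict_mask = mask)
  if (nrow(events) == 0L) {
    stop("no gamma episodes detected within theta states", call. = FALSE)
  }
  theta_phase <- instantaneous_phase(bandpass(trace, cfg$band_specs$theta))
  ps <- phases_at_events(theta_phase, trace$fs, events$time_s)
  rv <- resultant_vector(ps$phase_deg)
  tibble::tibble(
    session_id = session$session_id,
    animal_id = session$animal_id,
    genotype = session$genotype,
    band = spec$name,
    n_events = rv$n,
    vector_length = rv$length,
    vector_angle_deg = rv$angle_deg,
    low_n = rv$n < cfg$min_episodes
  )
}
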