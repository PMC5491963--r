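# Shared data model: traces, units, sessions, and the analysis configuration.

#' LFP trace
#'
#' A single-channel local field potential trace: voltage samples in microvolts
#' at a fixed sampling rate. Recordings under urethane anesthesia are
#' typically acquired in the 0-475 Hz band at 2000 Hz.
#'
#' @param samples Numeric vector of voltages (uV). Must be finite.
#' @param fs Sampling rate in Hz (default 2000).
#' @param channel_id,session_id Identifiers carried through the pipeline.
#' @return An object of class `tg_lfp_trace` with fields `samples`, `fs`,
#'   `channel_id`, `session_id`.
#' @seealso [lfp_session()], [wavelet_power()], [segment_states()]
#' @export
lfp_trace <- function(samples, fs = 2000, channel_id = "ch1",
                      session_id = NA_character_) {
  structure(
    list(samples = as.numeric(samples), fs = fs,
         channel_id = as.character(channel_id),
         session_id = as.character(session_id)),
    class = "tg_lfp_trace"
  )
}

#' @export
print.tg_lfp_trace <- function(x, ...) {
  cat(sprintf("<tg_lfp_trace %s> %d samples @ %g Hz (%.1f s), session %s\n",
              x$channel_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$session_id))
  invisible(x)
}

#' Duration of an LFP trace in seconds
#' @param trace A [lfp_trace()].
#' @return Scalar duration (s).
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$fs

#' Sorted spike unit
#'
#' One sorted single unit: spike timestamps (seconds, nondecreasing) and,
#' optionally, the mean spike waveform sampled at `waveform_fs` (1 ms span at
#' 32 kHz in the reference acquisition setup). The waveform may be a numeric
#' vector or a channels-by-samples matrix (tetrode); feature extraction picks
#' the largest-amplitude channel.
#'
#' @param unit_id Identifier.
#' @param spike_times Numeric vector of spike times in seconds, nondecreasing.
#' @param mean_waveform Optional numeric vector or matrix of uV samples.
#' @param waveform_fs Waveform sampling rate in Hz (default 32000).
#' @param layer Anatomical layer label: `"II"`, `"III"` or `"unknown"`.
#' @param cell_class `"pyramidal"`, `"interneuron"` or `"unclassified"`.
#' @return An object of class `tg_spike_unit`.
#' @export
spike_unit <- function(unit_id, spike_times, mean_waveform = NULL,
                       waveform_fs = 32000, layer = "unknown",
                       cell_class = "unclassified") {
  structure(
    list(unit_id = as.character(unit_id),
         spike_times = as.numeric(spike_times),
         mean_waveform = mean_waveform,
         waveform_fs = waveform_fs,
         layer = layer,
         cell_class = cell_class),
    class = "tg_spike_unit"
  )
}

#' @export
print.tg_spike_unit <- function(x, ...) {
  cat(sprintf("<tg_spike_unit %s> %d spikes, class %s, layer %s\n",
              x$unit_id, length(x$spike_times), x$cell_class, x$layer))
  invisible(x)
}

#' Recording session
#'
#' Bundles one or more LFP traces with zero or more sorted units and
#' animal/genotype metadata. The genotype is an opaque group label: no
#' analysis branches on it.
#'
#' @param lfp A [lfp_trace()] or list of traces sharing one sampling rate.
#' @param units List of [spike_unit()] objects.
#' @param animal_id,session_id Identifiers.
#' @param genotype Group label, e.g. `"WT"` or `"APP-KI"`.
#' @return An object of class `tg_session`.
#' @export
lfp_session <- function(lfp, units = list(), animal_id = "A1",
                        genotype = "WT", session_id = "S1") {
  if (inherits(lfp, "tg_lfp_trace")) lfp <- list(lfp)
  structure(
    list(lfp = lfp, units = units, animal_id = as.character(animal_id),
         genotype = as.character(genotype),
         session_id = as.character(session_id)),
    class = "tg_session"
  )
}

#' @export
print.tg_session <- function(x, ...) {
  cat(sprintf("<tg_session %s> animal %s (%s): %d LFP channel(s), %d unit(s)\n",
              x$session_id, x$animal_id, x$genotype,
              length(x$lfp), length(x$units)))
  invisible(x)
}

#' Bandpass filter corner specification
#'
#' Corner frequencies of one zero-phase FIR bandpass filter: the response is
#' zero at and beyond the stopband edges, one across the passband, with
#' raised-cosine transitions in between.
#'
#' @param stop_lo,pass_lo,pass_hi,stop_hi Corner frequencies in Hz, strictly
#'   ordered `stop_lo < pass_lo < pass_hi < stop_hi`.
#' @param name Optional band label.
#' @return An object of class `tg_band_spec`.
#' @export
band_spec <- function(stop_lo, pass_lo, pass_hi, stop_hi, name = NA_character_) {
  if (!(stop_lo < pass_lo && pass_lo < pass_hi && pass_hi < stop_hi)) {
    stop("band corners must satisfy stop_lo < pass_lo < pass_hi < stop_hi",
         call. = FALSE)
  }
  structure(
    list(stop_lo = stop_lo, pass_lo = pass_lo, pass_hi = pass_hi,
         stop_hi = stop_hi, name = name),
    class = "tg_band_spec"
  )
}

#' @export
print.tg_band_spec <- function(x, ...) {
  cat(sprintf("<tg_band_spec %s> stop %g | pass %g - %g | stop %g Hz\n",
              x$name, x$stop_lo, x$pass_lo, x$pass_hi, x$stop_hi))
  invisible(x)
}

#' Default filter corner tables
#'
#' Theta (1.5, 2.5, 4.5, 5.5), gamma (28, 30, 100, 102), slow gamma
#' (28, 30, 50, 52) and fast gamma (53, 55, 100, 102) Hz.
#'
#' @return Named list of [band_spec()] objects.
#' @export
default_band_specs <- function() {
  list(
    theta      = band_spec(1.5, 2.5, 4.5, 5.5,   name = "theta"),
    gamma      = band_spec(28, 30, 100, 102,     name = "gamma"),
    slow_gamma = band_spec(28, 30, 50, 52,       name = "slow_gamma"),
    fast_gamma = band_spec(53, 55, 100, 102,     name = "fast_gamma")
  )
}

#' Analysis configuration
#'
#' All numeric constants of the pipeline in one place. Defaults are the
#' urethane-anesthesia values: theta 2.5-4.5 Hz, slow wave 0.5-1.5 Hz, gamma
#' 30-100 Hz (slow 30-50, fast 55-100), 5-10 Hz normalization reference,
#' 10-s state bins, gamma-episode threshold at mean + 2 SD of band power with
#' 160-ms search windows, 100-ms episode separation and 400-ms analysis
#' windows, 200-ms theta-trough separation, 30-degree phase histogram bins,
#' and a 230-us peak-trough width threshold separating putative pyramidal
#' cells from interneurons.
#'
#' @param theta_band,slow_band,gamma_band,slow_gamma_band,fast_gamma_band
#'   Length-2 Hz vectors (low, high).
#' @param reference_band Hz pair used for power normalization.
#' @param state_bin_s State-segmentation bin length (s).
#' @param episode_sd_threshold SD multiplier for episode detection.
#' @param episode_window_ms Search window cut around supra-threshold points.
#' @param episode_separation_ms Minimum separation of retained episode maxima.
#' @param episode_crop_ms Analysis window attached to each episode.
#' @param theta_trough_separation_ms Minimum separation of theta troughs.
#' @param theta_cycle_range_s Accepted trough-to-trough periods (s); default
#'   is the theta passband inverted, `c(1/4.5, 1/2.5)`.
#' @param phase_hist_bin_deg Phase histogram bin width (degrees).
#' @param pyr_int_width_threshold_us Peak-trough width threshold (us).
#' @param wavelet_ratio Morlet constant `f / sigma_f`.
#' @param state_freq_step_hz Frequency spacing of band-power estimates used
#'   for state segmentation.
#' @param episode_freq_step_hz Frequency spacing of the band-averaged power
#'   used for episode detection.
#' @param min_spikes Minimum theta-state spikes for a locking estimate.
#' @param min_episodes Below this event count a coupling result is flagged
#'   low-n.
#' @param band_specs Named list of [band_spec()] filter corner tables.
#' @return An object of class `tg_analysis_config` (a named list).
#' @export
analysis_config <- function(theta_band = c(2.5, 4.5),
                            slow_band = c(0.5, 1.5),
                            gamma_band = c(30, 100),
                            slow_gamma_band = c(30, 50),
                            fast_gamma_band = c(55, 100),
                            reference_band = c(5, 10),
                            state_bin_s = 10,
                            episode_sd_threshold = 2,
                            episode_window_ms = 160,
                            episode_separation_ms = 100,
                            episode_crop_ms = 400,
                            theta_trough_separation_ms = 200,
                            theta_cycle_range_s = c(1 / 4.5, 1 / 2.5),
                            phase_hist_bin_deg = 30,
                            pyr_int_width_threshold_us = 230,
                            wavelet_ratio = 7,
                            state_freq_step_hz = 0.2,
                            episode_freq_step_hz = 2,
                            min_spikes = 50,
                            min_episodes = 30,
                            band_specs = default_band_specs()) {
  cfg <- list(
    theta_band = theta_band, slow_band = slow_band, gamma_band = gamma_band,
    slow_gamma_band = slow_gamma_band, fast_gamma_band = fast_gamma_band,
    reference_band = reference_band, state_bin_s = state_bin_s,
    episode_sd_threshold = episode_sd_threshold,
    episode_window_ms = episode_window_ms,
    episode_separation_ms = episode_separation_ms,
    episode_crop_ms = episode_crop_ms,
    theta_trough_separation_ms = theta_trough_separation_ms,
    theta_cycle_range_s = theta_cycle_range_s,
    phase_hist_bin_deg = phase_hist_bin_deg,
    pyr_int_width_threshold_us = pyr_int_width_threshold_us,
    wavelet_ratio = wavelet_ratio,
    state_freq_step_hz = state_freq_step_hz,
    episode_freq_step_hz = episode_freq_step_hz,
    min_spikes = min_spikes, min_episodes = min_episodes,
    band_specs = band_specs
  )
  bands <- c("theta_band", "slow_band", "gamma_band", "slow_gamma_band",
             "fast_gamma_band", "reference_band")
  for (b in bands) {
    if (length(cfg[[b]]) != 2L || cfg[[b]][1] >= cfg[[b]][2]) {
      stop(sprintf("%s must be an increasing (low, high) Hz pair", b),
           call. = FALSE)
    }
  }
  durs <- c(state_bin_s, episode_window_ms, episode_separation_ms,
            episode_crop_ms, theta_trough_separation_ms)
  if (any(durs <= 0)) stop("all durations must be positive", call. = FALSE)
  if (wavelet_ratio <= 0) stop("wavelet_ratio must be > 0", call. = FALSE)
  structure(cfg, class = "tg_analysis_config")
}

# Accept either a band name ("gamma") or a tg_band_spec.
resolve_band <- function(band, cfg) {
  if (inherits(band, "tg_band_spec")) return(band)
  if (is.character(band) && band %in% names(cfg$band_specs)) {
    return(cfg$band_specs[[band]])
  }
  stop(sprintf("unknown band '%s'; expected a band_spec or one of: %s",
               as.character(band)[1],
               paste(names(cfg$band_specs), collapse = ", ")), call. = FALSE)
}

#' Validate a session against the data-model invariants
#'
#' Checks each trace (positive sampling rate, finite samples, one shared fs),
#' each unit (nondecreasing spike times within the recorded duration,
#' plausible waveform length) and returns one row per violation. Validation
#' reports; it never raises and never mutates its input.
#'
#' @param session A [lfp_session()].
#' @return A tibble with columns `component`, `id`, `issue`; zero rows iff
#'   all invariants hold.
#' @export
validate_session <- function(session) {
  issues <- list()
  add <- function(component, id, issue) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      component = component, id = id, issue = issue)
  }
  fss <- vapply(session$lfp, function(tr) tr$fs, numeric(1))
  for (tr in session$lfp) {
    if (!is.numeric(tr$fs) || length(tr$fs) != 1L || is.na(tr$fs) ||
        tr$fs <= 0) {
      add("trace", tr$channel_id, "sampling rate fs must be a positive scalar")
    }
    if (length(tr$samples) == 0L) {
      add("trace", tr$channel_id, "trace has no samples")
    } else if (!all(is.finite(tr$samples))) {
      add("trace", tr$channel_id, "trace contains non-finite samples")
    }
  }
  if (length(unique(fss[fss > 0])) > 1L) {
    add("session", session$session_id,
        "LFP traces do not share one sampling rate")
  }
  max_dur <- if (length(session$lfp) > 0L && all(fss > 0)) {
    max(vapply(session$lfp, trace_duration, numeric(1)))
  } else {
    NA_real_
  }
  for (u in session$units) {
    st <- u$spike_times
    if (length(st) > 0L) {
      if (is.unsorted(st)) {
        add("unit", u$unit_id, "spike_times are not nondecreasing")
      }
      if (any(st < 0)) add("unit", u$unit_id, "spike_times contain negative times")
      if (!is.na(max_dur) && any(st > max_dur)) {
        add("unit", u$unit_id, "spike_times exceed the session duration")
      }
    }
    if (!is.null(u$mean_waveform)) {
      wf <- u$mean_waveform
      ns <- if (is.matrix(wf)) ncol(wf) else length(wf)
      expected <- round(u$waveform_fs * 1e-3) # 1 ms span
      if (ns != expected) {
        add("unit", u$unit_id,
            sprintf("mean_waveform has %d samples; expected %d (1 ms at %g Hz)",
                    ns, expected, u$waveform_fs))
      }
    }
  }
  if (length(issues) == 0L) {
    tibble::tibble(component = character(), id = character(),
                   issue = character())
  } else {
    dplyr::bind_rows(issues)
  }
}
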