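# Session- and cohort-level drivers that chain the pipeline stages and
# return tidy result tables.

#' Raw power spectrum of a session during one state
#'
#' Mean wavelet power at each frequency over the (valid) samples of the
#' requested state, e.g. the 0.4-10 Hz spectrum during theta periods at
#' 0.2-Hz steps.
#'
#' @param session A [lfp_session()] (or a bare [lfp_trace()]).
#' @param cfg An [analysis_config()].
#' @param freqs Frequency grid (Hz).
#' @param state `"theta"`, `"slow"` or `"all"`.
#' @param channel LFP channel index.
#' @return A tibble with columns `session_id`, `animal_id`, `genotype`,
#'   `freq_hz`, `power`.
#' @export
session_power_spectrum <- function(session, cfg = analysis_config(),
                                   freqs = seq(0.4, 10, by = 0.2),
                                   state = "theta", channel = 1L) {
  if (inherits(session, "tg_lfp_trace")) {
    session <- lfp_session(session, session_id = session$session_id)
  }
  trace <- session$lfp[[channel]]
  n <- length(trace$samples)
  mask <- if (state == "all") {
    rep(TRUE, n)
  } else {
    state_mask(segment_states(trace, cfg), state)
  }
  pw <- numeric(length(freqs))
  wavelet_apply(trace$samples, trace$fs, freqs, cfg$wavelet_ratio,
                function(p, i, half) {
                  ok <- mask
                  if (half > 0) {
                    ok[c(seq_len(half), (n - half + 1L):n)] <- FALSE
                  }
                  pw[i] <<- mean(p[ok])
                })
  tibble::tibble(
    session_id = session$session_id,
    animal_id = session$animal_id,
    genotype = session$genotype,
    freq_hz = freqs,
    power = pw
  )
}

#' Analyze one session end to end
#'
#' Runs state segmentation, gamma-episode detection and theta-phase coupling
#' in the requested gamma bands, plus per-unit classification, theta-state
#' firing rate and phase locking to each reference band, sharing the
#' intermediate signals (filters, phases, masks) across stages. Phase locking
#' uses theta-state spikes only.
#'
#' @param session A [lfp_session()].
#' @param cfg An [analysis_config()].
#' @param gamma_bands Character vector of band names for coupling.
#' @param lock_references Character vector of reference bands for spike
#'   locking (subset of `"theta"`, `"gamma"`, `"slow_gamma"`, `"fast_gamma"`).
#' @param channel LFP channel index.
#' @return A list of tibbles: `states` (one row: emergence rates and episode
#'   rate), `cfc` (one row per gamma band; zero-event bands are omitted),
#'   `units` (one row per unit and reference).
#' @export
analyze_session <- function(session, cfg = analysis_config(),
                            gamma_bands = "gamma",
                            lock_references = c("theta", "gamma"),
                            channel = 1L) {
  trace <- session$lfp[[channel]]
  fs <- trace$fs
  seg <- segment_states(trace, cfg)
  theta_mask <- state_mask(seg, "theta")
  theta_s <- sum(theta_mask) / fs
  theta_phase <- instantaneous_phase(bandpass(trace, cfg$band_specs$theta))

  phase_of <- list(theta = theta_phase)
  for (ref in setdiff(lock_references, "theta")) {
    phase_of[[ref]] <- instantaneous_phase(
      bandpass(trace, cfg$band_specs[[ref]]))
  }

  cfc <- list()
  ep_rate <- NA_real_
  for (bn in gamma_bands) {
    events <- detect_gamma_episodes(trace, bn, cfg, restrict_mask = theta_mask)
    if (bn == gamma_bands[1] && theta_s > 0) {
      ep_rate <- episode_rate(events, theta_s)
    }
    if (nrow(events) == 0L) next
    ps <- phases_at_events(theta_phase, fs, events$time_s)
    rv <- resultant_vector(ps$phase_deg)
    cfc[[bn]] <- tibble::tibble(
      session_id = session$session_id, animal_id = session$animal_id,
      genotype = session$genotype, band = bn, n_events = rv$n,
      vector_length = rv$length, vector_angle_deg = rv$angle_deg,
      low_n = rv$n < cfg$min_episodes
    )
  }

  units <- list()
  for (u in session$units) {
    cls <- u$cell_class
    if (!is.null(u$mean_waveform) && cls == "unclassified") {
      cls <- classify_unit(waveform_features(u),
                           cfg$pyr_int_width_threshold_us)
    }
    fr <- if (theta_s > 0) firing_rate(u, theta_mask, fs) else NA_real_
    for (ref in lock_references) {
      row <- spike_phase_locking(u, phase_of[[ref]], fs, mask = theta_mask,
                                 reference = ref,
                                 min_spikes = cfg$min_spikes)
      row$cell_class <- cls
      row$firing_rate_hz <- fr
      row$session_id <- session$session_id
      row$animal_id <- session$animal_id
      row$genotype <- session$genotype
      units[[length(units) + 1L]] <- row
    }
  }

  states <- tibble::tibble(
    session_id = session$session_id, animal_id = session$animal_id,
    genotype = session$genotype,
    theta_emergence = emergence_rate(seg, "theta"),
    slow_emergence = emergence_rate(seg, "slow"),
    theta_duration_s = theta_s,
    gamma_episode_rate = ep_rate
  )
  list(
    states = states,
    cfc = if (length(cfc) > 0L) dplyr::bind_rows(cfc) else tibble::tibble(),
    units = if (length(units) > 0L) dplyr::bind_rows(units) else
      tibble::tibble()
  )
}

#' Analyze every session of a cohort table
#'
#' Maps [analyze_session()] over the rows of a cohort tibble (as produced by
#' [generate_cohort()] or assembled from [read_bundle()] sessions) and binds
#' the result tables, carrying the `group` column through.
#'
#' @param cohort A tibble with a `session` list-column and optionally a
#'   `group` column.
#' @param cfg An [analysis_config()].
#' @param ... Passed to [analyze_session()].
#' @return A list of tibbles `states`, `cfc`, `units`, each with a `group`
#'   column when the input had one.
#' @export
analyze_cohort <- function(cohort, cfg = analysis_config(), ...) {
  res <- purrr::map(seq_len(nrow(cohort)), function(i) {
    out <- analyze_session(cohort$session[[i]], cfg, ...)
    if ("group" %in% names(cohort)) {
      out <- purrr::map(out, function(tb) {
        if (nrow(tb) > 0L) tb$group <- cohort$group[i]
        tb
      })
    }
    out
  })
  list(
    states = dplyr::bind_rows(purrr::map(res, "states")),
    cfc = dplyr::bind_rows(purrr::map(res, "cfc")),
    units = dplyr::bind_rows(purrr::map(res, "units"))
  )
}

#' Compare two analyzed cohorts
#'
#' Session-level Mann-Whitney comparisons of coupling strength (per gamma
#' band) and unit-level comparisons of locking strength (per reference band
#' and cell class), mirroring the convention of treating sessions as units
#' for LFP metrics and cells for locking metrics.
#'
#' @param analysis Output of [analyze_cohort()] on a two-group cohort.
#' @return A tibble of [compare_groups()] rows.
#' @export
compare_cohorts <- function(analysis) {
  out <- list()
  if (nrow(analysis$cfc) > 0L) {
    for (bn in unique(analysis$cfc$band)) {
      d <- dplyr::filter(analysis$cfc, .data$band == bn)
      out[[length(out) + 1L]] <- compare_groups(
        d, .data$vector_length, .data$group,
        metric = sprintf("cfc_vector_length_%s", bn))
    }
  }
  if (nrow(analysis$units) > 0L) {
    locks <- dplyr::filter(analysis$units, !is.na(.data$vector_length))
    for (ref in unique(locks$reference)) {
      for (cls in unique(locks$cell_class)) {
        d <- dplyr::filter(locks, .data$reference == ref,
                           .data$cell_class == cls)
        if (length(unique(d$group)) != 2L) next
        out[[length(out) + 1L]] <- compare_groups(
          d, .data$vector_length, .data$group,
          metric = sprintf("locking_%s_%s", ref, cls))
      }
    }
    st <- dplyr::filter(analysis$units, .data$reference ==
                          analysis$units$reference[1])
    for (cls in unique(st$cell_class)) {
      d <- dplyr::filter(st, .data$cell_class == cls,
                         !is.na(.data$firing_rate_hz))
      if (length(unique(d$group)) != 2L) next
      out[[length(out) + 1L]] <- compare_groups(
        d, .data$firing_rate_hz, .data$group,
        metric = sprintf("firing_rate_%s", cls))
    }
  }
  if (nrow(analysis$states) > 0L && "group" %in% names(analysis$states)) {
    out[[length(out) + 1L]] <- compare_groups(
      analysis$states, .data$theta_emergence, .data$group,
      metric = "theta_emergence")
    d <- dplyr::filter(analysis$states, !is.na(.data$gamma_episode_rate))
    if (length(unique(d$group)) == 2L) {
      out[[length(out) + 1L]] <- compare_groups(
        d, .data$gamma_episode_rate, .data$group,
        metric = "gamma_episode_rate")
    }
  }
  dplyr::bind_rows(out)
}
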