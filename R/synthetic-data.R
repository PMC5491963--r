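# Seeded surrogate sessions with the statistical structure the analyses
# assume: alternating theta/slow-wave states, theta-phase-modulated gamma
# bursts, 1/f background noise, and von Mises phase-locked spike trains.

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the circular
#' uniform. The mean resultant length of a von Mises sample converges to the
#' Bessel ratio `I1(kappa) / I0(kappa)`.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction in degrees.
#' @param kappa Concentration (>= 0).
#' @return Phases in degrees on `[0, 360)`.
#' @export
rvonmises <- function(n, mu_deg = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be nonnegative", call. = FALSE)
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-9) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.6) + 8L
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(stats::runif(sum(acc)) - 0.5) * acos(pmin(pmax(f[acc], -1), 1))
    out <- c(out, th)
  }
  wrap_deg(rad2deg(out[seq_len(n)]) + mu_deg)
}

#' 1/f^alpha background noise
#'
#' Gaussian noise whose power spectrum is shaped to `f^-alpha` by scaling the
#' Fourier coefficients of white noise, rescaled to the requested standard
#' deviation.
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param alpha Spectral exponent (default 1, i.e. pink noise).
#' @param sd Target standard deviation (uV).
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, alpha = 1, sd = 1) {
  if (n == 0L) return(numeric(0))
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1L) * fs / n
  fm <- pmin(f, fs - f)
  g <- ifelse(fm > 0, fm^(-alpha / 2), 0)
  x <- Re(stats::fft(X * g, inverse = TRUE) / n)
  if (stats::sd(x) > 0) x <- x * sd / stats::sd(x)
  x
}

#' Synthetic-session generator parameters
#'
#' Defaults emulate urethane-anesthesia recordings: alternating theta
#' (3.5 Hz) and slow-wave (1 Hz) states with ~16.5% theta occupancy, gamma
#' (60 Hz) bursts riding on theta with occurrence probability and amplitude
#' modulated as `1 + m cos(theta - preferred_phase)`, 1/f background noise,
#' and two spike classes (broad / narrow waveform, peak-trough widths drawn
#' from a bimodal distribution with a gap spanning 210-250 us) with von Mises
#' phase locking to theta and to the gamma carrier.
#'
#' @param duration_s Session duration (s).
#' @param fs LFP sampling rate (Hz).
#' @param theta_freq,theta_amp Theta frequency (Hz) and amplitude (uV).
#' @param slow_freq,slow_amp Slow-wave frequency (Hz) and amplitude (uV).
#' @param theta_occupancy Target fraction of time in theta state, in (0, 1).
#' @param theta_dwell_s Mean theta dwell time (s); slow dwell is derived from
#'   the occupancy. Dwells are quantized to the 10-s state-scoring bin.
#' @param gamma_freq Gamma carrier frequency (Hz).
#' @param gamma_amp Peak burst amplitude (uV).
#' @param burst_rate_per_cycle Candidate bursts per theta cycle (<= 1).
#' @param burst_duration_ms Burst (Hann envelope) duration.
#' @param modulation_depth Coupling depth `m` in `[0, 1]`.
#' @param preferred_phase_deg Theta phase (degrees, peak = 0) at which bursts
#'   preferentially occur.
#' @param continuous_gamma If `TRUE`, gamma is a continuous
#'   amplitude-modulated tone during theta states instead of discrete bursts.
#' @param noise_sd,noise_alpha 1/f^alpha noise level (uV) and exponent.
#' @param white_noise_sd Additional white noise floor (uV).
#' @param n_pyramidal,n_interneuron Units per class.
#' @param pyramidal_rate_hz,interneuron_rate_hz Mean firing rates (Hz).
#' @param kappa_theta,kappa_gamma von Mises concentrations of spike locking
#'   to theta phase and to the gamma carrier phase.
#' @param theta_pref_phase_deg,gamma_pref_phase_deg Preferred spike phases.
#' @param pyr_width_mean_us,pyr_width_sd_us,pyr_width_range_us Peak-trough
#'   width distribution of pyramidal cells (truncated normal, us).
#' @param int_width_mean_us,int_width_sd_us,int_width_range_us Same for
#'   interneurons.
#' @param seed Optional integer seed; a fixed seed makes the session
#'   deterministic.
#' @return An object of class `tg_generator_params`.
#' @export
generator_params <- function(duration_s = 600,
                             fs = 2000,
                             theta_freq = 3.5, theta_amp = 100,
                             slow_freq = 1.0, slow_amp = 200,
                             theta_occupancy = 0.165, theta_dwell_s = 30,
                             gamma_freq = 60, gamma_amp = 50,
                             burst_rate_per_cycle = 1,
                             burst_duration_ms = 80,
                             modulation_depth = 0.5,
                             preferred_phase_deg = 180,
                             continuous_gamma = FALSE,
                             noise_sd = 20, noise_alpha = 1,
                             white_noise_sd = 5,
                             n_pyramidal = 2, n_interneuron = 1,
                             pyramidal_rate_hz = 6.5,
                             interneuron_rate_hz = 8.3,
                             kappa_theta = 1, kappa_gamma = 1,
                             theta_pref_phase_deg = 180,
                             gamma_pref_phase_deg = 0,
                             pyr_width_mean_us = 330, pyr_width_sd_us = 35,
                             pyr_width_range_us = c(260, 420),
                             int_width_mean_us = 165, int_width_sd_us = 25,
                             int_width_range_us = c(110, 205),
                             seed = NULL) {
  p <- as.list(environment())
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(duration_s > 0, "duration_s must be positive")
  chk(fs > 0, "fs must be positive")
  chk(modulation_depth >= 0 && modulation_depth <= 1,
      "modulation_depth must lie in [0, 1]")
  chk(kappa_theta >= 0, "kappa_theta must be nonnegative")
  chk(kappa_gamma >= 0, "kappa_gamma must be nonnegative")
  chk(theta_occupancy > 0 && theta_occupancy < 1,
      "theta_occupancy must lie in (0, 1)")
  chk(burst_rate_per_cycle >= 0 && burst_rate_per_cycle <= 1,
      "burst_rate_per_cycle must lie in [0, 1]")
  amps <- c(theta_amp, slow_amp, gamma_amp, noise_sd, white_noise_sd)
  chk(all(amps >= 0), "all amplitudes must be nonnegative")
  chk(pyramidal_rate_hz >= 0 && interneuron_rate_hz >= 0,
      "firing rates must be nonnegative")
  if (length(problems) > 0L) {
    stop(paste0("invalid generator parameters:\n  ",
                paste(problems, collapse = "\n  ")), call. = FALSE)
  }
  structure(p, class = "tg_generator_params")
}

# Alternating state schedule with dwell times quantized to the state-scoring
# bin, hitting the occupancy target in expectation.
draw_schedule <- function(duration_s, occupancy, theta_dwell_s, bin_s = 10) {
  slow_dwell_s <- theta_dwell_s * (1 - occupancy) / occupancy
  state <- if (stats::runif(1) < occupancy) "theta" else "slow"
  starts <- numeric(0)
  ends <- numeric(0)
  states <- character(0)
  t <- 0
  while (t < duration_s) {
    mean_dwell <- if (state == "theta") theta_dwell_s else slow_dwell_s
    d <- max(bin_s, round(stats::rexp(1, 1 / mean_dwell) / bin_s) * bin_s)
    d <- min(d, duration_s - t)
    starts <- c(starts, t)
    ends <- c(ends, t + d)
    states <- c(states, state)
    t <- t + d
    state <- if (state == "theta") "slow" else "theta"
  }
  tibble::tibble(start_s = starts, end_s = ends, state = states)
}

#' Inject gamma bursts into a signal
#'
#' Adds Hann-enveloped bursts of a gamma carrier `cos(2 pi f t)` (global
#' carrier phase, so bursts are mutually coherent) centred at the given
#' times. Useful for constructing detection fixtures with a known schedule.
#'
#' @param samples Numeric signal vector.
#' @param fs Sampling rate (Hz).
#' @param times Burst centre times (s).
#' @param freq Carrier frequency (Hz).
#' @param duration_ms Envelope duration.
#' @param amplitude Peak amplitude (uV), scalar or per burst.
#' @return The signal with bursts added.
#' @export
inject_gamma_bursts <- function(samples, fs, times, freq = 60,
                                duration_ms = 80, amplitude = 50) {
  n <- length(samples)
  dur <- duration_ms / 1000
  amplitude <- rep_len(amplitude, length(times))
  half <- round(dur / 2 * fs)
  for (k in seq_along(times)) {
    c_idx <- round(times[k] * fs) + 1L
    idx <- (c_idx - half):(c_idx + half)
    ok <- idx >= 1L & idx <= n
    idx <- idx[ok]
    if (length(idx) == 0L) next
    t <- (idx - 1L) / fs
    env <- 0.5 * (1 + cos(2 * pi * (t - times[k]) / dur))
    samples[idx] <- samples[idx] +
      amplitude[k] * env * cos(2 * pi * freq * t)
  }
  samples
}

# Triangular biphasic mean waveform (1 ms at waveform_fs) with a prescribed
# peak-trough width; half-max width scales with the class.
make_waveform <- function(width_us, waveform_fs = 32000, amp_uv = 80) {
  ns <- round(waveform_fs * 1e-3)
  t_us <- (seq_len(ns) - 1L) / waveform_fs * 1e6
  peak_us <- 220
  sig1 <- 0.30 * width_us # peak lobe width tracks the class
  sig2 <- 0.45 * width_us
  w <- exp(-(t_us - peak_us)^2 / (2 * sig1^2)) -
    0.62 * exp(-(t_us - peak_us - width_us)^2 / (2 * sig2^2))
  amp_uv * w
}

#' Generate a synthetic recording session
#'
#' Builds one session under the generator's statistical model: a state-gated
#' theta/slow-wave LFP, gamma bursts whose per-cycle occurrence probability
#' and amplitude follow `1 + m cos(theta_phase - preferred_phase)`, 1/f
#' noise, and spike trains thinned from an inhomogeneous Poisson process with
#' von Mises phase preference to the theta phase and the gamma carrier phase.
#' Deterministic under a fixed `params$seed`.
#'
#' @param params A [generator_params()].
#' @param session_id,animal_id,genotype Metadata labels.
#' @return A list with `session` (a [lfp_session()]) and `truth`, the ground
#'   truth record: `schedule` (state dwells), `bursts` (time, theta phase,
#'   amplitude of every injected burst), `units` (per-unit class, width,
#'   rates, concentrations), and the originating `params`.
#' @export
generate_session <- function(params = generator_params(), session_id = "S1",
                             animal_id = "A1", genotype = "WT") {
  stopifnot(inherits(params, "tg_generator_params"))
  with_seed(params$seed, {
    fs <- params$fs
    n <- round(params$duration_s * fs)
    tt <- (seq_len(n) - 1L) / fs
    sched <- draw_schedule(params$duration_s, params$theta_occupancy,
                           params$theta_dwell_s)
    x <- numeric(n)
    bursts <- list()
    for (k in seq_len(nrow(sched))) {
      i0 <- round(sched$start_s[k] * fs) + 1L
      i1 <- min(round(sched$end_s[k] * fs), n)
      if (i1 < i0) next
      idx <- i0:i1
      rel <- tt[idx] - sched$start_s[k]
      if (sched$state[k] == "theta") {
        ph <- 2 * pi * params$theta_freq * rel
        x[idx] <- x[idx] + params$theta_amp * cos(ph)
        m <- params$modulation_depth
        phi0 <- deg2rad(params$preferred_phase_deg)
        if (params$continuous_gamma) {
          gmod <- (1 + m * cos(ph - phi0)) / (1 + m)
          x[idx] <- x[idx] +
            params$gamma_amp * gmod * cos(2 * pi * params$gamma_freq * tt[idx])
        } else if (params$burst_rate_per_cycle > 0 && params$gamma_amp > 0) {
          ncyc <- floor(params$theta_freq * (sched$end_s[k] - sched$start_s[k]))
          if (ncyc > 0) {
            occur <- stats::runif(ncyc) < params$burst_rate_per_cycle
            phi <- stats::runif(ncyc) * 2 * pi
            accept <- stats::runif(ncyc) < (1 + m * cos(phi - phi0)) / (1 + m)
            sel <- which(occur & accept)
            if (length(sel) > 0L) {
              tc <- sched$start_s[k] +
                (sel - 1 + phi[sel] / (2 * pi)) / params$theta_freq
              amp <- params$gamma_amp *
                (1 + m * cos(phi[sel] - phi0)) / (1 + m)
              x <- inject_gamma_bursts(x, fs, tc, params$gamma_freq,
                                       params$burst_duration_ms, amp)
              bursts[[length(bursts) + 1L]] <- tibble::tibble(
                time_s = tc,
                theta_phase_deg = wrap_deg(rad2deg(phi[sel])),
                amplitude = amp
              )
            }
          }
        }
      } else {
        x[idx] <- x[idx] +
          params$slow_amp * cos(2 * pi * params$slow_freq * rel)
      }
    }
    if (params$noise_sd > 0) {
      x <- x + pink_noise(n, fs, params$noise_alpha, params$noise_sd)
    }
    if (params$white_noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, params$white_noise_sd)
    }
    bursts <- if (length(bursts) > 0L) {
      dplyr::arrange(dplyr::bind_rows(bursts), .data$time_s)
    } else {
      tibble::tibble(time_s = numeric(), theta_phase_deg = numeric(),
                     amplitude = numeric())
    }

    units <- list()
    unit_truth <- list()
    classes <- c(rep("pyramidal", params$n_pyramidal),
                 rep("interneuron", params$n_interneuron))
    for (u in seq_along(classes)) {
      cls <- classes[u]
      rate <- if (cls == "pyramidal") params$pyramidal_rate_hz else
        params$interneuron_rate_hz
      if (cls == "pyramidal") {
        wr <- params$pyr_width_range_us
        width <- min(max(stats::rnorm(1, params$pyr_width_mean_us,
                                      params$pyr_width_sd_us), wr[1]), wr[2])
      } else {
        wr <- params$int_width_range_us
        width <- min(max(stats::rnorm(1, params$int_width_mean_us,
                                      params$int_width_sd_us), wr[1]), wr[2])
      }
      kt <- params$kappa_theta
      kg <- params$kappa_gamma
      mu_t <- deg2rad(params$theta_pref_phase_deg)
      mu_g <- deg2rad(params$gamma_pref_phase_deg)
      lam_max <- rate * exp(kt) / besselI(kt, 0) * exp(kg) / besselI(kg, 0)
      n_cand <- stats::rpois(1, lam_max * params$duration_s)
      cand <- sort(stats::runif(n_cand, 0, params$duration_s))
      # exact continuous-time phases (no sample-grid quantization)
      row <- findInterval(cand, sched$start_s)
      th_ok <- sched$state[row] == "theta"
      rel <- cand - sched$start_s[row]
      lam <- rep(rate, length(cand))
      th_phase <- 2 * pi * params$theta_freq * rel[th_ok]
      g_phase <- 2 * pi * params$gamma_freq * cand[th_ok]
      lam[th_ok] <- rate *
        exp(kt * cos(th_phase - mu_t)) / besselI(kt, 0) *
        exp(kg * cos(g_phase - mu_g)) / besselI(kg, 0)
      keep <- stats::runif(length(cand)) < lam / lam_max
      spikes <- cand[keep]
      uid <- sprintf("%s_u%02d", session_id, u)
      units[[u]] <- spike_unit(
        unit_id = uid, spike_times = spikes,
        mean_waveform = make_waveform(width, 32000),
        waveform_fs = 32000,
        layer = sample(c("II", "III"), 1),
        cell_class = "unclassified"
      )
      unit_truth[[u]] <- tibble::tibble(
        unit_id = uid, true_class = cls, width_us = width,
        rate_hz = rate, kappa_theta = kt, kappa_gamma = kg,
        theta_pref_phase_deg = params$theta_pref_phase_deg,
        gamma_pref_phase_deg = params$gamma_pref_phase_deg,
        n_spikes = length(spikes)
      )
    }
    session <- lfp_session(
      lfp = lfp_trace(x, fs, channel_id = "ch1", session_id = session_id),
      units = units, animal_id = animal_id, genotype = genotype,
      session_id = session_id
    )
    truth <- list(
      schedule = sched,
      bursts = bursts,
      units = if (length(unit_truth) > 0L) dplyr::bind_rows(unit_truth) else
        tibble::tibble(),
      params = params
    )
    list(session = session, truth = truth)
  })
}

#' Generate two synthetic cohorts
#'
#' Draws `n_animals` animals per group and `sessions_per_animal` sessions per
#' animal, with small per-animal random effects (lognormal jitter on
#' amplitudes and concentrations, Gaussian jitter on the modulation depth,
#' clamped to `[0, 1]`). Seeds derive deterministically from `base_seed` by a
#' counter scheme (`base + 100000 * group + 1000 * animal + session`), so a
#' cohort is reproducible from one integer.
#'
#' @param params_a,params_b [generator_params()] for the two groups.
#' @param n_animals Animals per group.
#' @param sessions_per_animal Sessions per animal.
#' @param base_seed Integer master seed.
#' @param labels Group labels (also used as genotype labels).
#' @return A tibble with columns `group`, `animal_id`, `session_id`, and
#'   list-columns `session`, `truth`.
#' @export
generate_cohort <- function(params_a, params_b, n_animals = 5,
                            sessions_per_animal = 6, base_seed = 1,
                            labels = c("WT", "APP-KI")) {
  rows <- list()
  plist <- list(params_a, params_b)
  for (g in 1:2) {
    for (a in seq_len(n_animals)) {
      animal_seed <- base_seed + 100000L * (g - 1L) + 1000L * a
      jit <- with_seed(animal_seed, list(
        amp = stats::rlnorm(1, 0, 0.05),
        m = stats::rnorm(1, 0, 0.03),
        kap = stats::rlnorm(1, 0, 0.05)
      ))
      p <- plist[[g]]
      animal_id <- sprintf("%s_a%d", labels[g], a)
      for (s in seq_len(sessions_per_animal)) {
        ps <- p
        ps$theta_amp <- p$theta_amp * jit$amp
        ps$gamma_amp <- p$gamma_amp * jit$amp
        ps$modulation_depth <- min(max(p$modulation_depth + jit$m, 0), 1)
        ps$kappa_theta <- p$kappa_theta * jit$kap
        ps$kappa_gamma <- p$kappa_gamma * jit$kap
        ps$seed <- animal_seed + s
        session_id <- sprintf("%s_s%d", animal_id, s)
        gen <- generate_session(ps, session_id = session_id,
                                animal_id = animal_id, genotype = labels[g])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          group = labels[g], animal_id = animal_id, session_id = session_id,
          session = list(gen$session), truth = list(gen$truth)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
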