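---
title: "Methods: theta-gamma coupling and spike phase locking in anesthetized LFP recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: theta-gamma coupling and spike phase locking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetagamma)
```

## The analysis problem

Under urethane anesthesia the cortical local field potential (LFP) alternates
between two spontaneous states: a *theta state* dominated by 2.5-4.5 Hz
oscillations and a *slow-wave state* dominated by 0.5-1.5 Hz oscillations.
During theta states, transient gamma oscillations (30-100 Hz; slow gamma
30-50 Hz, fast gamma 55-100 Hz) ride on the theta rhythm, and their timing
relative to the theta cycle — cross-frequency coupling (CFC) — together with
the phase locking of single-unit spikes to theta and gamma, indexes the
temporal coordination of the local circuit. This package implements the full
measurement chain for such recordings and pairs it with a synthetic-session
generator so that every stage can be verified by parameter recovery, without
any recorded data.

## Spectral engine

Time-resolved power is computed by convolution with complex Morlet wavelets

$$w(t, f) = A \exp(-t^2 / 2\sigma_t^2)\, \exp(2 i \pi f t), \qquad
\sigma_f = \frac{1}{2\pi \sigma_t}, \qquad
A = (\sigma_t \sqrt{\pi})^{-1/2},$$

one wavelet per analysis frequency, with the family characterized by a
constant ratio $f/\sigma_f = 7$. The amplitude $A$ normalizes each wavelet to
unit total energy. Numerical choices:

* **Support truncation.** Kernels are cut at $\pm 4\sigma_t$, which carries
  more than 99.99% of the energy; the discrete energy
  $\sum |w|^2 / f_s$ is renormalized to exactly 1 after truncation, so the
  unit-energy contract holds to machine precision at every frequency.
* **Edge handling.** Convolution uses zero padding, and every sample within
  $4\sigma_t$ of either trace edge is flagged invalid per frequency. Invalid
  samples are excluded from all statistics (band means, thresholds, bin
  powers). Reflection padding was deliberately avoided: it fabricates
  oscillatory energy at the boundary, whereas explicit masking only discards
  data.
* **Frequency grids.** 0.2-Hz steps for the 0.4-10 Hz range (state scoring,
  low-frequency spectra), 2-Hz steps across a gamma band for the
  band-averaged power used in episode detection, and 2-Hz-wide band centres
  from 3 to 139 Hz for trigger-averaged spectra. Only the first of these is
  externally prescribed; the others trade frequency resolution against
  runtime and are documented here as package defaults.

Power is normalized, per electrode, to mean power in the 5-10 Hz reference
band — a scalar division that controls for impedance differences between
electrodes. Raw power scales with the square of the input voltage; normalized
power is scale-free (both properties are asserted in the test suite).

## State segmentation

The trace is split into 10-s bins (a final partial bin is dropped; at least
three full bins are required — the shortest recording for which a
segmentation is meaningful, a choice this package makes explicit). For each
bin the ratio of mean raw theta-band power (2.5-4.5 Hz) to mean raw
slow-wave-band power (0.5-1.5 Hz) is computed; bins with ratio $\ge 1$ are
theta states, bins below 1 slow-wave states, with the tie assigned to theta
by the $\ge$ convention. Because the label depends only on a power ratio, it
is invariant to voltage scaling and to normalization; the per-bin estimator
(mean wavelet power at 0.2-Hz spacing) keeps a single spectral engine for the
whole pipeline.

## Bandpass filtering and phase

All band-limited operations use an acausal (zero phase shift),
frequency-domain FIR bandpass: the frequency response is zero at and beyond
the stopband corners, one across the passband, with raised-cosine transitions
between the corner pairs (theta 1.5/2.5-4.5/5.5 Hz, gamma 28/30-100/102 Hz,
slow gamma 28/30-50/52 Hz, fast gamma 53/55-100/102 Hz). The transition shape
is a package choice — only the corner frequencies and the zero-phase FIR
class are externally fixed. The response is real and even, so no phase is
introduced at any frequency; the filter passes band-centre tones within 1 dB
and attenuates stop-edge tones by more than 40 dB (measured on the middle
third of a 30-s tone, away from onset transients).

Instantaneous phase is the angle of the Hilbert analytic signal of the
filtered trace, reported in degrees on $[0, 360)$ with the **oscillation peak
at 0 degrees** — the convention used for every phase quantity in the package.

## Theta cycles and gamma episodes

Theta troughs are strict local minima of the theta-filtered signal
($x_{t-1} > x_t$ and $x_{t+1} > x_t$). Minima qualify as cycle boundaries
when consecutive spacing falls within the period range of a ~3.5-Hz cycle,
taken here as the inverted filter passband $[1/4.5, 1/2.5]$ s — a
consistency choice, since only "approximately the 3.5-Hz period" is
externally prescribed. Retained troughs must be separated by at least 200 ms;
when two qualify within that window the deeper one wins (tie-break:
earliest).

Gamma episodes are detected from band-averaged time-varying wavelet power:

1. the power series is thresholded at its mean + 2 SD over the whole valid
   recording;
2. 160-ms windows are cut centred on each supra-threshold sample ("cut
   around" is read as centred);
3. in each window, the amplitude maximum of the band-filtered signal
   (absolute value; ties to the earliest sample) marks the episode;
4. duplicate maxima are discarded and retained maxima must be separated by at
   least 100 ms, the larger-amplitude member of a conflicting pair winning;
5. events outside the theta-state mask are then dropped, and each event
   carries a 400-ms analysis window.

The threshold is computed over the entire recording and events are restricted
to theta states *afterwards*; the alternative (thresholding on theta-only
samples) is a defensible reading of the source conventions, but the chosen
order is deterministic and stated explicitly. Because the threshold is
relative, detection is invariant to overall voltage scaling.

## Coupling and phase locking

Theta-gamma coupling is the mean resultant vector of the theta phases at the
detected gamma amplitude maxima: length in $[0, 1]$ is the coupling strength,
angle the preferred theta phase. The vector is computed from the **raw event
phases**, never from the 30-degree histogram (which is retained for display
and serialization); binning a phase sample before averaging biases the
resultant downward. Results with fewer than 30 events are flagged low-n
rather than suppressed.

Spike phase locking extracts the reference-band phase at each theta-state
spike time and summarizes it with the same resultant vector plus the Rayleigh
test ($Z = nR^2$, with the standard finite-$n$ corrected p-value); a unit is
phase-locked at $p < 0.05$. Units contribute an estimate only when at least
50 theta-state spikes are available — an explicit variance bound, since no
external criterion is prescribed — and skipped units are reported with the
reason rather than dropped silently. The gamma phase series for locking is
the continuous band-filtered phase over theta-state samples, not gated to
detected episodes. Waveform classification uses the peak-trough width of the
largest-amplitude channel's mean waveform with the 230-us threshold
(pyramidal above, interneuron below, exactly-at-threshold left unclassified);
extremum positions are refined by a local parabolic fit so widths are
insensitive to the 31.25-us waveform sampling grid.

## Group statistics

Two-group comparisons use the two-sided Mann-Whitney U test (exact when the
smaller group has at most 8 observations and no ties; otherwise the normal
approximation with tie and continuity corrections), reported as mean ± SEM
per group. Frequency-wise spectra comparisons are corrected with the
Benjamini-Hochberg false discovery rate — the specific FDR procedure is a
package choice and is stated in all reports. Session values can be averaged
into one value per animal to re-test conclusions under the assumption that
within-animal recordings share volume-conducted currents. The power analysis
is simulation-based: the smallest equal group size at which the Mann-Whitney
test attains a target power (default 0.9) is found by Monte-Carlo doubling
plus bisection, with a null effect reported as unattainable rather than as a
number.

## The synthetic-data generator

`generate_session()` builds sessions under the statistical model the analyses
assume:

* an alternating theta/slow state schedule with exponential dwell times
  quantized to the 10-s scoring bin (so schedule recovery is not confounded
  by bins straddling transitions) and a target theta occupancy — the default
  0.165 matches the ~16% theta occupancy typical of these recordings;
* theta (3.5 Hz) and slow-wave (1 Hz) sinusoids gated by state;
* gamma bursts: per theta cycle, a candidate burst occurs with probability
  `burst_rate_per_cycle`, its theta phase is accepted with probability
  proportional to $1 + m\cos(\theta - \phi_0)$ and its amplitude is scaled by
  the same factor, so both occurrence and amplitude follow the modulation law
  with depth $m \in [0,1]$. Bursts are Hann-enveloped packets (80 ms default)
  of a globally coherent 60-Hz carrier. A continuous mode replaces the bursts
  with an amplitude-modulated tone, which is the cleaner substrate for
  spike-locking recovery because the band-filtered phase is then defined at
  every theta-state sample;
* $1/f^\alpha$ background noise (default $\alpha = 1$) plus a white floor —
  realistic in spectrum, though not in the waveform asymmetries, harmonics
  and nonstationarities of real anesthetized LFP;
* spike trains thinned from an inhomogeneous Poisson process whose intensity
  is a product of von Mises factors in the theta phase and the gamma carrier
  phase, using exact continuous-time phases (sample-grid quantization of the
  intensity would bias recovered locking by up to half a phase-sample); the
  mean resultant length of such a train against either reference converges to
  the Bessel ratio $I_1(\kappa)/I_0(\kappa)$, which is the oracle used
  throughout the tests;
* mean waveforms with peak-trough widths drawn from a bimodal distribution
  (pyramidal 330 ± 35 us truncated to [260, 420]; interneuron 165 ± 25 us
  truncated to [110, 205]), leaving the empirically observed 210-250 us gap
  empty by construction with margin for measurement error.

Cohorts add per-animal lognormal jitter on amplitudes and concentrations and
Gaussian jitter on $m$ (clamped to $[0,1]$), with all seeds derived from one
base seed by a counter scheme.

What passing recovery tests does **not** show: robustness to real-data
features the generator omits — sharp-wave artifacts, electrode drift,
asymmetric theta waveforms (whose harmonics can masquerade as low-gamma),
volume conduction across channels, and non-sinusoidal slow waves. The
pipeline's contracts (unit energy, zero phase, relative thresholds,
separation rules) hold regardless, but effect sizes measured on real data
will differ from the generator's.

## Problem sizes and determinism

The verification suite chooses problem sizes that make the statistics
decisive while keeping a full run cheap: schedule recovery on 600-s sessions
at the native 2000 Hz; coupling recovery on ~1700-s sessions at 500 Hz (long
enough that >= 500 episodes survive detection even at $m = 1$, where
amplitude modulation suppresses anti-phase bursts); locking recovery at
1000 Hz, where the 60-Hz carrier advances only ~22 degrees per sample so
phase-lookup quantization attenuates the resultant by < 1%; and replicate
cohort comparisons (5 animals x 6 sessions per group) on 60-s sessions at
500 Hz with theta occupancy 0.5 — the sampling rate and session length scale
the computation, not the statistical contrast being tested. Every stochastic
step flows from an explicit seed: fixed-seed sessions are byte-identical and
the command-line pipeline writes a run manifest (seed, configuration hash,
version) beside every output.

## Known limitations

* The wavelet and FIR transforms assume regularly sampled, gap-free traces;
  there is no artifact rejection or interpolation.
* Episode detection reports at most one maximum per 100 ms within a band;
  genuinely overlapping gamma packets are merged by design.
* The Rayleigh test assumes independent phase samples; strongly
  rhythmic spike trains violate this, and its p-values should be read as
  descriptive screening, as is conventional.
* The group machinery implements two aggregation levels (sessions or cells,
  and animals); hierarchical session-within-animal models are out of scope.
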