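# thetagamma

Theta–gamma cross-frequency coupling and spike–LFP phase locking for local
field potential (LFP) recordings under urethane anesthesia.

## What it is for

In anesthetized rodents the cortical LFP alternates between a **theta state**
(2.5–4.5 Hz) and a **slow-wave state** (0.5–1.5 Hz). During theta states,
transient **gamma** oscillations (30–100 Hz; slow gamma 30–50 Hz, fast gamma
55–100 Hz) occur preferentially at particular phases of the theta cycle, and
single units fire preferentially at particular phases of theta and gamma.
Both forms of temporal coordination are degraded in mouse models of
Alzheimer's disease, which makes them quantitative readouts of circuit
integrity. This package implements the complete measurement chain for
electrophysiologists analyzing such recordings:

* complex **Morlet wavelet** time–frequency power,
  `w(t, f) = A exp(−t²/2σ_t²) exp(2iπft)` with `f/σ_f = 7` and unit-energy
  normalization, plus power normalization to the 5–10 Hz reference band;
* **state segmentation** into theta / slow-wave states by the per-10-s-bin
  power ratio (theta iff ratio ≥ 1) and state emergence rates;
* zero-phase **FIR bandpass filtering** (raised-cosine transitions at the
  standard corner tables), Hilbert **instantaneous phase** with the
  oscillation peak at 0°, **theta-cycle** selection, and **gamma-episode**
  detection at a mean + 2 SD band-power threshold with 160-ms search
  windows and a 100-ms separation rule;
* **cross-frequency coupling**: the mean resultant vector
  `R e^{iφ} = mean(exp(i·θ_k))` over the theta phases `θ_k` of gamma
  amplitude maxima — length `R` is the coupling strength, angle `φ` the
  preferred phase — with 30° phase histograms for display;
* **spike analysis**: waveform widths (half-maximum and peak–trough),
  pyramidal/interneuron classification at the 230-µs peak–trough threshold,
  theta-state firing rates, and phase locking with the **Rayleigh test**
  (`Z = nR²`);
* **group statistics**: Mann–Whitney U, per-frequency comparisons with
  Benjamini–Hochberg FDR, per-animal aggregation, and simulation-based
  power / sample-size analysis;
* a seeded **synthetic-session generator** (states, phase-modulated gamma
  bursts, 1/f noise, von Mises phase-locked spike trains, bimodal waveform
  widths) with ground-truth records, so every stage is verifiable by
  parameter recovery.

Everything is tidyverse-shaped: analysis results are tibbles, result
containers have `autoplot()` / `tidy()` / `glance()` methods, and session- or
cohort-level drivers (`analyze_session()`, `analyze_cohort()`,
`compare_cohorts()`) chain with the pipe.

## Worked example

Generate a synthetic session with strong coupling (modulation depth 0.8,
preferred theta phase 180°), then run the pipeline:

```r
library(thetagamma)

p <- generator_params(duration_s = 300, fs = 500, theta_occupancy = 0.5,
                      theta_dwell_s = 30, modulation_depth = 0.8,
                      preferred_phase_deg = 180, seed = 42)
session <- generate_session(p, session_id = "demo", animal_id = "m01")$session
session
#> <tg_session demo> animal m01 (WT): 1 LFP channel(s), 3 unit(s)

seg <- segment_states(session$lfp[[1]])
emergence_rate(seg, "theta")
#> [1] 0.4

session_cfc(session)
#>   session_id animal_id genotype  band n_events vector_length vector_angle_deg low_n
#> 1       demo       m01       WT gamma      178         0.589              176 FALSE
```

The recording spends 40% of its bins in theta state; 178 gamma episodes were
detected during theta, and their theta phases concentrate (resultant length
0.589) around 176° — recovering the programmed preferred phase of 180° from
the raw signal. Per-unit locking:

```r
res <- analyze_session(session, lock_references = c("theta", "gamma"))
res$units[, c("unit_id", "cell_class", "reference", "n_spikes",
              "vector_length", "rayleigh_p", "phase_locked")]
#>    unit_id  cell_class reference n_spikes vector_length rayleigh_p phase_locked
#> 1 demo_u01   pyramidal     theta      812        0.4532   1.02e-71         TRUE
#> 2 demo_u01   pyramidal     gamma      812        0.1317   7.19e-07         TRUE
#> 3 demo_u02   pyramidal     theta      769        0.4588   1.35e-69         TRUE
#> 4 demo_u02   pyramidal     gamma      769        0.0628   4.83e-02         TRUE
#> 5 demo_u03 interneuron     theta     1033        0.4695   7.92e-98         TRUE
#> 6 demo_u03 interneuron     gamma     1033        0.0661   1.10e-02         TRUE
```

All three units lock to theta with resultant length ≈ 0.45 — the Bessel-ratio
value `I₁(1)/I₀(1) ≈ 0.446` implied by the generator's von Mises
concentration κ = 1 — and lock more weakly to gamma, whose bursty presence
dilutes the measured phase preference. Units are classified from their mean
waveforms; every result row keeps its Rayleigh p-value and provenance.

Two cohorts are compared with
`generate_cohort() |> analyze_cohort() |> compare_cohorts()`, which reports
Mann–Whitney U with mean ± SEM per group for coupling (session-level),
locking and firing rate (unit-level, per cell class), and state metrics.

A thin command-line pipeline wraps the same functions
(`inst/cli/thetagamma.R`): `simulate` writes session bundles (JSON metadata,
CSV spike/waveform tables, binary or CSV LFP arrays, MD5 manifest),
`analyze` produces per-session/per-unit metric CSVs, and `compare` produces
group-comparison reports; all randomness flows from `--seed`.

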