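# oscillopipe

Analysis of *in vitro* hippocampal electrophysiology: theta rhythmicity,
theta-gamma cross-frequency coupling, chirp (ZAP) resonance sections, and
patch-clamp sweep features — plus a seeded synthetic-data generator that
emulates the statistical structure of such recordings so the entire pipeline
is testable without any recorded data.

Intended for electrophysiologists and methods developers who need a
reproducible, scriptable version of the slice-LFP analysis chain usually
assembled ad hoc in MATLAB: multitaper spectra, an autocorrelogram
rhythmicity score, the Tort modulation index with circular-shift surrogate
significance, and the standard intracellular feature set (f-I slope,
adaptation, PSC amplitudes/kinetics/failures).

## The statistics at the core

* **Oscillation strength** — height (in %) of the first side peak of the
  normalized autocorrelogram of the theta-filtered trace: 100 for a perfect
  oscillator, ~0 for noise.
* **Modulation index (MI)** — amplitude of a fast band binned by theta
  phase (18 x 20 deg bins), normalized to a distribution \(P\); then
  \(\mathrm{MI} = \big(\log N + \sum_j P_j \log P_j\big)/\log N \in [0,1]\),
  the KL divergence from uniform. Significance: observed MI must exceed
  mean + 2 SD of MIs from circularly time-shifted amplitude surrogates.
* **Comodulogram / band peak** — MI per 5 Hz amplitude band over
  5-400 Hz against the dominant-theta phase (filtered +/-1 Hz around the
  dominant frequency); per-experiment value = maximum MI in slow gamma
  (25-45 Hz) or fast gamma (150-250 Hz).
* **Patch features** — spike threshold (dV/dt >= 20 mV/ms), amplitude,
  half-width, AHP, membrane resistance, sag, f-I slope over threshold to
  threshold + 200 pA, adaptation = 100 (1 - first ISI / last ISI), evoked
  PSC amplitude/latency/rise/half-width/CV/failure rate, normalized I/O
  curves, spontaneous event frequency.

## Worked example

```r
library(oscillopipe)

spec <- lfp_spec(
  theta_freq_hz = 4.5, theta_amp = 3, phase_diffusion = 2, amp_cv = 0.3,
  gamma_components = list(gamma_component(35, 10, 0.5, coupling_kappa = 2)),
  noise_amp = 1, fs_hz = 500, duration_s = 30, seed = 1)
tr <- generate_coupled_lfp(spec)

rhythmicity(tr)
#> <rhythmicity> strength 68.9%, theta 4.50 Hz

com <- comodulogram(tr, amp_lo = 25, amp_hi = 45, n_surrogates = 200,
                    seed = 1)
band_peak(com, band_spec(25, 45))
#> $peak_mi   [1] 0.00129
#> $peak_freq_hz [1] 37.5
com$significant
#> [1] TRUE TRUE TRUE TRUE
```

The strength (68.9%) says the theta carrier keeps cycle-to-cycle phase memory
at this diffusion level; the band-peak MI (1.3e-3 at 37.5 Hz, flagged
significant against 200 circular-shift surrogates in every 5 Hz band of the
slow-gamma range) recovers the 35 Hz coupled component the generator put
in. MI magnitudes are small by construction — the literal 5 Hz amplitude
bands pass only part of the theta-rate modulation (see the methods
vignette) — but calibration (kappa = 0 gives no significance) is exact.

A two-group end-to-end experiment:

```r
report <- run_cohort(default_cohort_config(duration_s = 60), master_seed = 1)
report
#> <cohort_report> 10 animals/group, test = t
#> strength_percent: 45.5 +/- 1.3 vs 33.3 +/- 1.03, t p = 8.043e-07 *
#> peak_sd: 0.972 +/- 0.231 vs 1.14 +/- 0.233, t p = 0.6121
#> theta_freq_hz: 4.4 +/- 0.135 vs 4.36 +/- 0.124, t p = 0.8303
#> theta_power: 4.57 +/- 2.13 vs 5.43 +/- 1.96, t p = 0.7697
#> sg_peak_mi: 0.000679 +/- 0.00016 vs 9.34e-05 +/- 1.38e-05, t p = 0.00185 *
#> fg_peak_mi: 0.00117 +/- 0.000226 vs 0.000154 +/- 2.29e-05, t p = 0.0003017 *
#> sg_power: 0.292 +/- 0.147 vs 0.453 +/- 0.157, t p = 0.4649
#> fg_power: 0.14 +/- 0.0698 vs 0.185 +/- 0.0635, t p = 0.6366
```

The pattern — oscillation strength and both band-peak MIs significant;
theta frequency, theta power and both gamma powers not — is the designed
contrast the acceptance suite checks over 20 replicate cohorts.

## Command line

```sh
exec/oscillopipe simulate --config spec.json --seed 3 --out trace.csv
exec/oscillopipe rhythm   --trace trace.csv --theta-band 3:8
exec/oscillopipe cfc      --trace trace.csv --amp-range 5:400 --surrogates 200
exec/oscillopipe cohort   --seed 1 --n 10 --out-dir results/
```

Traces are two-column CSV (`time_s,value`) with a JSON sidecar
(`fs_hz, units, kind`); configs are JSON with the same field names as
`lfp_spec()`.

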