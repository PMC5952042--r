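---
title: "Methods: theta-gamma coupling and intracellular analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: theta-gamma coupling and intracellular analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oscillopipe)
```

## What this package computes

`oscillopipe` implements the analysis chain used to characterise early
network-level changes in hippocampal slice electrophysiology: multitaper
power spectra of the local field potential (LFP), an autocorrelogram-based
theta rhythmicity score, theta-gamma phase-amplitude coupling quantified by
the Kullback-Leibler modulation index (MI) with circular-shift surrogate
testing, section-wise analysis of chirp (ZAP) driven responses, and
patch-clamp sweep analysis (spike shape, f-I curves, evoked and spontaneous
post-synaptic currents). A seeded synthetic-data module generates every
class of input the pipeline consumes, so each stage is testable without any
recorded data.

## The signal model behind the synthetic LFP

A synthetic recording is

$$x(t) = A_\theta\,e(t)\cos\varphi(t)
  + \sum_k A_k \frac{e^{\kappa_k \cos(\varphi(t)-\phi_k)}}{\sqrt{I_0(2\kappa_k)}}
    \cos\varphi_k(t) + \sigma_n\,n(t)$$

* **Theta carrier.** $\varphi(t)$ is a Wiener phase track,
  $d\varphi = 2\pi f_\theta\,dt + \sigma_\varphi\sqrt{dt}\,dW$. The
  diffusion rate $\sigma_\varphi$ (rad/sqrt(s)) is the rhythmicity dial: the
  autocorrelation envelope decays like $e^{-\sigma_\varphi^2 \tau/2}$, so
  oscillation strength (the first autocorrelogram side peak) falls smoothly
  as $\sigma_\varphi$ rises. Frequency jitter per cycle was rejected as the
  control because it produces nonstationary spectra; phase diffusion gives a
  stationary Lorentzian line of FWHM $\sigma_\varphi^2/2\pi$ Hz.
* **Amplitude envelope.** $e(t)$ is a slow unit-variance
  Ornstein-Uhlenbeck process (tau = 0.35 s, about 1.5 theta cycles) scaled
  to the requested coefficient of variation and floored at 0.05. A smooth
  envelope rather than independent per-cycle draws was chosen so that the
  theta-band filter (3-8 Hz) does not strip the amplitude fluctuations the
  waveform-SD statistic is supposed to see; per-cycle peak amplitudes still
  carry the requested CV.
* **Gamma components.** Each component's carrier has its own phase
  diffusion, set so its linewidth equals the requested bandwidth. Its
  amplitude is the von Mises envelope
  $e^{\kappa\cos(\varphi-\phi_{pref})}/\sqrt{I_0(2\kappa)}$: at $\kappa = 0$
  it is exactly constant (exactly uncoupled), and the RMS normalisation
  keeps gamma band *power* independent of $\kappa$. (Normalising by the
  circular mean $I_0(\kappa)$, the other natural choice, fixes the mean
  amplitude but lets power grow as $I_0(2\kappa)/I_0(\kappa)^2$ — about
  2.5-fold at $\kappa = 2.5$ — which would confound coupling with power in
  the group comparison.) That matches the empirical observation the pipeline must be
  able to reproduce: coupling can change without a change in gamma power.
* **Noise.** Gaussian noise shaped to a $1/f$ spectrum (exponent 1 by
  default, amplitude in uV). Slice recordings do not come with a published
  noise floor, so pink noise of order the gamma amplitudes is the default.

Seeding: a single integer seed is expanded (via `sample.int`) into
independent sub-seeds for the theta phase, the envelope, the noise and each
gamma component, so adding a component does not silently change the others.
Identical spec + seed regenerates traces bit-exactly, and generators restore
the caller's RNG state.

## Filtering and the analytic signal

All band-pass filtering is 4th-order Butterworth applied forward-backward
(zero phase) — phase is a measured quantity here, so the filter must not
shift it. Filtering runs on second-order sections: transfer-function
coefficient forms of an order-8 bandpass at, say, 5-7 Hz on a 5 kHz trace
are numerically unstable (this was verified to produce NaNs in double
precision), while the SOS cascade reproduces `scipy.signal.sosfiltfilt` to
numerical precision. The first and last 2 s of every phase/amplitude series
are excluded from downstream statistics (filter and Hilbert transients).

Phase is reported in degrees in (-180, 180], 0 at the oscillation peak and
+/-180 at the trough, increasing with time (a quarter period after a peak
the phase is +90).

## Spectra

Power spectra are multitaper estimates with seven DPSS tapers. Only the
taper count is conventionally reported, so the time-bandwidth product is set
to nw = 4, the standard pairing (2 nw - 1 = 7). The DPSS are computed from
the tridiagonal commuting matrix by Sturm bisection plus inverse iteration
(compiled code), which is exact at any trace length and was verified against
`scipy.signal.windows.dpss` to 1e-14. With unit-energy tapers the one-sided
density integrates to the sample variance (Parseval), so band power is in
squared trace units; band integration uses the trapezoidal rule. Theta-band
power is integrated in 5 s bins and averaged.

## Rhythmicity

The oscillation-strength index is the height of the first positive side peak
of the normalized autocorrelogram of the theta-filtered trace, times 100,
searched in the lag window [0.5, 1.5]/f_theta and clipped to [0, 100]. The
source study describes only "a value derived from the autocorrelogram"; the
first side peak is the simplest such scalar, it is bounded, equals 100 for a
pure sinusoid and ~0 for noise, and produces values around 30% for noisy but
rhythmic traces, consistent with the printed control range. The biased
autocorrelation estimator is used (guaranteeing |acf| <= 1); its bias factor
at theta lags of a 100 s epoch is ~0.2% and is ignored.

The cycle-averaged waveform detects theta peaks (local maxima above zero,
refractory half a cycle, earliest sample on ties), averages raw-trace
windows of +/-1 period, and reports the SD of the per-cycle filtered peak
amplitudes. Whether that SD is in uV or normalized units is not stated in
the source; it is reported in uV here (the statistic is used comparatively,
so the unit cancels in group contrasts).

## Phase-amplitude coupling

The MI is the Tort KL-divergence statistic: amplitudes are binned by theta
phase into 18 bins of 20 degrees, the per-bin means normalized to a
distribution P, and MI = (log N + sum P log P)/log N, in [0, 1].

Two deliberate numerical choices:

* **Empty bins.** The entropy uses the standard 0 log 0 = 0 convention,
  under which MI is finite for any admissible P and the analytic bounds are
  exact: MI = 0 for phase-uniform amplitude and MI = 1 when all amplitude
  mass falls in one bin, both to 1e-12. (An additive epsilon floor in empty
  bins was considered and rejected: it perturbs the MI = 1 bound by ~1e-10,
  which the acceptance tolerance does not allow, and it is unnecessary for
  finiteness.)
* **Amplitude filter bandwidth.** The comodulogram filters each 5 Hz band
  literally (center +/- 2.5 Hz), as the methods text reads. This has a real
  consequence: a 5 Hz-wide filter's envelope cannot follow amplitude
  modulation faster than ~2.5 Hz, so theta-frequency modulation reaches the
  envelope only through the filter skirts and measured MI values are small
  (1e-4 to 1e-3 for strongly coupled synthetic data). Detection is
  nevertheless robust, because the circular-shift surrogate floor shrinks
  in proportion; all calibration criteria (false-positive rate, kappa
  monotonicity, peak localisation) pass with the literal reading, so it is
  kept. Users comparing absolute MI magnitudes across studies should be
  aware they depend strongly on this bandwidth choice.

The theta phase reference is extracted by finding the dominant frequency in
3-8 Hz (multitaper) and filtering from 1 Hz below to 1 Hz above it. The
reference warns when the dominant frequency sits at the search-band edge or
drifts by more than 1 Hz between recording halves (chirps and other
nonstationary inputs).

Surrogates circularly shift the amplitude series by a uniform random offset
of at least one theta period (preserving the amplitude autocorrelation,
destroying phase alignment); the observed MI is significant when it exceeds
the surrogate mean by more than twice the surrogate SD. Under normality
this one-sided rule has a nominal rate of ~2.3%; the empirical
false-positive rate on uncoupled synthetic data is below 10% (tested over
50 seeds). Surrogates are recomputed per 5 Hz band (conservative; whether
the original analysis did this per band or once per band-peak is unstated).
The default 200 surrogates is a runtime compromise; the count is a
parameter.

The per-experiment summary is the *band-peak MI*: the maximum MI over band
centers inside slow gamma (25-45 Hz) or fast gamma (150-250 Hz), ties going
to the lower frequency.

## ZAP (chirp) analysis

The 0-12 Hz sweep (linear by default; exponential also supported — the
source describes both dialects) is cut into six 2 Hz sections by the
instantaneous stimulus frequency, half-open intervals [lo, hi). Within a
section the phase reference is the section's own drive band (the drive
frequency is known and nonstationary, so a global dominant frequency would
be wrong), floored at 0.5 Hz so the 0-2 Hz section remains filterable.
Sections shorter than 3 driven cycles are marked missing and excluded from
the peak. Normalized theta power is each section's integrated drive-band
power divided by the sum over sections (sum-to-1; the normalisation
denominator is unstated in the source, and the sum convention makes shares
comparable across preparations).

## Intracellular analysis

Spikes are upward dV/dt crossings of 20 mV/ms followed by a peak above 0 mV
within 5 ms, with 1 ms refractory — the standard criterion for fast-spiking
cells. Shape features: threshold = Vm at the criterion crossing; amplitude
= peak - threshold; half-width at half amplitude above threshold with
linear interpolation of the crossings; AHP = minimum within 20 ms after the
peak, minus threshold. The synthetic spike is piecewise linear with a
sub-threshold approach ramp at 15 mV/ms, so every shape parameter is exactly
recoverable at sample resolution.

f-I analysis: rate = spike count / step duration; threshold current t =
smallest current evoking any spike; slope = least squares over [t, t+200 pA]
(the conventional analysis window); maximal firing = largest mean rate over
the step (the reciprocal minimum ISI alternative is deliberately not the
default and is easy to add); adaptation = 100 (1 - first ISI / last ISI) at
the highest current with at least three spikes. The adaptation formula is
stated prominently because the source gives only "adaptation (%)" and
alternatives (first/mean, slope of ISI ramp) exist.

Evoked responses: noise SD is the median absolute deviation of the
pre-stimulus baseline; a sweep is a failure when the baseline-subtracted
extremum within 20 ms does not exceed 3 noise SDs. When noise is present,
detection runs on a 0.5 ms boxcar-smoothed copy: the raw extremum of pure
noise over a 20 ms window exceeds 3 SD in roughly a third of sweeps, which
would wreck failure-rate calibration; smoothing restores it without
touching the noiseless analytic anchors (amplitude exact, 10-90% rise of a
mono-exponential = ln 9 tau), which bypass smoothing. The same smoothing
applies to spontaneous event detection (threshold still expressed in raw
noise SDs). Latency is stimulus onset to the 10%-of-peak crossing; the CV
is computed over successes only. I/O curves normalise per-duration mean
amplitudes to the per-cell maximum (maximum exactly 1).

## The synthetic cohort and what a green end-to-end test establishes

The end-to-end test simulates a control group (rhythmic theta, slow- and
fast-gamma coupling) against a "mutant" group with raised phase diffusion
(3.5 -> 4.5 rad/sqrt(s)), abolished coupling (kappa -> 0) and *matched*
amplitudes, n = 10 per group, and requires the qualitative significance
pattern: oscillation strength and both band-peak MIs differ; theta
frequency, theta power and both gamma powers do not.

Design choices that make this a fair emulation rather than a rigged one:

* **Between-animal heterogeneity is mandatory.** Every animal receives a
  lognormal amplitude gain (CV 1.0, same law in both groups) on all
  components and noise, plus Gaussian theta-frequency jitter (SD 0.3 Hz).
  The gain CV is taken from the source's own dispersions (theta power
  7.07 +/- 2.2 SEM over n = 10 implies a between-animal CV near 1). It is
  also what makes "theta power not significant" physically honest: phase
  diffusion unavoidably moves a few percent of theta power outside the
  fixed 3-8 Hz integration band, and with homogeneous amplitudes a t-test
  at n = 10 would detect that systematic few-percent difference — a
  pattern the real experiment, with its large inter-animal variability,
  does not show.
* **Theta at 4.5 Hz.** Within the observed slice range (group means of
  4.9 and 6.2 Hz). The slower carrier matters for the literal 5 Hz
  amplitude bands: modulation sidebands at f_theta pass the +/-2.5 Hz
  envelope bandwidth far better at 4.5 Hz than at 6 Hz, giving control MI
  values (~1-3 x 10^-3) on the order the source prints, with clean
  separation from the uncoupled floor.
* **Coupling strengths** kappa = 2.5 for both bands and gamma bandwidths of
  10 Hz were fixed so that the designed effect is unambiguous at n = 10;
  they are effect-size choices of the stated world, not fitted numbers.

What a green test establishes: the pipeline detects designed rhythmicity
and coupling differences and does not invent amplitude differences, under
heterogeneity comparable to the real experiment. What it does not
establish: agreement with any printed group value (no data were deposited),
realism of the waveform shape beyond second-order statistics, or behaviour
under artifacts (movement, line noise) that the generator does not emulate.
Group comparisons use Student's pooled t-tests by default (Welch and
Mann-Whitney available), two-sided, alpha = 0.05, with no correction across
the eight metrics — matching the reporting conventions of the source
analysis.

## Runtime scaling in the tests

The acceptance tests run the stated numbers of seeds/surrogates but reduce
sampling rate (500-1000 Hz instead of 5000 Hz) and, for the 20-cohort
end-to-end test, the recording length (60 s instead of 100 s); every band
analysed stays far below Nyquist. One quantity proved sensitive to epoch
length: the argmax of the 79-band comodulogram, whose null-MI floor widens
on short traces, occasionally (~5% of runs at 30 s) overtaking the true
coupling band. The peak-localisation test therefore runs on full 100 s
epochs; the other calibrations were verified insensitive to the scaling.

## Known limitations

* MI magnitudes depend strongly on the literal 5 Hz amplitude bandwidth
  (see above); cross-study comparison of absolute MI requires matching that
  choice.
* The synthetic neuron is phenomenological (template spikes, prescribed f-I
  law), not conductance-based; it validates feature *extraction*, not
  biophysics.
* `mad()` noise estimates assume events are sparse (< ~10% duty cycle);
  very high event rates inflate the threshold.
* The 0-2 Hz ZAP section is analysed with a 0.5 Hz filter floor; responses
  genuinely below 0.5 Hz are attenuated.
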