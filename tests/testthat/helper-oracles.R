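# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own code paths.

# brute-force Tort MI: bin-by-loop, direct KL evaluation
oracle_mi <- function(phase_deg, amplitude, n_bins = 18) {
  width <- 360 / n_bins
  means <- numeric(n_bins)
  for (j in seq_len(n_bins)) {
    lo <- -180 + (j - 1) * width
    hi <- lo + width
    sel <- phase_deg > lo & phase_deg <= hi
    means[j] <- if (any(sel)) mean(amplitude[sel]) else 0
  }
  p <- means / sum(means)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  (log(n_bins) - h) / log(n_bins)
}

# closed-form 10-90% rise time of a saturating exponential
rise_ln9 <- function(tau_ms) log(9) * tau_ms

# time (ms) at which the difference-of-exponentials kernel reaches
# frac * peak on its rising limb, found by bisection on the normalised kernel
oracle_doe_frac_time <- function(frac, rise_tau, decay_tau) {
  tp <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  nrm <- exp(-tp / decay_tau) - exp(-tp / rise_tau)
  f <- function(t) (exp(-t / decay_tau) - exp(-t / rise_tau)) / nrm - frac
  stats::uniroot(f, c(1e-9, tp))$root
}

# unit-variance white-noise trace
white_trace <- function(n, fs, seed) {
  set.seed(seed)
  trace(rnorm(n), fs_hz = fs)
}

sine_trace <- function(freq, fs, dur, amp = 1, phase = 0) {
  t <- seq_len(round(fs * dur)) / fs
  trace(amp * cos(2 * pi * freq * t + phase), fs_hz = fs)
}

# a standard coupled spec used across CFC tests (slow theta so the 6 Hz-wide
# amplitude bands can follow the modulation)
coupled_spec <- function(kappa, seed, fs = 500, dur = 30, center = 35,
                         theta = 4.5, pd = 2, noise = 1) {
  lfp_spec(theta_freq_hz = theta, theta_amp = 3, phase_diffusion = pd,
           amp_cv = 0.3,
           gamma_components = list(
             gamma_component(center, 10, 0.5, coupling_kappa = kappa)),
           noise_amp = noise, fs_hz = fs, duration_s = dur, seed = seed)
}

# band-peak MI of one coupled recording, no surrogates
quick_band_peak <- function(spec, lo = 25, hi = 45) {
  tr <- generate_coupled_lfp(spec)
  com <- suppressWarnings(
    comodulogram(tr, amp_lo = lo, amp_hi = hi, n_surrogates = 0))
  band_peak(com, band_spec(lo, hi))$peak_mi
}

# hand-built membrane-potential trace with triangular spikes at given onset
# times; rise 0.25 ms to +40 mV from -40 mV threshold, passing the 20 mV/ms
# detection criterion, baseline -60 mV
make_spike_train_trace <- function(spike_ms, fs = 20000, dur_ms = 700) {
  dt <- 1000 / fs
  n <- round(dur_ms / dt)
  x <- rep(-60, n)
  nr <- round(0.25 / dt)
  nf <- round(0.75 / dt)
  napp <- round(2 / dt)  # sub-criterion approach ramp (10 mV/ms)
  for (s in spike_ms) {
    i0 <- round(s / dt) + 1
    approach <- -60 + (1:napp) * 20 / (napp + 1)
    up <- -40 + (0:nr) * 80 / nr
    dn <- 40 - (1:nf) * 100 / nf
    idx <- (i0 - napp) + seq_len(napp + nr + nf + 1) - 1
    seg <- c(approach, up, dn)
    ok <- idx <= n & idx >= 1
    x[idx[ok]] <- seg[ok]
  }
  trace(x, fs_hz = fs, units = "mV", kind = "vm")
}
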