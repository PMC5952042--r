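test_that("spike detection counts templates and ignores subthreshold sweeps", {
  ns <- neuron_spec(rheobase_pa = 100, fi_slope_hz_per_pa = 0.2, seed = 2)
  sw <- generate_step_sweeps(ns, c(50, 200), noise_mv = 0.02)
  expect_length(detect_spikes(sw[[1]]), 0)
  expect_length(detect_spikes(sw[[2]]), 12)
  # amplitude doubling preserves the spike count
  doubled <- sw[[2]]
  doubled$vm$samples <- doubled$vm$samples * 2
  expect_length(detect_spikes(doubled), 12)
})

test_that("spike shape features are exact on the piecewise-linear template", {
  # threshold -40, peak +40 (amplitude 80), rise 0.25 ms, fall 0.75 ms
  # through threshold: half-amplitude width = rise/2 + (fall to half level)
  tr <- make_spike_train_trace(c(100, 200, 300))
  idx <- detect_spikes(tr)
  expect_length(idx, 3)
  sf <- spike_shape_features(tr, idx)
  expect_equal(sf$threshold_mv, -40, tolerance = 1e-9)
  expect_equal(sf$amplitude_mv, 80, tolerance = 1e-9)
  # fall spans 100 mV in 0.75 ms; half level (0 mV) crossed 0.3 ms past peak
  expect_equal(sf$halfwidth_ms, 0.25 / 2 + 0.75 * (40 / 100), tolerance = 0.01)
  # AHP: trace dips to -60 baseline after the spike -> -20 below threshold
  expect_equal(sf$ahp_mv, -20, tolerance = 1e-9)
})

test_that("passive properties recover the generator's parameters", {
  ns <- neuron_spec(resting_mv = -62, input_resistance_mohm = 200,
                    sag_mv = 1.5, seed = 4)
  sw <- generate_step_sweeps(ns, c(-100, -50, 250))
  pp <- passive_properties(sw)
  expect_lt(abs(pp$resting_mv - -62), 0.5)
  expect_lt(abs(pp$membrane_resistance_mohm - 200), 4)
  expect_lt(abs(pp$sag_mv - 1.5), 0.4)
  ns0 <- neuron_spec(sag_mv = 0, seed = 5)
  sw0 <- generate_step_sweeps(ns0, c(-50, 250), noise_mv = 0)
  expect_lt(passive_properties(sw0)$sag_mv, 0.2)
  expect_error(passive_properties(sw[3]), "hyperpolarising")
})

test_that("f-I analysis: exact slope line and adaptation definition", {
  # rates 20/40/60 Hz at t+100/t+200/t+300 -> slope over [t, t+200] = 0.2
  ns <- neuron_spec(rheobase_pa = 100, fi_slope_hz_per_pa = 0.2,
                    adaptation_frac = 0, seed = 6)
  sw <- generate_step_sweeps(ns, c(-50, 100, 200, 300, 400), noise_mv = 0.02)
  fi <- fi_analysis(sw)
  expect_equal(fi$fi_curve$threshold_current_pa, 200)
  expect_equal(fi$fi_slope_hz_per_pa, 0.2, tolerance = 1e-6)
  expect_equal(fi$max_firing_hz, 60, tolerance = 1e-6)
  # non-adapting generator: adaptation ~ 0
  expect_lt(abs(fi$adaptation_percent), 3)
  # hand-built ISIs 10,10,20,20 ms -> 100 * (1 - 10/20) = 50%
  tr <- make_spike_train_trace(c(100, 110, 120, 140, 160))
  sweep <- structure(list(vm = tr, current_pa = 700,
                          step_window_s = c(0.05, 0.65)),
                     class = "step_sweep")
  filler <- generate_step_sweeps(neuron_spec(seed = 7), c(250, 350),
                                 noise_mv = 0.02)
  fi2 <- fi_analysis(c(filler, list(sweep)))
  expect_lt(abs(fi2$adaptation_percent - 50), 0.5)
  expect_error(fi_analysis(generate_step_sweeps(neuron_spec(seed = 8),
                                                c(-50, 10))),
               "suprathreshold")
})

test_that("full feature table recovers 20 random synthetic neurons", {
  # reduced-width version of the acceptance recovery (5 neurons here)
  set.seed(77)
  for (i in 1:5) {
    ns <- neuron_spec(
      resting_mv = runif(1, -70, -55),
      input_resistance_mohm = runif(1, 100, 300),
      rheobase_pa = runif(1, 80, 200),
      fi_slope_hz_per_pa = runif(1, 0.2, 0.6),
      adaptation_frac = runif(1, 0, 0.4),
      spike_peak_mv = runif(1, 30, 50),
      spike_threshold_mv = runif(1, -45, -35),
      spike_halfwidth_ms = runif(1, 0.4, 0.9),
      ahp_mv = runif(1, -20, -10),
      sag_mv = runif(1, 0, 2),
      seed = 1000 + i)
    sw <- generate_step_sweeps(ns, c(-100, -50, seq(50, 600, by = 50)))
    pf <- patch_features(sw)
    expect_lt(abs(pf$resting_mv - ns$resting_mv), 0.5)
    expect_lt(abs(pf$ap_threshold_mv - ns$spike_threshold_mv), 0.5)
    expect_lt(abs(pf$spike_amplitude_mv -
                  (ns$spike_peak_mv - ns$spike_threshold_mv)), 0.5)
    expect_lt(abs(pf$ahp_mv - ns$ahp_mv), 0.5)
    expect_equal(pf$membrane_resistance_mohm, ns$input_resistance_mohm,
                 tolerance = 0.05)
    expect_equal(pf$fi_slope_hz_per_pa, ns$fi_slope_hz_per_pa,
                 tolerance = 0.05)
  }
})

test_that("evoked measurement: amplitudes, kinetics, failures", {
  # noiseless template: amplitude exact, rise = closed form
  ps <- psc_spec(peak_pa = -50, rise_tau_ms = 1, decay_tau_ms = 8,
                 noise_pa = 0, latency_jitter_ms = 0, seed = 3)
  me <- measure_evoked(generate_psc_sweeps(ps, 2))
  expect_equal(me$mean_amp_pa, -50, tolerance = 0.01)  # sample resolution
  t10 <- oracle_doe_frac_time(0.1, 1, 8)
  t90 <- oracle_doe_frac_time(0.9, 1, 8)
  expect_equal(me$mean_rise_ms, t90 - t10, tolerance = 0.1)
  # mono-exponential rise: 10-90% time = ln(9) tau (sample-resolution check)
  fs <- 10000; tau <- 1
  t <- seq_len(fs) / fs * 1000  # ms
  x <- numeric(length(t))
  on <- t > 50
  x[on] <- -50 * (1 - exp(-(t[on] - 50) / tau))
  sweep <- trace(x, fs_hz = fs, units = "pA", kind = "im")
  m1 <- measure_evoked(list(sweep), stim_onset_ms = 50, window_ms = 30)
  expect_equal(m1$mean_rise_ms, rise_ln9(tau), tolerance = 0.11)
  # saturated sweeps: all-failure duration flagged missing in io_curve
  io <- generate_io_sweeps(psc_spec(noise_pa = 1, seed = 9),
                           durations_us = seq(100, 900, by = 100),
                           n_per_duration = 6)
  ioc <- io_curve(io)
  expect_equal(max(ioc$normalized_amplitudes[!ioc$missing]), 1)
  plateau <- ioc$normalized_amplitudes[ioc$stimulus_durations_us >= 400]
  expect_true(all(abs(plateau - 1) < 0.05))
  # linear (unsaturated) region is monotone
  ramp <- ioc$normalized_amplitudes[ioc$stimulus_durations_us <= 400]
  expect_true(all(diff(ramp) > 0))
})

test_that("spontaneous detection: empty trace and noise monotonicity", {
  fs <- 5000
  silent <- trace(rnorm(30 * fs, sd = 2), fs_hz = fs, units = "pA",
                  kind = "im")
  ev <- detect_spontaneous(silent)
  expect_equal(ev$frequency_hz, 0, tolerance = 0.2)
  base <- generate_spontaneous_psc(
    psc_spec(peak_pa = -20, noise_pa = 1, event_rate_hz = 6, seed = 10), 40)
  n1 <- detect_spontaneous(base)$n_events
  noisy <- base
  set.seed(1); noisy$samples <- noisy$samples + rnorm(length(base$samples), 0, 4)
  n2 <- detect_spontaneous(noisy)$n_events
  expect_lte(n2, n1)
})
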