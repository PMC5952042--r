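test_that("generators are bit-deterministic given spec + seed", {
  sp <- coupled_spec(2, seed = 7)
  expect_identical(generate_coupled_lfp(sp)$samples,
                   generate_coupled_lfp(sp)$samples)
  z1 <- generate_zap_response(sp, 0, 12, "linear")
  z2 <- generate_zap_response(sp, 0, 12, "linear")
  expect_identical(z1$trace$samples, z2$trace$samples)
  ns <- neuron_spec(seed = 3)
  s1 <- generate_step_sweeps(ns, c(-50, 300))
  s2 <- generate_step_sweeps(ns, c(-50, 300))
  expect_identical(s1[[2]]$vm$samples, s2[[2]]$vm$samples)
  ps <- psc_spec(seed = 4, failure_prob = 0.3)
  expect_identical(generate_psc_sweeps(ps, 5)[[3]]$samples,
                   generate_psc_sweeps(ps, 5)[[3]]$samples)
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_coupled_lfp(sp)); after <- runif(1)
  expect_identical(before, after)
})

test_that("LFP spec invariants are enforced", {
  expect_error(lfp_spec(fs_hz = 60, gamma_components =
    list(gamma_component(35, 10, 1, 0))), "twice")
  expect_error(gamma_component(35, 10, 1, coupling_kappa = -1), "kappa")
  expect_error(lfp_spec(duration_s = 0), "duration")
  expect_error(lfp_spec(theta_amp = NaN), "theta_amp")
})

test_that("mean gamma power is kappa-invariant (von Mises normalisation)", {
  pw <- vapply(c(0, 2, 4), function(k) {
    mean(vapply(1:5, function(s) {
      sp <- coupled_spec(k, seed = 900 + s, dur = 20, noise = 0)
      tr <- generate_coupled_lfp(sp)
      band_power_bins(tr, band_spec(25, 45))$mean_power
    }, numeric(1)))
  }, numeric(1))
  expect_lt(max(abs(pw / pw[1] - 1)), 0.15)
})

test_that("background noise has the requested spectral slope", {
  sp <- lfp_spec(theta_amp = 0, noise_amp = 1, noise_exponent = 1,
                 fs_hz = 500, duration_s = 40, seed = 11)
  tr <- generate_coupled_lfp(sp)
  est <- multitaper_psd(tr)
  keep <- est$freqs_hz > 1 & est$freqs_hz < 200
  fit <- stats::lm(log(est$psd[keep]) ~ log(est$freqs_hz[keep]))
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.15)
})

test_that("multitaper peak of a noise-free theta spec hits theta_freq_hz", {
  sp <- lfp_spec(theta_freq_hz = 6.2, phase_diffusion = 0, amp_cv = 0,
                 noise_amp = 0, fs_hz = 500, duration_s = 20, seed = 1)
  est <- multitaper_psd(generate_coupled_lfp(sp))
  expect_equal(est$freqs_hz[which.max(est$psd)], 6.2, tolerance = 0.05)
})

test_that("zap generator: sweep laws, resonance and flat envelope", {
  sp <- lfp_spec(theta_amp = 1, phase_diffusion = 0, amp_cv = 0,
                 noise_amp = 0, fs_hz = 500, duration_s = 120, seed = 2)
  z <- generate_zap_response(sp, 0, 12, "linear")
  i60 <- round(60 * 500)
  expect_equal(z$stim_log$freq_hz[i60], 6, tolerance = 0.01)
  # flat envelope when resonance gain is zero
  env <- analytic_amplitude(z$trace)
  mid <- 5000:55000
  expect_lt(stats::sd(env[mid]) / mean(env[mid]), 0.05)
  # exponential sweep: section durations strictly decreasing
  ze <- generate_zap_response(sp, 0, 12, "exponential")
  sec <- section_by_stimulus(ze$trace, ze$stim_log)
  durs <- vapply(sec$sections, function(s) trace_duration(s$trace),
                 numeric(1))
  expect_true(all(diff(durs) < 0))
  expect_error(generate_zap_response(sp, 5, 3), "f_start")
  expect_error(generate_zap_response(sp, 0, 12, "triangular"))
})

test_that("step sweeps follow the f-I contract and Ohm's law", {
  ns <- neuron_spec(rheobase_pa = 100, fi_slope_hz_per_pa = 0.2,
                    input_resistance_mohm = 200, seed = 5)
  sw <- generate_step_sweeps(ns, c(-50, 200), noise_mv = 0)
  # I = rheobase + 100, slope 0.2 -> 12 spikes in 600 ms
  expect_length(detect_spikes(sw[[2]]), 12)
  # steady-state deflection -10 mV at -50 pA, 200 MOhm
  x <- sw[[1]]$vm$samples
  fs <- sw[[1]]$vm$fs_hz
  i_off <- round(sw[[1]]$step_window_s[2] * fs)
  vss <- mean(x[(i_off - round(0.1 * fs)):i_off])
  expect_equal(vss - ns$resting_mv, -10, tolerance = 0.2)
})

test_that("PSC sweeps: failures, latency and spontaneous rate", {
  # binomial 99% interval for failure fraction at p = 0.5, n = 200
  ps <- psc_spec(failure_prob = 0.5, seed = 6)
  me <- measure_evoked(generate_psc_sweeps(ps, 200))
  expect_gte(me$failure_rate, 0.41); expect_lte(me$failure_rate, 0.59)
  # noiseless, jitterless: latency = latency_ms + kernel time-to-10%,
  # exact at sample resolution
  psn <- psc_spec(noise_pa = 0, latency_jitter_ms = 0, latency_ms = 4.7,
                  seed = 7)
  men <- measure_evoked(generate_psc_sweeps(psn, 3))
  t10 <- oracle_doe_frac_time(0.1, psn$rise_tau_ms, psn$decay_tau_ms)
  expect_lt(abs(men$mean_latency_ms - (4.7 + t10)), 0.21)
  expect_lt(abs(men$mean_amp_pa - -50), 0.05)
  # spontaneous Poisson rate recovery
  sp <- generate_spontaneous_psc(
    psc_spec(peak_pa = -20, noise_pa = 2, event_rate_hz = 8, seed = 8), 60)
  ev <- detect_spontaneous(sp)
  expect_lt(abs(ev$frequency_hz - 8), 1)
  expect_lt(abs(mean(ev$amplitudes_pa) - -20), 1)
})
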