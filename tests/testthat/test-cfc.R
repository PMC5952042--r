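test_that("modulation index: bounds, oracle, invariances", {
  set.seed(10)
  ph <- runif(20000, -179.999, 180)
  # uniform amplitude -> MI exactly 0
  expect_identical(modulation_index(phase_amp_pair(ph, rep(3, 20000), 500))$mi,
                   0)
  # all mass in one bin -> MI exactly 1
  amp1 <- as.numeric(ph > 0 & ph <= 20)
  expect_equal(modulation_index(phase_amp_pair(ph, amp1, 500))$mi, 1,
               tolerance = 1e-14)
  # brute-force oracle equivalence on structured amplitude
  amp <- exp(1.3 * cos(ph * pi / 180 - 0.4)) + runif(20000)
  pair <- phase_amp_pair(ph, amp, 500)
  res <- modulation_index(pair)
  expect_equal(res$mi, oracle_mi(ph, amp), tolerance = 1e-12)
  expect_equal(sum(res$binned_mean_amp), 1, tolerance = 1e-12)
  # amplitude scaling invariance
  expect_equal(modulation_index(phase_amp_pair(ph, amp * 10, 500))$mi, res$mi,
               tolerance = 1e-12)
  # constant phase offset invariance
  ph2 <- ((ph + 40 + 180) %% 360) - 180
  ph2[ph2 <= -180] <- 180
  expect_equal(modulation_index(phase_amp_pair(ph2, amp, 500))$mi, res$mi,
               tolerance = 0.02 * res$mi + 1e-4)
  expect_error(modulation_index(phase_amp_pair(ph, rep(0, 20000), 500)),
               "all-zero")
  expect_error(phase_amp_pair(ph[1:10], amp, 500), "equal length")
  expect_error(phase_amp_pair(c(0, 200), c(1, 1), 500), "-180")
})

test_that("theta reference applies the +/-1 Hz rule and trough convention", {
  tr <- generate_coupled_lfp(
    lfp_spec(theta_freq_hz = 6, phase_diffusion = 0.3, amp_cv = 0.1,
             noise_amp = 0.2, fs_hz = 500, duration_s = 30, seed = 2))
  ref <- theta_reference(tr)
  expect_equal(ref$f_theta_hz, 6, tolerance = 0.2)
  expect_equal(ref$band$lo_hz, ref$f_theta_hz - 1)
  expect_equal(ref$band$hi_hz, ref$f_theta_hz + 1)
  # trough samples of the filtered signal map to +/-180 degrees
  filt <- bandpass(tr, ref$band)
  mid <- 3000:12000
  i_trough <- mid[which.min(filt$samples[mid])]
  expect_gt(abs(ref$phase_deg[i_trough]), 177)
  # nonstationary (chirp) input raises a warning
  fs <- 500; t <- seq_len(fs * 30) / fs
  chirp <- trace(cos(2 * pi * (3 * t + (4 / 60) * t^2)), fs_hz = fs)
  expect_warning(theta_reference(chirp), "nonstationary|edge")
})

test_that("surrogate test is seeded, calibrated and detects coupling", {
  tr <- generate_coupled_lfp(coupled_spec(4, seed = 21))
  ref <- suppressWarnings(theta_reference(tr))
  keep <- oscillopipe:::edge_keep_idx(length(tr$samples), tr$fs_hz)
  amp <- analytic_amplitude(bandpass(tr, band_spec(32.5, 37.5)))[keep]
  pair <- phase_amp_pair(ref$phase_deg[keep], amp, tr$fs_hz)
  a <- surrogate_test(pair, 100, seed = 5, theta_freq_hz = ref$f_theta_hz)
  b <- surrogate_test(pair, 100, seed = 5, theta_freq_hz = ref$f_theta_hz)
  expect_identical(a, b)
  expect_true(a$significant)
  # uncoupled recording: not significant (single-seed check; rate in
  # test-acceptance)
  tr0 <- generate_coupled_lfp(coupled_spec(0, seed = 22))
  ref0 <- suppressWarnings(theta_reference(tr0))
  amp0 <- analytic_amplitude(bandpass(tr0, band_spec(32.5, 37.5)))[keep]
  pair0 <- phase_amp_pair(ref0$phase_deg[keep], amp0, tr0$fs_hz)
  s0 <- surrogate_test(pair0, 100, seed = 5, theta_freq_hz = ref0$f_theta_hz)
  expect_false(s0$significant)
  expect_error(surrogate_test(pair, 10), "50")
})

test_that("comodulogram localises coupling and is scale invariant", {
  sp <- coupled_spec(2, seed = 31)
  tr <- generate_coupled_lfp(sp)
  com <- suppressWarnings(comodulogram(tr, amp_lo = 5, amp_hi = 100,
                                       n_surrogates = 0))
  pk_f <- com$amp_freq_centers_hz[which.max(com$mi_values)]
  expect_gte(pk_f, 30); expect_lte(pk_f, 40)
  tr10 <- tr; tr10$samples <- tr10$samples * 10
  com10 <- suppressWarnings(comodulogram(tr10, amp_lo = 5, amp_hi = 100,
                                         n_surrogates = 0))
  expect_equal(com10$mi_values, com$mi_values, tolerance = 1e-8)
  expect_error(comodulogram(tr, amp_hi = 400), "too low")
})

test_that("band_peak takes the in-band maximum with low-frequency ties", {
  com <- structure(list(amp_freq_centers_hz = c(27.5, 32.5, 37.5, 42.5),
                        mi_values = c(0.1, 0.4, 0.2, 0.1)),
                   class = "comodulogram")
  bp <- band_peak(com, band_spec(25, 45))
  expect_equal(bp$peak_freq_hz, 32.5)
  expect_equal(bp$peak_mi, 0.4)
  flat <- com; flat$mi_values <- rep(0.2, 4)
  expect_equal(band_peak(flat, band_spec(25, 45))$peak_freq_hz, 27.5)
  expect_error(band_peak(com, band_spec(100, 200)), "overlap")
  # generator ordering: stronger SG coupling than FG coupling
  sp <- lfp_spec(theta_freq_hz = 4.5, phase_diffusion = 2, amp_cv = 0.3,
                 gamma_components = list(
                   gamma_component(35, 10, 0.5, coupling_kappa = 3),
                   gamma_component(120, 10, 0.5, coupling_kappa = 0.5)),
                 noise_amp = 1, fs_hz = 500, duration_s = 30, seed = 8)
  tr <- generate_coupled_lfp(sp)
  com2 <- suppressWarnings(comodulogram(tr, amp_lo = 25, amp_hi = 130,
                                        n_surrogates = 0))
  expect_gt(band_peak(com2, band_spec(25, 45))$peak_mi,
            band_peak(com2, band_spec(110, 130))$peak_mi)
})

test_that("phase-amplitude profile tiles correctly", {
  set.seed(12)
  ph <- runif(30000, -179.999, 180)
  amp <- exp(2 * cos(ph * pi / 180))  # preferred phase 0
  pair <- phase_amp_pair(ph, amp, 500)
  prof <- phase_amplitude_profile(pair, n_bins = 18, cycles = 2)
  expect_length(prof$profile, 36)
  expect_equal(sum(prof$profile), 2, tolerance = 1e-12)
  pk_bin <- which.max(prof$profile[1:18])
  expect_true(abs(prof$phase_deg[pk_bin]) <= 20)
  unif <- phase_amplitude_profile(phase_amp_pair(ph, rep(1, 30000), 500))
  expect_true(all(abs(unif$profile - 1 / 18) < 1e-12))
})
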