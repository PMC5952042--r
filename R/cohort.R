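# End-to-end cohort driver: simulate two groups of synthetic animals, run the
# spectral / rhythmicity / coupling pipeline on each recording, and compare
# the eight figure-level metrics between groups.

#' Analyse one LFP recording into the eight cohort metrics
#'
#' Computes oscillation strength, per-cycle waveform peak SD, dominant theta
#' frequency, integrated theta-band power (5 s bins), slow- and fast-gamma
#' band-peak MI, and slow- and fast-gamma band power.
#'
#' @param trace an LFP [trace()].
#' @param theta_band theta search band.
#' @param sg_band,fg_band slow/fast gamma bands.
#' @param mi_step amplitude band width (Hz) for the comodulogram.
#' @return Named list of the eight metrics.
#' @export
analyze_lfp_recording <- function(trace, theta_band = band_spec(3, 8),
                                  sg_band = band_spec(25, 45),
                                  fg_band = band_spec(150, 250),
                                  mi_step = 5) {
  rhy <- rhythmicity(trace, theta_band)
  wav <- cycle_average(trace, rhy$theta_freq_hz, theta_band)
  th_pow <- band_power_bins(trace, theta_band)$mean_power
  sg_pow <- band_power_bins(trace, sg_band)$mean_power
  fg_pow <- band_power_bins(trace, fg_band)$mean_power
  com_sg <- suppressWarnings(
    comodulogram(trace, amp_lo = sg_band$lo_hz, amp_hi = sg_band$hi_hz,
                 step = mi_step, theta_search = theta_band, n_surrogates = 0))
  com_fg <- suppressWarnings(
    comodulogram(trace, amp_lo = fg_band$lo_hz, amp_hi = fg_band$hi_hz,
                 step = mi_step, theta_search = theta_band, n_surrogates = 0))
  list(strength_percent = rhy$strength_percent,
       peak_sd = wav$peak_sd,
       theta_freq_hz = rhy$theta_freq_hz,
       theta_power = th_pow,
       sg_peak_mi = band_peak(com_sg, sg_band)$peak_mi,
       fg_peak_mi = band_peak(com_fg, fg_band)$peak_mi,
       sg_power = sg_pow,
       fg_power = fg_pow)
}

#' Cohort configuration
#'
#' Describes a two-group synthetic experiment. Each group is given the
#' [lfp_spec()] parameters of its generative model; per-animal heterogeneity
#' (a lognormal gain on all amplitudes, emulating electrode/preparation
#' variability, and Gaussian jitter of the theta frequency) is drawn from the
#' same law in both groups.
#'
#' @param control,mutant named lists of [lfp_spec()] arguments (without
#'   `seed`, `fs_hz`, `duration_s`, which are set cohort-wide).
#' @param n_per_group animals per group.
#' @param fs_hz,duration_s recording parameters for every animal.
#' @param gain_cv between-animal coefficient of variation of the overall
#'   amplitude gain (lognormal).
#' @param freq_sd_hz between-animal SD of theta frequency (Hz).
#' @param test `"t"` (Student's, default) or `"mann_whitney"`.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(control, mutant, n_per_group = 10, fs_hz = 1000,
                          duration_s = 100, gain_cv = 1, freq_sd_hz = 0.3,
                          test = c("t", "mann_whitney")) {
  test <- match.arg(test)
  structure(list(control = control, mutant = mutant,
                 n_per_group = n_per_group, fs_hz = fs_hz,
                 duration_s = duration_s, gain_cv = gain_cv,
                 freq_sd_hz = freq_sd_hz, test = test),
            class = "cohort_config")
}

#' Default cohort configuration
#'
#' The "stated world" used by the end-to-end tests: the control group has
#' moderately rhythmic theta (6 Hz) with slow- and fast-gamma coupling; the
#' mutant group has raised phase diffusion (less rhythmic theta) and
#' abolished coupling, with matched theta/gamma amplitudes — the qualitative
#' pattern of the early network phenotype this pipeline characterises.
#'
#' @param kappa_sg,kappa_fg control-group coupling strengths.
#' @param ... passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function(kappa_sg = 2.5, kappa_fg = 2.5, ...) {
  base <- list(theta_freq_hz = 4.5, theta_amp = 3, amp_cv = 0.3,
               noise_exponent = 1, noise_amp = 1)
  gammas <- function(ks, kf) list(
    gamma_component(35, 10, 0.55, coupling_kappa = ks,
                    preferred_phase_deg = 0),
    gamma_component(200, 10, 0.3, coupling_kappa = kf,
                    preferred_phase_deg = 0))
  control <- c(base, list(phase_diffusion = 3.5,
                          gamma_components = gammas(kappa_sg, kappa_fg)))
  mutant <- c(base, list(phase_diffusion = 4.5,
                         gamma_components = gammas(0, 0)))
  cohort_config(control, mutant, ...)
}

animal_spec <- function(group_params, fs_hz, duration_s, gain, dfreq, seed) {
  p <- group_params
  p$theta_freq_hz <- max(3.5, min(7.5, p$theta_freq_hz + dfreq))
  p$theta_amp <- p$theta_amp * gain
  p$noise_amp <- p$noise_amp * gain
  p$gamma_components <- lapply(p$gamma_components, function(g) {
    g$base_amp <- g$base_amp * gain
    g
  })
  do.call(lfp_spec, c(p, list(fs_hz = fs_hz, duration_s = duration_s,
                              seed = seed)))
}

#' Run a two-group synthetic cohort
#'
#' Simulates `n_per_group` animals per group from the config, analyses every
#' recording with [analyze_lfp_recording()], and compares each of the eight
#' metrics between groups (two-sided, alpha = 0.05, no multiple-testing
#' correction across metrics — the conventional reporting). Fully
#' reproducible from `config` + `master_seed`.
#'
#' @param config a [cohort_config()].
#' @param master_seed integer seed for the whole cohort.
#' @return A `cohort_report`: list with `metrics` (one row per animal),
#'   `comparisons` (named list of `group_comparison`s) and `provenance`.
#' @export
run_cohort <- function(config, master_seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_per_group
  sdlog <- sqrt(log(1 + config$gain_cv^2))
  draws <- with_seed(master_seed, {
    list(gain = exp(stats::rnorm(2 * n, -sdlog^2 / 2, sdlog)),
         dfreq = stats::rnorm(2 * n, 0, config$freq_sd_hz),
         seeds = sample.int(.Machine$integer.max, 2 * n))
  })
  groups <- rep(c("control", "mutant"), each = n)
  rows <- lapply(seq_len(2 * n), function(i) {
    params <- config[[groups[i]]]
    spec <- animal_spec(params, config$fs_hz, config$duration_s,
                        draws$gain[i], draws$dfreq[i], draws$seeds[i])
    tr <- generate_coupled_lfp(spec)
    met <- analyze_lfp_recording(tr)
    c(list(group = groups[i], animal = i, seed = draws$seeds[i]), met)
  })
  metrics <- do.call(rbind, lapply(rows, as.data.frame))
  metric_names <- c("strength_percent", "peak_sd", "theta_freq_hz",
                    "theta_power", "sg_peak_mi", "fg_peak_mi", "sg_power",
                    "fg_power")
  cmp_fun <- if (config$test == "t") two_tailed_t else mann_whitney
  comparisons <- lapply(metric_names, function(m) {
    cmp_fun(metrics[[m]][metrics$group == "control"],
            metrics[[m]][metrics$group == "mutant"], metric_name = m)
  })
  names(comparisons) <- metric_names
  structure(
    list(metrics = metrics, comparisons = comparisons,
         provenance = list(config = unclass(config),
                           master_seed = master_seed,
                           package_version =
                             as.character(utils::packageVersion("oscillopipe")))),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d animals/group, test = %s\n",
              x$provenance$config$n_per_group, x$provenance$config$test))
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}

#' Write the per-animal metric table to CSV
#'
#' Deterministic byte-for-byte output for a given report (used to verify that
#' a cohort regenerates identically from config + master seed).
#'
#' @param report a `cohort_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(report, path) {
  m <- report$metrics
  num <- vapply(m, is.numeric, logical(1))
  m[num] <- lapply(m[num], function(col) format(col, digits = 17, trim = TRUE))
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
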