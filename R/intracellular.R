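# Patch-clamp sweep analysis: spike detection and shape features, passive
# membrane properties, f-I curves, evoked PSC metrics with failure
# classification, stimulus-duration I/O curves, and spontaneous event
# detection.

#' Detect action potentials in a current-step sweep
#'
#' A spike is an upward dV/dt crossing of `dvdt_thresh_mv_per_ms` followed by
#' a membrane-potential peak above 0 mV within 5 ms; a 1 ms refractory period
#' suppresses double counting. Returned indices mark the threshold crossing.
#'
#' @param sweep a `step_sweep` (see [generate_step_sweeps()]) or a
#'   [trace()] of membrane potential in mV.
#' @param dvdt_thresh_mv_per_ms spike onset criterion (standard 20 mV/ms for
#'   fast-spiking cells).
#' @return Integer vector of onset sample indices (possibly empty).
#' @export
detect_spikes <- function(sweep, dvdt_thresh_mv_per_ms = 20) {
  tr <- if (inherits(sweep, "step_sweep")) sweep$vm else sweep
  stopifnot(inherits(tr, "trace"))
  x <- tr$samples
  fs <- tr$fs_hz
  dvdt <- diff(x) * fs / 1000  # mV/ms
  above <- dvdt >= dvdt_thresh_mv_per_ms
  onsets <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(onsets)) return(integer(0))
  refr <- round(0.001 * fs)
  look <- round(0.005 * fs)
  out <- integer(0)
  last <- -Inf
  for (i in onsets) {
    if (i - last < refr) next
    hi <- min(length(x), i + look)
    if (max(x[i:hi]) > 0) {
      out <- c(out, i)
      last <- i
    }
  }
  out
}

# linearly interpolated crossing time (in samples, fractional) of level `lev`
# between samples i and i+1 spanning it
interp_cross <- function(x, i, lev) {
  i + (lev - x[i]) / (x[i + 1] - x[i])
}

#' Spike shape features
#'
#' For each detected spike: threshold voltage (Vm at the dV/dt criterion
#' crossing), amplitude (peak minus threshold), half-width (duration at half
#' amplitude above threshold, linearly interpolated) and AHP amplitude
#' (minimum within 20 ms after the peak, minus threshold; negative).
#' Spikes truncated by the trace end are excluded. Values are averaged over
#' spikes.
#'
#' @param sweep a `step_sweep` or mV [trace()].
#' @param spike_idx onset indices from [detect_spikes()]; detected when NULL.
#' @return List with `threshold_mv`, `amplitude_mv`, `halfwidth_ms`,
#'   `ahp_mv`, `n_spikes`.
#' @export
spike_shape_features <- function(sweep, spike_idx = NULL) {
  tr <- if (inherits(sweep, "step_sweep")) sweep$vm else sweep
  if (is.null(spike_idx)) spike_idx <- detect_spikes(sweep)
  if (!length(spike_idx)) stop("no spikes to measure")
  x <- tr$samples
  fs <- tr$fs_hz
  look <- round(0.003 * fs)       # peak search window
  ahp_win <- round(0.020 * fs)    # AHP search window after the peak
  feats <- lapply(spike_idx, function(i) {
    if (i + look + ahp_win > length(x)) return(NULL)  # truncated spike
    thr <- x[i]
    ipk <- i - 1 + which.max(x[i:(i + look)])
    peak <- x[ipk]
    amp <- peak - thr
    half <- thr + amp / 2
    # rising crossing (scan back from peak), falling crossing (forward)
    iu <- ipk
    while (iu > i && x[iu - 1] > half) iu <- iu - 1
    t_up <- interp_cross(x, iu - 1, half)
    id <- ipk
    while (id < length(x) - 1 && x[id + 1] > half) id <- id + 1
    t_dn <- interp_cross(x, id, half)
    ahp <- min(x[ipk:(ipk + ahp_win)]) - thr
    c(thr = thr, amp = amp, hw = (t_dn - t_up) * 1000 / fs, ahp = ahp)
  })
  feats <- do.call(rbind, feats[!vapply(feats, is.null, logical(1))])
  if (is.null(feats)) stop("all spikes truncated at the trace end")
  list(threshold_mv = mean(feats[, "thr"]),
       amplitude_mv = mean(feats[, "amp"]),
       halfwidth_ms = mean(feats[, "hw"]),
       ahp_mv = mean(feats[, "ahp"]),
       n_spikes = nrow(feats))
}

#' Passive membrane properties from hyperpolarising sweeps
#'
#' Resting potential is the pre-step mean; membrane resistance is
#' steady-state deflection / current from the smallest-magnitude
#' hyperpolarising step (steady state = last 100 ms of the step); sag is the
#' difference between the most negative deflection and the steady state.
#'
#' @param sweeps list of `step_sweep`s; at least one with negative current.
#' @return List with `resting_mv`, `membrane_resistance_mohm`, `sag_mv`.
#' @export
passive_properties <- function(sweeps) {
  neg <- Filter(function(s) s$current_pa < 0, sweeps)
  if (!length(neg)) stop("no hyperpolarising sweep supplied")
  for (s in neg) {
    if (length(detect_spikes(s)))
      stop("spiking detected during a hyperpolarising step")
  }
  s <- neg[[which.min(vapply(neg, function(s) abs(s$current_pa), numeric(1)))]]
  fs <- s$vm$fs_hz
  x <- s$vm$samples
  i_on <- round(s$step_window_s[1] * fs) + 1
  i_off <- round(s$step_window_s[2] * fs)
  resting <- mean(x[1:(i_on - 1)])
  ss_idx <- (i_off - round(0.1 * fs)):i_off
  v_ss <- mean(x[ss_idx])
  rm_mohm <- (v_ss - resting) / s$current_pa * 1000
  v_min <- min(x[i_on:i_off])
  list(resting_mv = resting, membrane_resistance_mohm = rm_mohm,
       sag_mv = abs(v_min - v_ss))
}

#' Firing-versus-current analysis
#'
#' Firing rate is spike count over the step duration. The threshold current
#' `t` is the smallest current evoking at least one spike; the f-I slope is
#' the least-squares slope of rate versus current over `[t, t + 200]` pA
#' (the conventional analysis window); the maximal firing rate is the largest
#' rate observed; adaptation is `100 * (1 - first ISI / last ISI)` at the
#' highest current with at least three spikes.
#'
#' @param sweeps list of `step_sweep`s.
#' @param slope_window_pa width of the current window above threshold used
#'   for the slope fit.
#' @return List with `fi_curve` (`currents_pa` relative to threshold,
#'   `rates_hz`, `threshold_current_pa`), `max_firing_hz`,
#'   `fi_slope_hz_per_pa`, `adaptation_percent`.
#' @export
fi_analysis <- function(sweeps, slope_window_pa = 200) {
  cur <- vapply(sweeps, function(s) s$current_pa, numeric(1))
  dur <- vapply(sweeps, function(s) diff(s$step_window_s), numeric(1))
  spk <- lapply(sweeps, detect_spikes)
  rates <- vapply(spk, length, integer(1)) / dur
  supra <- which(rates > 0 & cur > 0)
  if (length(supra) < 3) stop("need at least 3 suprathreshold sweeps")
  t_thr <- min(cur[supra])
  win <- which(cur >= t_thr & cur <= t_thr + slope_window_pa)
  fit <- stats::lm(rates[win] ~ cur[win])
  slope <- unname(stats::coef(fit)[2])
  # adaptation at the highest current with >= 3 spikes
  cand <- which(vapply(spk, length, integer(1)) >= 3)
  adapt <- NA_real_
  if (length(cand)) {
    j <- cand[which.max(cur[cand])]
    isi <- diff(spk[[j]])
    adapt <- 100 * (1 - isi[1] / isi[length(isi)])
  }
  ord <- order(cur[supra])
  list(fi_curve = list(currents_pa = cur[supra][ord] - t_thr,
                       rates_hz = rates[supra][ord],
                       threshold_current_pa = t_thr),
       max_firing_hz = max(rates), fi_slope_hz_per_pa = slope,
       adaptation_percent = adapt)
}

# centred boxcar smoother (identity when w <= 1); used to make extremum
# detection robust to baseline noise without biasing noiseless templates
boxcar <- function(x, w) {
  if (w <= 1) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  y[is.na(y)] <- x[is.na(y)]
  y
}

#' Full membrane / firing property table for one cell
#'
#' Convenience wrapper combining [passive_properties()], [fi_analysis()] and
#' [spike_shape_features()] (shape measured on the lowest suprathreshold
#' sweep, where spikes are well separated).
#'
#' @param sweeps list of `step_sweep`s covering hyperpolarising and
#'   depolarising currents.
#' @return Named list: `resting_mv`, `membrane_resistance_mohm`, `sag_mv`,
#'   `spike_amplitude_mv`, `spike_halfwidth_ms`, `ahp_mv`,
#'   `ap_threshold_mv`, `max_firing_hz`, `adaptation_percent`,
#'   `fi_slope_hz_per_pa`.
#' @export
patch_features <- function(sweeps) {
  pp <- passive_properties(sweeps)
  fi <- fi_analysis(sweeps)
  cur <- vapply(sweeps, function(s) s$current_pa, numeric(1))
  low <- which(cur == fi$fi_curve$threshold_current_pa)[1]
  sf <- spike_shape_features(sweeps[[low]])
  list(resting_mv = pp$resting_mv,
       membrane_resistance_mohm = pp$membrane_resistance_mohm,
       sag_mv = pp$sag_mv,
       spike_amplitude_mv = sf$amplitude_mv,
       spike_halfwidth_ms = sf$halfwidth_ms,
       ahp_mv = sf$ahp_mv,
       ap_threshold_mv = sf$threshold_mv,
       max_firing_hz = fi$max_firing_hz,
       adaptation_percent = fi$adaptation_percent,
       fi_slope_hz_per_pa = fi$fi_slope_hz_per_pa)
}

measure_one_evoked <- function(tr, stim_onset_ms, window_ms, direction) {
  x <- tr$samples
  fs <- tr$fs_hz
  i_stim <- round(stim_onset_ms / 1000 * fs) + 1
  if (i_stim < round(0.05 * fs))
    stop("need at least 50 ms of baseline before the stimulus")
  base_idx <- 1:(i_stim - 1)
  base <- mean(x[base_idx])
  noise_sd <- stats::mad(x[base_idx])
  i_hi <- min(length(x), i_stim + round(window_ms / 1000 * fs))
  seg <- (x - base)[i_stim:i_hi]
  if (direction == "negative") seg <- -seg
  # with a noisy baseline, detect on a 0.5 ms boxcar-smoothed copy: the raw
  # extremum of pure noise beats 3 SD far too often over a 20 ms window
  if (noise_sd > 0) seg <- boxcar(seg, max(1L, round(0.0005 * fs)))
  ipk <- which.max(seg)
  peak <- seg[ipk]
  if (peak <= 3 * noise_sd) {
    return(list(peak_pa = 0, latency_ms = NA_real_, rise_10_90_ms = NA_real_,
                halfwidth_ms = NA_real_, is_failure = TRUE))
  }
  lev_cross_back <- function(lev, from) {
    i <- from
    while (i > 1 && seg[i - 1] > lev) i <- i - 1
    if (i == 1) 1 else interp_cross(seg, i - 1, lev)
  }
  t10 <- lev_cross_back(0.1 * peak, ipk)
  t90 <- lev_cross_back(0.9 * peak, ipk)
  i <- ipk
  while (i < length(seg) && seg[i + 1] > 0.5 * peak) i <- i + 1
  t_dn <- if (i < length(seg)) interp_cross(seg, i, 0.5 * peak) else i
  t_up <- lev_cross_back(0.5 * peak, ipk)
  sgn <- if (direction == "negative") -1 else 1
  list(peak_pa = sgn * peak, latency_ms = (t10 - 1) * 1000 / fs,
       rise_10_90_ms = (t90 - t10) * 1000 / fs,
       halfwidth_ms = (t_dn - t_up) * 1000 / fs, is_failure = FALSE)
}

#' Measure evoked post-synaptic responses
#'
#' Per sweep: baseline mean and noise SD (median absolute deviation) from the
#' pre-stimulus window; a sweep is a failure when the baseline-subtracted
#' extremum within `window_ms` after the stimulus does not exceed 3 noise
#' SDs. For successes, amplitude is the baseline-subtracted extremum, latency
#' runs from stimulus onset to the 10%-of-peak crossing, rise time is 10-90%
#' and half-width is measured at 50% of peak (all linearly interpolated).
#' The amplitude coefficient of variation is computed over successes.
#'
#' @param sweeps list of [trace()]s (`kind = "im"`).
#' @param stim_onset_ms stimulus onset within each sweep (ms); taken from the
#'   sweep attribute when NULL.
#' @param window_ms post-stimulus detection window (ms).
#' @param direction `"negative"` (inward), `"positive"`, or `"auto"`.
#' @return List with `responses` (one row per sweep: `peak_pa`, `latency_ms`,
#'   `rise_10_90_ms`, `halfwidth_ms`, `is_failure`) and summary fields
#'   `mean_amp_pa`, `cv`, `mean_latency_ms`, `mean_rise_ms`,
#'   `mean_halfwidth_ms`, `failure_rate`.
#' @export
measure_evoked <- function(sweeps, stim_onset_ms = NULL, window_ms = 20,
                           direction = c("auto", "negative", "positive")) {
  direction <- match.arg(direction)
  if (is.null(stim_onset_ms)) stim_onset_ms <- attr(sweeps[[1]], "stim_ms")
  if (direction == "auto") {
    pool <- rowMeans(vapply(sweeps, function(s) s$samples,
                            numeric(length(sweeps[[1]]$samples))))
    direction <- if (abs(min(pool)) >= abs(max(pool))) "negative" else
      "positive"
  }
  rows <- lapply(sweeps, measure_one_evoked, stim_onset_ms = stim_onset_ms,
                 window_ms = window_ms, direction = direction)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  ok <- !df$is_failure
  amps <- df$peak_pa[ok]
  list(responses = df,
       mean_amp_pa = if (any(ok)) mean(amps) else NA_real_,
       cv = if (sum(ok) > 1) stats::sd(amps) / abs(mean(amps)) else NA_real_,
       mean_latency_ms = mean(df$latency_ms[ok]),
       mean_rise_ms = mean(df$rise_10_90_ms[ok]),
       mean_halfwidth_ms = mean(df$halfwidth_ms[ok]),
       failure_rate = mean(df$is_failure))
}

#' Normalised input/output curve over stimulus durations
#'
#' Mean evoked amplitude per stimulus duration, normalised to the cell's
#' maximum mean response (the normalised maximum is exactly 1). Durations at
#' which every sweep failed are flagged missing.
#'
#' @param sweeps_by_duration named list (names = stimulus durations, us) of
#'   sweep lists, e.g. from [generate_io_sweeps()].
#' @inheritParams measure_evoked
#' @return List with `stimulus_durations_us`, `mean_amp_pa`,
#'   `normalized_amplitudes`, `missing`.
#' @export
io_curve <- function(sweeps_by_duration, stim_onset_ms = NULL,
                     window_ms = 20,
                     direction = c("auto", "negative", "positive")) {
  direction <- match.arg(direction)
  if (length(sweeps_by_duration) < 3) stop("need at least 3 durations")
  dur <- as.numeric(names(sweeps_by_duration))
  means <- vapply(sweeps_by_duration, function(sw) {
    m <- measure_evoked(sw, stim_onset_ms = stim_onset_ms,
                        window_ms = window_ms, direction = direction)
    m$mean_amp_pa
  }, numeric(1))
  missing <- !is.finite(means)
  mx <- max(abs(means[!missing]))
  list(stimulus_durations_us = dur, mean_amp_pa = unname(means),
       normalized_amplitudes = unname(abs(means) / mx), missing = unname(missing))
}

#' Detect spontaneous synaptic events
#'
#' Template-free threshold detection: noise SD is estimated by the median
#' absolute deviation of the whole (median-centred) trace; events are
#' deflections exceeding `threshold_sd` noise SDs from baseline, separated by
#' at least `min_iei_ms`. Per-event amplitude, 10-90% rise and half-width are
#' measured around each event peak as for evoked responses.
#'
#' @param trace a current [trace()] (`kind = "im"`), >= 30 s recommended.
#' @param direction `"negative"` (inward, default) or `"positive"`.
#' @param threshold_sd detection threshold in noise SDs.
#' @param min_iei_ms minimum inter-event interval (ms).
#' @return A `spontaneous_events` list: `event_times_s`, `amplitudes_pa`,
#'   `frequency_hz`, `rise_ms`, `halfwidth_ms`, `n_events`.
#' @export
detect_spontaneous <- function(trace, direction = c("negative", "positive"),
                               threshold_sd = 3, min_iei_ms = 5) {
  direction <- match.arg(direction)
  stopifnot(inherits(trace, "trace"))
  x <- trace$samples
  fs <- trace$fs_hz
  base <- stats::median(x)
  noise_sd <- stats::mad(x)
  seg <- if (direction == "negative") base - x else x - base
  # detect on a smoothed copy (see measure_one_evoked); the threshold stays
  # in raw-noise units
  if (noise_sd > 0) seg <- boxcar(seg, max(1L, round(0.0005 * fs)))
  thr <- threshold_sd * noise_sd
  pk <- find_peaks(seg, min_sep = round(min_iei_ms / 1000 * fs),
                   min_height = thr)
  if (!length(pk)) {
    return(structure(list(event_times_s = numeric(0),
                          amplitudes_pa = numeric(0), frequency_hz = 0,
                          rise_ms = numeric(0), halfwidth_ms = numeric(0),
                          n_events = 0L),
                     class = "spontaneous_events"))
  }
  sgn <- if (direction == "negative") -1 else 1
  rise <- hw <- numeric(length(pk))
  for (k in seq_along(pk)) {
    ipk <- pk[k]
    peak <- seg[ipk]
    back_cross <- function(lev) {
      i <- ipk
      lo <- max(1, ipk - round(0.02 * fs))
      while (i > lo && seg[i - 1] > lev) i <- i - 1
      if (i == lo) i else interp_cross(seg, i - 1, lev)
    }
    t10 <- back_cross(0.1 * peak); t90 <- back_cross(0.9 * peak)
    t_up <- back_cross(0.5 * peak)
    i <- ipk
    hi <- min(length(seg) - 1, ipk + round(0.05 * fs))
    while (i < hi && seg[i + 1] > 0.5 * peak) i <- i + 1
    t_dn <- interp_cross(seg, i, 0.5 * peak)
    rise[k] <- (t90 - t10) * 1000 / fs
    hw[k] <- (t_dn - t_up) * 1000 / fs
  }
  structure(
    list(event_times_s = trace$t0_s + (pk - 1) / fs,
         amplitudes_pa = sgn * seg[pk], frequency_hz = length(pk) /
           trace_duration(trace),
         rise_ms = rise, halfwidth_ms = hw, n_events = length(pk)),
    class = "spontaneous_events"
  )
}

#' @export
print.spontaneous_events <- function(x, ...) {
  cat(sprintf("<spontaneous_events> %d events, %.2f Hz, mean amp %.1f pA\n",
              x$n_events, x$frequency_hz,
              if (x$n_events) mean(x$amplitudes_pa) else NA))
  invisible(x)
}

#' Write a set of current-step sweeps to a directory
#'
#' One CSV per sweep plus a `manifest.json` recording the sampling rate,
#' per-sweep injected current and the step window. Round-trips through
#' [read_step_sweeps()].
#'
#' @param sweeps list of `step_sweep`s.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_step_sweeps <- function(sweeps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(sweeps), function(i) {
    fn <- sprintf("sweep_%03d.csv", i)
    write_trace(sweeps[[i]]$vm, file.path(dir, fn))
    list(file = fn, current_pa = sweeps[[i]]$current_pa)
  })
  manifest <- list(step_window_s = sweeps[[1]]$step_window_s,
                   sweeps = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a set of current-step sweeps from a directory
#'
#' @param dir directory written by [write_step_sweeps()] (per-sweep CSV
#'   traces and a `manifest.json` protocol file).
#' @return List of `step_sweep`s.
#' @export
read_step_sweeps <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  win <- as.numeric(manifest$step_window_s)
  lapply(seq_len(nrow(manifest$sweeps)), function(i) {
    structure(list(vm = read_trace(file.path(dir, manifest$sweeps$file[i])),
                   current_pa = as.numeric(manifest$sweeps$current_pa[i]),
                   step_window_s = win),
              class = "step_sweep")
  })
}
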