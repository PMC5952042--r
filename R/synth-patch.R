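# Synthetic patch-clamp data: current-step membrane-potential sweeps with a
# parameterised f-I relationship and stereotyped spike shape, plus evoked and
# spontaneous post-synaptic current sweeps with stochastic failures.

#' Synthetic neuron specification
#'
#' Parameters of the current-step generator. Defaults are typical of
#' fast-spiking parvalbumin interneurons (control group of the membrane /
#' firing property table this module emulates).
#'
#' @param resting_mv resting potential (mV).
#' @param input_resistance_mohm membrane resistance (MOhm).
#' @param rheobase_pa threshold current (pA).
#' @param fi_slope_hz_per_pa firing gain (Hz/pA).
#' @param adaptation_frac fractional ISI lengthening across the step in
#'   [0, 1): first ISI / last ISI = 1 - adaptation_frac.
#' @param spike_peak_mv,spike_threshold_mv,spike_halfwidth_ms,ahp_mv spike
#'   shape: peak and threshold voltages, half-width (at half spike amplitude
#'   above threshold) and AHP amplitude relative to threshold (negative).
#' @param sag_mv depolarising-sag amplitude on hyperpolarising steps (mV).
#' @param tau_m_ms membrane time constant (ms).
#' @param seed integer seed.
#' @return A `synthetic_neuron_spec` object.
#' @export
neuron_spec <- function(resting_mv = -62.3, input_resistance_mohm = 190,
                        rheobase_pa = 150, fi_slope_hz_per_pa = 0.56,
                        adaptation_frac = 0.14, spike_peak_mv = 44,
                        spike_threshold_mv = -39.2, spike_halfwidth_ms = 0.52,
                        ahp_mv = -17, sag_mv = 1.36, tau_m_ms = 10,
                        seed = 1) {
  if (!(spike_peak_mv > spike_threshold_mv && spike_threshold_mv > resting_mv))
    stop("need spike_peak_mv > spike_threshold_mv > resting_mv")
  if (fi_slope_hz_per_pa < 0) stop("fi_slope_hz_per_pa must be >= 0")
  if (adaptation_frac < 0 || adaptation_frac >= 1)
    stop("adaptation_frac must be in [0, 1)")
  structure(list(resting_mv = resting_mv,
                 input_resistance_mohm = input_resistance_mohm,
                 rheobase_pa = rheobase_pa,
                 fi_slope_hz_per_pa = fi_slope_hz_per_pa,
                 adaptation_frac = adaptation_frac,
                 spike_peak_mv = spike_peak_mv,
                 spike_threshold_mv = spike_threshold_mv,
                 spike_halfwidth_ms = spike_halfwidth_ms, ahp_mv = ahp_mv,
                 sag_mv = sag_mv, tau_m_ms = tau_m_ms, seed = seed),
            class = "synthetic_neuron_spec")
}

#' Synthetic post-synaptic current specification
#'
#' @param peak_pa event amplitude (pA; negative = inward).
#' @param rise_tau_ms,decay_tau_ms exponential time constants
#'   (`decay_tau_ms > rise_tau_ms > 0`).
#' @param latency_ms synaptic delay from stimulus onset (ms).
#' @param latency_jitter_ms SD of the latency (ms).
#' @param failure_prob probability that a stimulus evokes no response.
#' @param noise_pa baseline noise SD (pA).
#' @param event_rate_hz Poisson rate for spontaneous event trains.
#' @param seed integer seed.
#' @return A `synthetic_psc_spec` object.
#' @export
psc_spec <- function(peak_pa = -50, rise_tau_ms = 0.3, decay_tau_ms = 3,
                     latency_ms = 4.7, latency_jitter_ms = 0.2,
                     failure_prob = 0, noise_pa = 2, event_rate_hz = 8,
                     seed = 1) {
  if (!(decay_tau_ms > rise_tau_ms && rise_tau_ms > 0))
    stop("need decay_tau_ms > rise_tau_ms > 0")
  if (failure_prob < 0 || failure_prob > 1)
    stop("failure_prob must be in [0, 1]")
  structure(list(peak_pa = peak_pa, rise_tau_ms = rise_tau_ms,
                 decay_tau_ms = decay_tau_ms, latency_ms = latency_ms,
                 latency_jitter_ms = latency_jitter_ms,
                 failure_prob = failure_prob, noise_pa = noise_pa,
                 event_rate_hz = event_rate_hz, seed = seed),
            class = "synthetic_psc_spec")
}

# stereotyped spike shape appended into a Vm vector at sample i0 (threshold
# crossing on the grid). Piecewise linear rise/fall so that analytic shape
# features (threshold, amplitude, half-width, AHP) are exactly recoverable by
# interpolation-based measurement.
insert_spike <- function(vm, i0, spec, fs_hz, baseline_mv) {
  dt_ms <- 1000 / fs_hz
  # sub-threshold pre-ramp (15 mV/ms, below the 20 mV/ms detection
  # criterion) from the preceding membrane potential up to threshold, so the
  # dV/dt criterion first fires exactly at the threshold sample i0
  i <- i0 - 1
  while (i >= 1) {
    rv <- spec$spike_threshold_mv - 15 * dt_ms * (i0 - i)
    if (rv <= vm[i]) break  # ramp meets the existing trajectory from below
    vm[i] <- rv
    i <- i - 1
  }
  A <- spec$spike_peak_mv - spec$spike_threshold_mv
  D <- -spec$ahp_mv  # AHP depth below threshold (positive number)
  hw <- spec$spike_halfwidth_ms
  rise_ms <- max(2 * dt_ms, round(0.5 * hw / dt_ms) * dt_ms)
  # fall chosen so the half-amplitude width equals hw given the linear fall
  # from peak to threshold - D:
  #   hw = rise/2 + fall * (A/2) / (A + D)
  fall_ms <- max(2 * dt_ms, round((hw - rise_ms / 2) * (A + D) / (A / 2)
                                  / dt_ms) * dt_ms)
  nr <- round(rise_ms / dt_ms)
  nf <- round(fall_ms / dt_ms)
  up <- spec$spike_threshold_mv + A * (0:nr) / nr
  down <- spec$spike_peak_mv - (A + D) * (1:nf) / nf
  # AHP recovery, tau 3 ms; long enough that the tail rejoins the baseline
  # with a step far below the 20 mV/ms detection criterion
  ntail <- round(25 / dt_ms)
  tail_v <- (spec$spike_threshold_mv - D) +
    (baseline_mv - spec$spike_threshold_mv + D) *
      (1 - exp(-(1:ntail) * dt_ms / 3))
  shape <- c(up, down, tail_v)
  idx <- i0 + seq_along(shape) - 1
  ok <- idx <= length(vm)
  vm[idx[ok]] <- shape[ok]
  vm
}

#' Generate current-step membrane-potential sweeps
#'
#' One sweep per entry of `currents_pa`. For depolarising currents above
#' rheobase the spike count over the step is
#' `round(fi_slope_hz_per_pa * (I - rheobase_pa) * step_s)`, with ISIs ramped
#' linearly so that first ISI / last ISI = `1 - adaptation_frac`.
#' Hyperpolarising steps deflect by `I * Rm` (pA * MOhm / 1000 = mV) with a
#' depolarising sag of `sag_mv`.
#'
#' @param spec a [neuron_spec()].
#' @param currents_pa injected currents (pA), one sweep each.
#' @param step_ms step duration (ms), conventionally 600.
#' @param fs_hz sampling rate (patch standard 20000).
#' @param pre_ms,post_ms baseline before / after the step (ms).
#' @param noise_mv membrane noise SD (mV); keep small so spike-shape
#'   measurement stays exact.
#' @return List of `step_sweep` objects: each has `vm` (a [trace()], mV),
#'   `current_pa` and `step_window_s`.
#' @export
generate_step_sweeps <- function(spec, currents_pa, step_ms = 600,
                                 fs_hz = 20000, pre_ms = 100, post_ms = 100,
                                 noise_mv = 0.05) {
  stopifnot(inherits(spec, "synthetic_neuron_spec"))
  if (step_ms <= 0) stop("step duration must be > 0")
  dt_ms <- 1000 / fs_hz
  n <- round((pre_ms + step_ms + post_ms) / dt_ms)
  i_on <- round(pre_ms / dt_ms) + 1
  i_off <- round((pre_ms + step_ms) / dt_ms)
  step_s <- step_ms / 1000
  tau <- spec$tau_m_ms
  with_seed(spec$seed, {
    lapply(currents_pa, function(I) {
      vm <- rep(spec$resting_mv, n)
      t_in <- (0:(i_off - i_on)) * dt_ms
      dv_ss <- I * spec$input_resistance_mohm / 1000
      nspk <- if (I > spec$rheobase_pa) {
        round(spec$fi_slope_hz_per_pa * (I - spec$rheobase_pa) * step_s)
      } else 0L
      if (I >= 0 && nspk == 0) {
        plateau <- min(spec$resting_mv + dv_ss, spec$spike_threshold_mv - 1)
        vm[i_on:i_off] <- spec$resting_mv +
          (plateau - spec$resting_mv) * (1 - exp(-t_in / tau))
      } else if (I < 0) {
        sagg <- exp(-t_in / 100) - exp(-t_in / 25)
        sagg <- if (max(sagg) > 0) sagg / max(sagg) else sagg
        vm[i_on:i_off] <- spec$resting_mv +
          dv_ss * (1 - exp(-t_in / tau)) - spec$sag_mv * sagg
      } else {
        plateau <- spec$spike_threshold_mv - 3
        vm[i_on:i_off] <- spec$resting_mv +
          (plateau - spec$resting_mv) * (1 - exp(-t_in / tau))
        # spike times: linear ISI ramp with first/last = 1 - adaptation_frac
        if (nspk == 1) {
          st_ms <- pre_ms + step_ms / 2
        } else {
          nisi <- nspk - 1
          r <- 1 / (1 - spec$adaptation_frac)
          u <- if (nisi == 1) 1 else 1 + (0:(nisi - 1)) * (r - 1) / (nisi - 1)
          isis <- u * (0.95 * step_ms - 5) / sum(u)
          st_ms <- pre_ms + 5 + c(0, cumsum(isis))
        }
        for (s in st_ms) {
          i0 <- round(s / dt_ms) + 1
          vm <- insert_spike(vm, i0, spec, fs_hz, plateau)
        }
      }
      # relaxation back to rest after the step (no spike in tail region)
      t_out <- (1:(n - i_off)) * dt_ms
      vm[(i_off + 1):n] <- vm[i_off] +
        (spec$resting_mv - vm[i_off]) * (1 - exp(-t_out / tau))
      if (noise_mv > 0) vm <- vm + stats::rnorm(n, 0, noise_mv)
      structure(list(vm = trace(vm, fs_hz = fs_hz, units = "mV",
                                kind = "vm"),
                     current_pa = I,
                     step_window_s = c(pre_ms, pre_ms + step_ms) / 1000),
                class = "step_sweep")
    })
  })
}

# difference-of-exponentials kernel normalised to unit peak
psc_kernel <- function(t_ms, rise_tau, decay_tau) {
  tp <- rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
  nrm <- exp(-tp / decay_tau) - exp(-tp / rise_tau)
  out <- (exp(-t_ms / decay_tau) - exp(-t_ms / rise_tau)) / nrm
  out[t_ms < 0] <- 0
  out
}

#' Generate evoked post-synaptic current sweeps
#'
#' Each sweep holds baseline noise and, with probability
#' `1 - failure_prob`, a difference-of-exponentials synaptic event starting
#' `latency_ms` (plus Gaussian jitter) after the stimulus.
#'
#' @param spec a [psc_spec()].
#' @param n_sweeps number of sweeps.
#' @param sweep_ms sweep duration (ms).
#' @param stim_ms stimulus onset within the sweep (ms; `< sweep_ms`).
#' @param fs_hz sampling rate.
#' @param amp_scale multiplier on `peak_pa` (used by the I/O generator).
#' @return List of [trace()]s (`kind = "im"`, pA) with attribute
#'   `stim_ms`.
#' @export
generate_psc_sweeps <- function(spec, n_sweeps, sweep_ms = 100, stim_ms = 50,
                                fs_hz = 10000, amp_scale = 1) {
  stopifnot(inherits(spec, "synthetic_psc_spec"))
  if (stim_ms >= sweep_ms) stop("stim_ms must be before the end of the sweep")
  dt_ms <- 1000 / fs_hz
  n <- round(sweep_ms / dt_ms)
  tt <- (seq_len(n) - 1) * dt_ms
  with_seed(spec$seed, {
    sweeps <- lapply(seq_len(n_sweeps), function(k) {
      x <- if (spec$noise_pa > 0) stats::rnorm(n, 0, spec$noise_pa) else
        numeric(n)
      fail <- stats::runif(1) < spec$failure_prob
      if (!fail) {
        lat <- spec$latency_ms +
          if (spec$latency_jitter_ms > 0)
            stats::rnorm(1, 0, spec$latency_jitter_ms) else 0
        onset <- stim_ms + max(lat, 0)
        x <- x + amp_scale * spec$peak_pa *
          psc_kernel(tt - onset, spec$rise_tau_ms, spec$decay_tau_ms)
      }
      tr <- trace(x, fs_hz = fs_hz, units = "pA", kind = "im")
      attr(tr, "stim_ms") <- stim_ms
      tr
    })
    sweeps
  })
}

#' Generate a spontaneous post-synaptic current trace
#'
#' Inserts Poisson-timed events at `event_rate_hz` into baseline noise.
#'
#' @param spec a [psc_spec()].
#' @param duration_s trace duration (s).
#' @param fs_hz sampling rate.
#' @return A [trace()] (`kind = "im"`, pA) with attribute `event_times_s`.
#' @export
generate_spontaneous_psc <- function(spec, duration_s = 60, fs_hz = 10000) {
  stopifnot(inherits(spec, "synthetic_psc_spec"))
  n <- round(duration_s * fs_hz)
  dt_ms <- 1000 / fs_hz
  with_seed(spec$seed, {
    nev <- stats::rpois(1, spec$event_rate_hz * duration_s)
    times_s <- sort(stats::runif(nev, 0.05, duration_s - 0.05))
    # enforce the analyser's minimum separability (5 ms dead time)
    if (length(times_s) > 1)
      times_s <- times_s[c(TRUE, diff(times_s) > 0.006)]
    x <- if (spec$noise_pa > 0) stats::rnorm(n, 0, spec$noise_pa) else
      numeric(n)
    kern_t <- seq(0, 10 * spec$decay_tau_ms, by = dt_ms)
    kern <- spec$peak_pa * psc_kernel(kern_t, spec$rise_tau_ms,
                                      spec$decay_tau_ms)
    for (ts in times_s) {
      i0 <- round(ts * fs_hz) + 1
      idx <- i0 + seq_along(kern) - 1
      ok <- idx <= n
      x[idx[ok]] <- x[idx[ok]] + kern[ok]
    }
    tr <- trace(x, fs_hz = fs_hz, units = "pA", kind = "im")
    attr(tr, "event_times_s") <- times_s
    tr
  })
}

#' Generate an input/output stimulus-duration series
#'
#' Evoked sweeps grouped by stimulus duration; response amplitude ramps
#' linearly with duration and saturates (plateaus) at `sat_us`.
#'
#' @param spec a [psc_spec()].
#' @param durations_us stimulus durations (microseconds).
#' @param n_per_duration sweeps per duration.
#' @param sat_us saturation duration (conventional 400).
#' @inheritParams generate_psc_sweeps
#' @return Named list (one element per duration) of sweep lists.
#' @export
generate_io_sweeps <- function(spec, durations_us = seq(50, 900, by = 50),
                               n_per_duration = 10, sat_us = 400,
                               sweep_ms = 100, stim_ms = 50, fs_hz = 10000) {
  out <- lapply(seq_along(durations_us), function(i) {
    d <- durations_us[i]
    sp <- spec
    sp$seed <- spec$seed + i
    generate_psc_sweeps(sp, n_per_duration, sweep_ms = sweep_ms,
                        stim_ms = stim_ms, fs_hz = fs_hz,
                        amp_scale = min(d, sat_us) / sat_us)
  })
  names(out) <- as.character(durations_us)
  out
}
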