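# Synthetic LFP generation: a phase-diffusing theta carrier, gamma components
# whose amplitude is phase-locked to theta through a von Mises envelope, and
# spectrally shaped (1/f) background noise. The generator is the ground truth
# against which every field-analysis stage is tested.

#' Gamma component of a synthetic LFP
#'
#' @param center_freq_hz carrier frequency (Hz).
#' @param bandwidth_hz spectral full width (Hz) realised by phase diffusion of
#'   the carrier.
#' @param base_amp envelope amplitude scale (uV). The von Mises coupling
#'   envelope is normalised to unit root-mean-square over the theta cycle, so
#'   mean gamma power does not depend on the coupling strength.
#' @param coupling_kappa von Mises concentration of the theta-phase coupling
#'   (>= 0; 0 = exactly uncoupled).
#' @param preferred_phase_deg theta phase (degrees) at which the envelope
#'   peaks.
#' @return A list describing the component.
#' @export
gamma_component <- function(center_freq_hz, bandwidth_hz = 10, base_amp = 1,
                            coupling_kappa = 0, preferred_phase_deg = 0) {
  if (coupling_kappa < 0) stop("coupling_kappa must be >= 0")
  list(center_freq_hz = center_freq_hz, bandwidth_hz = bandwidth_hz,
       base_amp = base_amp, coupling_kappa = coupling_kappa,
       preferred_phase_deg = preferred_phase_deg)
}

#' Synthetic LFP specification
#'
#' Describes the statistical structure of a simulated field recording:
#' a theta oscillation (3-8 Hz regime) whose cycle-to-cycle regularity is
#' controlled by Wiener phase diffusion, gamma components amplitude-coupled to
#' the theta phase, and pink background noise. Identical spec + seed yields a
#' bit-identical trace.
#'
#' @param theta_freq_hz mean theta frequency (Hz).
#' @param theta_amp theta amplitude (uV).
#' @param phase_diffusion per-sample phase-noise SD scaled per sqrt(second)
#'   (rad/sqrt(s)); 0 gives a perfectly rhythmic carrier.
#' @param amp_cv coefficient of variation of the slow theta amplitude
#'   envelope (per-cycle peak amplitude CV).
#' @param gamma_components list of [gamma_component()]s.
#' @param noise_exponent spectral slope of the background noise (1 = pink).
#' @param noise_amp background noise SD (uV).
#' @param fs_hz sampling rate (Hz; acquisition standard 5000).
#' @param duration_s trace duration (s).
#' @param seed integer master seed; expanded into independent per-component
#'   substreams.
#' @return A `synthetic_lfp_spec` object.
#' @examples
#' spec <- lfp_spec(gamma_components = list(
#'   gamma_component(35, 10, 0.5, coupling_kappa = 2)
#' ), duration_s = 20, fs_hz = 1000)
#' tr <- generate_coupled_lfp(spec)
#' @export
lfp_spec <- function(theta_freq_hz = 6, theta_amp = 3, phase_diffusion = 2,
                     amp_cv = 0.3, gamma_components = list(),
                     noise_exponent = 1, noise_amp = 1, fs_hz = 5000,
                     duration_s = 100, seed = 1) {
  spec <- list(theta_freq_hz = theta_freq_hz, theta_amp = theta_amp,
               phase_diffusion = phase_diffusion, amp_cv = amp_cv,
               gamma_components = gamma_components,
               noise_exponent = noise_exponent, noise_amp = noise_amp,
               fs_hz = fs_hz, duration_s = duration_s, seed = seed)
  validate_lfp_spec(spec)
  structure(spec, class = "synthetic_lfp_spec")
}

validate_lfp_spec <- function(spec) {
  num_ok <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  with(spec, {
    if (!num_ok(theta_freq_hz) || theta_freq_hz <= 0)
      stop("theta_freq_hz must be a positive finite number")
    if (!num_ok(theta_amp) || theta_amp < 0) stop("theta_amp must be >= 0")
    if (!num_ok(phase_diffusion) || phase_diffusion < 0)
      stop("phase_diffusion must be >= 0")
    if (!num_ok(amp_cv) || amp_cv < 0) stop("amp_cv must be >= 0")
    if (!num_ok(noise_amp) || noise_amp < 0) stop("noise_amp must be >= 0")
    if (!num_ok(fs_hz) || fs_hz <= 0) stop("fs_hz must be positive")
    if (!num_ok(duration_s) || duration_s <= 0)
      stop("duration_s must be positive")
    for (g in gamma_components) {
      if (g$coupling_kappa < 0) stop("coupling_kappa must be >= 0")
      if (fs_hz <= 2 * g$center_freq_hz)
        stop("fs_hz must exceed twice the highest gamma center frequency")
    }
  })
  invisible(spec)
}

# Wiener phase track: d(phi) = 2 pi f dt + sigma sqrt(dt) dW
phase_track <- function(n, f_hz, sigma, dt) {
  incr <- 2 * pi * f_hz * dt + sigma * sqrt(dt) * stats::rnorm(n)
  cumsum(incr)
}

# unit-variance Ornstein-Uhlenbeck sequence (AR(1)); slow envelope modulator
ou_track <- function(n, tau_s, dt) {
  a <- exp(-dt / tau_s)
  innov <- stats::rnorm(n) * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  for (i in 2:n) x[i] <- a * x[i - 1] + innov[i]
  x
}

# Gaussian noise with power spectral density ~ 1/f^alpha, unit variance
shaped_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w)
  W <- stats::fft(w)
  # symmetric amplitude scale ~ f^(-alpha/2): bin k and n-k carry the same
  # frequency, DC removed
  m <- pmin(0:(n - 1), n - (0:(n - 1)))
  sc <- ifelse(m == 0, 0, m^(-alpha / 2))
  x <- Re(stats::fft(W * sc, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Generate a synthetic theta-gamma LFP trace
#'
#' The theta carrier is `theta_amp * env(t) * cos(phi(t))` with Wiener phase
#' diffusion and a slow (tau = 0.35 s) Ornstein-Uhlenbeck amplitude envelope
#' of CV `amp_cv`. Each gamma component contributes
#' `base_amp * exp(kappa * cos(phi - phi_pref)) / sqrt(I0(2 kappa)) *
#' cos(phi_g(t))`, so its mean power is independent of `kappa`; its carrier
#' phase diffuses to realise the requested bandwidth. Background noise has spectral
#' slope `noise_exponent` and SD `noise_amp`.
#'
#' @param spec a [lfp_spec()].
#' @return A [trace()] (`kind = "lfp"`, uV) of `fs_hz * duration_s` samples.
#' @export
generate_coupled_lfp <- function(spec) {
  stopifnot(inherits(spec, "synthetic_lfp_spec"))
  validate_lfp_spec(spec)
  n <- round(spec$fs_hz * spec$duration_s)
  dt <- 1 / spec$fs_hz
  ncomp <- length(spec$gamma_components)
  with_seed(spec$seed, {
    subseeds <- sample.int(.Machine$integer.max, 3 + ncomp)
    phi <- with_seed(subseeds[1],
                     phase_track(n, spec$theta_freq_hz, spec$phase_diffusion,
                                 dt))
    env <- if (spec$amp_cv > 0) {
      pmax(1 + spec$amp_cv * with_seed(subseeds[2], ou_track(n, 0.35, dt)),
           0.05)
    } else rep(1, n)
    x <- spec$theta_amp * env * cos(phi)
    for (i in seq_len(ncomp)) {
      g <- spec$gamma_components[[i]]
      sig_g <- sqrt(2 * pi * g$bandwidth_hz)
      phig <- with_seed(subseeds[3 + i],
                        phase_track(n, g$center_freq_hz, sig_g, dt))
      kap <- g$coupling_kappa
      # RMS normalisation (sqrt of the circular mean of the squared
      # envelope), so mean gamma *power* is independent of kappa
      envg <- if (kap > 0) {
        exp(kap * cos(phi - g$preferred_phase_deg * pi / 180)) /
          sqrt(besselI(2 * kap, 0))
      } else rep(1, n)
      x <- x + g$base_amp * envg * cos(phig)
    }
    if (spec$noise_amp > 0) {
      x <- x + spec$noise_amp *
        with_seed(subseeds[3], shaped_noise(n, spec$noise_exponent))
    }
    trace(x, fs_hz = spec$fs_hz, units = "uV", kind = "lfp")
  })
}

#' Generate a chirp-driven (ZAP) oscillatory response
#'
#' Simulates the network response to a stimulus whose frequency sweeps from
#' `f_start_hz` to `f_end_hz` over the spec's duration, either linearly or
#' exponentially. The response amplitude is shaped by a Gaussian resonance
#' profile centred at `resonance_center_hz`; gamma components from the spec
#' are coupled to the drive phase, optionally only while the drive frequency
#' lies inside `coupling_f_range`.
#'
#' @param spec a [lfp_spec()]; `theta_amp` sets the drive response amplitude,
#'   `gamma_components` the coupled fast oscillations, `noise_*` the noise.
#' @param f_start_hz,f_end_hz sweep frequency range; `0 <= f_start < f_end`
#'   and `f_end` below Nyquist.
#' @param sweep `"linear"` or `"exponential"` frequency ramp.
#' @param resonance_center_hz centre of the resonance profile (Hz).
#' @param resonance_gain peak fractional amplitude gain of the resonance
#'   (0 = flat).
#' @param resonance_width_hz Gaussian SD of the resonance profile (Hz).
#' @param coupling_f_range optional length-2 vector; gamma coupling is active
#'   only while the instantaneous drive frequency is inside it.
#' @return List with `trace` (a [trace()]) and `stim_log` (list with
#'   `freq_hz` per sample and `fs_hz`).
#' @export
generate_zap_response <- function(spec, f_start_hz = 0, f_end_hz = 12,
                                  sweep = c("linear", "exponential"),
                                  resonance_center_hz = 6,
                                  resonance_gain = 0,
                                  resonance_width_hz = 2,
                                  coupling_f_range = NULL) {
  stopifnot(inherits(spec, "synthetic_lfp_spec"))
  sweep <- match.arg(sweep)
  if (f_start_hz < 0 || f_end_hz <= f_start_hz ||
      f_end_hz > spec$fs_hz / 2)
    stop("need 0 <= f_start < f_end <= fs/2")
  n <- round(spec$fs_hz * spec$duration_s)
  dt <- 1 / spec$fs_hz
  tt <- (seq_len(n) - 1) * dt
  f_inst <- switch(sweep,
    linear = f_start_hz + (f_end_hz - f_start_hz) * tt / spec$duration_s,
    exponential = {
      f0 <- max(f_start_hz, 0.1)
      f0 * (f_end_hz / f0)^(tt / spec$duration_s)
    })
  ncomp <- length(spec$gamma_components)
  with_seed(spec$seed, {
    subseeds <- sample.int(.Machine$integer.max, 2 + ncomp)
    phi <- cumsum(2 * pi * f_inst * dt)
    gain <- 1 + resonance_gain *
      exp(-(f_inst - resonance_center_hz)^2 / (2 * resonance_width_hz^2))
    x <- spec$theta_amp * gain * cos(phi)
    for (i in seq_len(ncomp)) {
      g <- spec$gamma_components[[i]]
      sig_g <- sqrt(2 * pi * g$bandwidth_hz)
      phig <- with_seed(subseeds[2 + i],
                        phase_track(n, g$center_freq_hz, sig_g, dt))
      kap_t <- rep(g$coupling_kappa, n)
      if (!is.null(coupling_f_range))
        kap_t[f_inst < coupling_f_range[1] | f_inst >= coupling_f_range[2]] <- 0
      envg <- exp(kap_t * cos(phi - g$preferred_phase_deg * pi / 180)) /
        sqrt(besselI(2 * kap_t, 0))
      x <- x + g$base_amp * envg * cos(phig)
    }
    if (spec$noise_amp > 0) {
      x <- x + spec$noise_amp *
        with_seed(subseeds[1], shaped_noise(n, spec$noise_exponent))
    }
    list(trace = trace(x, fs_hz = spec$fs_hz, units = "uV", kind = "lfp"),
         stim_log = list(freq_hz = f_inst, fs_hz = spec$fs_hz))
  })
}
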