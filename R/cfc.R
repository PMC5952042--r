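# Theta-gamma phase-amplitude coupling: Kullback-Leibler modulation index
# (Tort-style), the comodulogram over 5 Hz amplitude bands, and circular-shift
# surrogate significance testing.

#' Phase/amplitude pair
#'
#' Bundles a phase series (degrees, `(-180, 180]`) with an amplitude envelope
#' sampled at the same rate. Inputs to [modulation_index()] and
#' [surrogate_test()].
#'
#' @param phase_deg numeric phase series in degrees.
#' @param amplitude non-negative amplitude envelope, same length.
#' @param fs_hz sampling rate.
#' @return A `phase_amp_pair` object.
#' @export
phase_amp_pair <- function(phase_deg, amplitude, fs_hz) {
  if (length(phase_deg) != length(amplitude))
    stop("phase and amplitude must have equal length")
  if (any(phase_deg > 180 | phase_deg <= -180))
    stop("phase must lie in (-180, 180] degrees")
  if (any(amplitude < 0)) stop("amplitude must be non-negative")
  structure(list(phase_deg = phase_deg, amplitude = amplitude, fs_hz = fs_hz),
            class = "phase_amp_pair")
}

phase_bin_index <- function(phase_deg, n_bins) {
  idx <- ceiling((phase_deg + 180) / (360 / n_bins))
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- n_bins
  idx
}

mi_from_binned <- function(mean_amp) {
  n_bins <- length(mean_amp)
  tot <- sum(mean_amp)
  if (tot <= 0) stop("all-zero amplitude: modulation index undefined")
  p <- mean_amp / tot
  nz <- p > 0  # 0 * log(0) = 0 convention keeps the entropy finite and the
               # analytic bounds MI(uniform)=0, MI(one bin)=1 exact
  (log(n_bins) + sum(p[nz] * log(p[nz]))) / log(n_bins)
}

#' Modulation index of a phase/amplitude pair
#'
#' Bins the amplitude by phase into `n_bins` equal bins, normalises the
#' per-bin mean amplitudes to a distribution P, and returns the
#' Kullback-Leibler divergence of P from uniform, normalised by `log(n_bins)`
#' so that MI is in [0, 1]: 0 for phase-uniform amplitude, 1 when all
#' amplitude mass falls in a single bin.
#'
#' @param pair a [phase_amp_pair()].
#' @param n_bins number of phase bins (default 18, i.e. 20 degree bins).
#' @return An `mi_result`: list with `mi`, `n_bins`, `binned_mean_amp`
#'   (normalised to sum 1; empty bins contribute zero mass).
#' @examples
#' ph <- runif(5000, -180, 180)
#' amp <- exp(cos(ph * pi / 180))
#' modulation_index(phase_amp_pair(ph, amp, 1000))$mi
#' @export
modulation_index <- function(pair, n_bins = 18) {
  stopifnot(inherits(pair, "phase_amp_pair"))
  idx <- phase_bin_index(pair$phase_deg, n_bins)
  cnt <- tabulate(idx, nbins = n_bins)
  sums <- numeric(n_bins)
  s <- rowsum(pair$amplitude, idx)
  sums[as.integer(rownames(s))] <- s
  m <- ifelse(cnt > 0, sums / pmax(cnt, 1L), 0)
  mi <- mi_from_binned(m)
  structure(list(mi = mi, n_bins = n_bins,
                 binned_mean_amp = m / sum(m)),
            class = "mi_result")
}

#' Theta phase reference of an LFP trace
#'
#' Finds the dominant theta frequency (multitaper PSD, searched in
#' `theta_search`), band-pass filters the trace from 1 Hz below to 1 Hz above
#' that frequency, and extracts the instantaneous phase. Warns if the dominant
#' frequency sits at the search-band edge or drifts by more than 1 Hz between
#' the two halves of the recording (nonstationary reference).
#'
#' @param trace an LFP [trace()].
#' @param theta_search [band_spec()] search band for the dominant frequency.
#' @return List with `phase_deg` (full length), `f_theta_hz`, `band` (the
#'   +/- 1 Hz filter band) and `warning_flag`.
#' @export
theta_reference <- function(trace, theta_search = band_spec(3, 8)) {
  est <- multitaper_psd(trace)
  f0 <- dominant_frequency(est, theta_search)
  flag <- FALSE
  df <- est$freqs_hz[2] - est$freqs_hz[1]
  if (f0 <= theta_search$lo_hz + df || f0 >= theta_search$hi_hz - df) {
    warning("dominant theta frequency at the search-band edge")
    flag <- TRUE
  }
  n <- length(trace$samples)
  halves <- vapply(list(1:(n %/% 2), (n %/% 2 + 1):n), function(ix) {
    seg <- trace; seg$samples <- trace$samples[ix]
    dominant_frequency(multitaper_psd(seg), theta_search)
  }, numeric(1))
  if (abs(diff(halves)) > 1) {
    warning("dominant theta frequency is nonstationary across the recording")
    flag <- TRUE
  }
  band <- band_spec(max(0.5, f0 - 1), f0 + 1)
  filt <- bandpass(trace, band)
  list(phase_deg = analytic_phase(filt), f_theta_hz = f0, band = band,
       warning_flag = flag)
}

#' Circular-shift surrogate test for phase-amplitude coupling
#'
#' Generates surrogates by circularly shifting the amplitude series by a
#' uniformly random offset of at least one theta period (and at most the
#' series length minus one period), recomputes the MI for each, and declares
#' the observed MI significant when it exceeds the surrogate mean by more than
#' two surrogate standard deviations. Shifting preserves the amplitude
#' autocorrelation while destroying its alignment to phase.
#'
#' @param pair a [phase_amp_pair()].
#' @param n_surrogates number of surrogates (>= 50).
#' @param seed integer seed controlling the shifts (reproducible).
#' @param n_bins phase bins for the MI.
#' @param theta_freq_hz theta frequency used for the minimum shift; inferred
#'   from the phase series when NULL.
#' @return List with `mi`, `surrogate_mean`, `surrogate_sd`, `significant`.
#' @export
surrogate_test <- function(pair, n_surrogates = 200, seed = 1, n_bins = 18,
                           theta_freq_hz = NULL) {
  stopifnot(inherits(pair, "phase_amp_pair"))
  if (n_surrogates < 50) stop("need at least 50 surrogates")
  n <- length(pair$amplitude)
  if (is.null(theta_freq_hz)) {
    dph <- diff(pair$phase_deg)
    dph <- (dph + 180) %% 360 - 180
    theta_freq_hz <- mean(dph) * pair$fs_hz / 360
  }
  period <- round(pair$fs_hz / theta_freq_hz)
  if (n < 3 * period) stop("trace shorter than 3 theta periods")
  idx <- phase_bin_index(pair$phase_deg, n_bins)
  cnt <- tabulate(idx, nbins = n_bins)
  mean_amp_for <- function(amp) {
    sums <- numeric(n_bins)
    s <- rowsum(amp, idx)
    sums[as.integer(rownames(s))] <- s
    ifelse(cnt > 0, sums / pmax(cnt, 1L), 0)
  }
  mi0 <- mi_from_binned(mean_amp_for(pair$amplitude))
  shifts <- with_seed(seed, {
    sample.int(n - 2 * period, n_surrogates, replace = TRUE) + period - 1L
  })
  mis <- vapply(shifts, function(s) {
    amp_s <- c(pair$amplitude[(s + 1):n], pair$amplitude[1:s])
    mi_from_binned(mean_amp_for(amp_s))
  }, numeric(1))
  mu <- mean(mis); sg <- stats::sd(mis)
  list(mi = mi0, surrogate_mean = mu, surrogate_sd = sg,
       significant = mi0 > mu + 2 * sg)
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Comodulogram: MI across 5 Hz amplitude bands
#'
#' For each amplitude band of width `step` Hz spanning `amp_lo`-`amp_hi` Hz,
#' filters the trace to that band, extracts the Hilbert amplitude and computes
#' its modulation index against the theta phase reference. Surrogate
#' statistics are computed per band when `n_surrogates > 0` (set it to 0 to
#' skip the costly surrogate pass).
#'
#' @param trace an LFP [trace()].
#' @param amp_lo,amp_hi,step amplitude-frequency range and band width, Hz.
#' @param theta_search theta search band for the phase reference.
#' @param n_bins phase bins.
#' @param n_surrogates surrogates per band (0 = skip).
#' @param seed seed for the surrogate shifts.
#' @param edge_s seconds excluded at each end of the phase/amplitude series
#'   (filter transients).
#' @return A `comodulogram`: list with `amp_freq_centers_hz`, `mi_values`,
#'   `surrogate_mean`, `surrogate_sd`, `significant`, `theta_band_used`,
#'   `f_theta_hz`.
#' @export
comodulogram <- function(trace, amp_lo = 5, amp_hi = 400, step = 5,
                         theta_search = band_spec(3, 8), n_bins = 18,
                         n_surrogates = 200, seed = 1, edge_s = 2) {
  stopifnot(inherits(trace, "trace"))
  if (trace$fs_hz < 2 * amp_hi)
    stop(sprintf("sampling rate %g Hz too low for amplitude bands up to %g Hz",
                 trace$fs_hz, amp_hi))
  ref <- theta_reference(trace, theta_search)
  keep <- edge_keep_idx(length(trace$samples), trace$fs_hz, edge_s)
  phase <- ref$phase_deg[keep]
  los <- seq(amp_lo, amp_hi - step, by = step)
  centers <- los + step / 2
  nb <- length(centers)
  mi <- mu <- sg <- rep(NA_real_, nb)
  sig <- rep(NA, nb)
  for (i in seq_len(nb)) {
    filt <- bandpass(trace, band_spec(los[i], los[i] + step))
    amp <- analytic_amplitude(filt)[keep]
    pair <- phase_amp_pair(phase, amp, trace$fs_hz)
    if (n_surrogates > 0) {
      st <- surrogate_test(pair, n_surrogates = n_surrogates,
                           seed = seed + i, n_bins = n_bins,
                           theta_freq_hz = ref$f_theta_hz)
      mi[i] <- st$mi; mu[i] <- st$surrogate_mean; sg[i] <- st$surrogate_sd
      sig[i] <- st$significant
    } else {
      mi[i] <- modulation_index(pair, n_bins = n_bins)$mi
    }
  }
  structure(
    list(amp_freq_centers_hz = centers, mi_values = mi, surrogate_mean = mu,
         surrogate_sd = sg, significant = sig, theta_band_used = ref$band,
         f_theta_hz = ref$f_theta_hz),
    class = "comodulogram"
  )
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("<comodulogram> %d bands %g-%g Hz, theta %.2f Hz, max MI %.4g\n",
              length(x$mi_values), min(x$amp_freq_centers_hz),
              max(x$amp_freq_centers_hz), x$f_theta_hz, max(x$mi_values)))
  invisible(x)
}

#' Band-peak MI of a comodulogram
#'
#' The maximum MI over the band centers falling inside `band` (per-experiment
#' summary value); ties resolve to the lowest frequency.
#'
#' @param com a [comodulogram()].
#' @param band a [band_spec()], e.g. slow gamma 25-45 Hz or fast gamma
#'   150-250 Hz.
#' @return List with `band`, `peak_mi`, `peak_freq_hz`.
#' @export
band_peak <- function(com, band) {
  stopifnot(inherits(com, "comodulogram"), inherits(band, "band_spec"))
  keep <- which(com$amp_freq_centers_hz >= band$lo_hz &
                com$amp_freq_centers_hz <= band$hi_hz)
  if (!length(keep)) stop("band does not overlap the comodulogram")
  j <- keep[which.max(com$mi_values[keep])]
  list(band = band, peak_mi = com$mi_values[j],
       peak_freq_hz = com$amp_freq_centers_hz[j])
}

#' Phase-binned amplitude profile over tiled theta cycles
#'
#' The normalised binned amplitude distribution repeated over `cycles` theta
#' cycles, the conventional display of gamma amplitude versus theta phase.
#'
#' @param pair a [phase_amp_pair()].
#' @param n_bins phase bins per cycle.
#' @param cycles number of cycles to tile.
#' @return List with `phase_deg` (bin centers, from -180 upward) and
#'   `profile` (sums to `cycles`).
#' @export
phase_amplitude_profile <- function(pair, n_bins = 18, cycles = 2) {
  res <- modulation_index(pair, n_bins = n_bins)
  w <- 360 / n_bins
  centers <- -180 + w / 2 + w * (0:(n_bins * cycles - 1))
  list(phase_deg = centers, profile = rep(res$binned_mean_amp, cycles))
}
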