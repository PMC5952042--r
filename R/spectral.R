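# Multitaper spectral estimation. Power spectra use DPSS (Slepian) tapers,
# seven by default, with time-bandwidth product nw = 4 (2*nw - 1 = 7, the
# standard pairing when only the taper count is prescribed).

dpss_tapers <- function(n, nw = 4, k = 7) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .osc_cache[[key]]
  if (!is.null(hit)) return(hit)
  v <- cpp_dpss(as.integer(n), as.numeric(nw), as.integer(k))
  .osc_cache[[key]] <- v
  v
}

#' Multitaper power spectral density
#'
#' Average of DPSS-tapered periodograms, one-sided. With unit-energy tapers
#' the integral of the returned density over frequency equals the sample
#' variance (Parseval), so integrated band power is in squared trace units.
#'
#' @param trace a [trace()], at least 2 s long.
#' @param n_tapers number of DPSS tapers (paper-standard 7).
#' @param nw time-bandwidth product; must satisfy `n_tapers < 2 * nw`.
#' @return A `spectral_estimate`: list with `freqs_hz`, `psd`
#'   (units^2 per Hz), `n_tapers`, `nw`, `segment_s`.
#' @examples
#' tr <- trace(sin(2 * pi * 6 * seq(0, 10, by = 1 / 500)), fs_hz = 500)
#' est <- multitaper_psd(tr)
#' est$freqs_hz[which.max(est$psd)]
#' @export
multitaper_psd <- function(trace, n_tapers = 7, nw = 4) {
  stopifnot(inherits(trace, "trace"))
  if (n_tapers >= 2 * nw)
    stop("invalid taper set: n_tapers must be < 2 * nw")
  x <- trace$samples
  n <- length(x)
  if (n < 2 * trace$fs_hz) stop("trace shorter than 2 s; too short for a PSD")
  x <- x - mean(x)
  v <- dpss_tapers(n, nw, n_tapers)
  nfreq <- floor(n / 2) + 1
  acc <- numeric(nfreq)
  for (k in seq_len(n_tapers)) {
    X <- stats::fft(v[, k] * x)
    acc <- acc + (Mod(X[seq_len(nfreq)])^2)
  }
  psd <- acc / (n_tapers * trace$fs_hz)
  # one-sided: double everything except DC (and Nyquist when n is even)
  scale2 <- rep(2, nfreq)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[nfreq] <- 1
  psd <- psd * scale2
  structure(
    list(freqs_hz = (seq_len(nfreq) - 1) * trace$fs_hz / n, psd = psd,
         n_tapers = n_tapers, nw = nw, segment_s = n / trace$fs_hz,
         units = trace$units),
    class = "spectral_estimate"
  )
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d freqs to %.1f Hz, %d tapers (nw=%g), %g s\n",
              length(x$freqs_hz), max(x$freqs_hz), x$n_tapers, x$nw,
              x$segment_s))
  invisible(x)
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Integrate a spectral estimate over a band
#'
#' Trapezoidal integration of the density over the band, giving power in
#' squared trace units.
#'
#' @param est a `spectral_estimate` from [multitaper_psd()].
#' @param band a [band_spec()], or NULL for the full range.
#' @return Integrated power (units^2).
#' @export
integrate_psd <- function(est, band = NULL) {
  f <- est$freqs_hz
  p <- est$psd
  if (!is.null(band)) {
    keep <- f >= band$lo_hz & f <= band$hi_hz
    if (!any(keep)) stop("band does not overlap the frequency grid")
    f <- f[keep]; p <- p[keep]
  }
  trapz(f, p)
}

#' Multitaper spectrogram
#'
#' Sliding-window multitaper PSD; each column is the spectrum of one window.
#'
#' @param trace a [trace()].
#' @param window_s window length in seconds (must not exceed the trace).
#' @param step_s step between window starts, seconds (> 0).
#' @inheritParams multitaper_psd
#' @return List with `times_s` (window centres), `freqs_hz` and `power`
#'   (frequency x time matrix of densities).
#' @export
spectrogram <- function(trace, window_s = 5, step_s = window_s / 2,
                        n_tapers = 7, nw = 4) {
  stopifnot(inherits(trace, "trace"))
  if (step_s <= 0) stop("step_s must be > 0")
  n <- length(trace$samples)
  wlen <- round(window_s * trace$fs_hz)
  if (wlen > n) stop("window longer than trace")
  step <- max(1L, round(step_s * trace$fs_hz))
  starts <- seq(1L, n - wlen + 1L, by = step)
  cols <- lapply(starts, function(s) {
    seg <- trace
    seg$samples <- trace$samples[s:(s + wlen - 1L)]
    est <- multitaper_psd(seg, n_tapers = n_tapers, nw = nw)
    est$psd
  })
  freqs <- (seq_len(floor(wlen / 2) + 1) - 1) * trace$fs_hz / wlen
  list(times_s = trace$t0_s + (starts - 1 + wlen / 2) / trace$fs_hz,
       freqs_hz = freqs, power = do.call(cbind, cols))
}

#' Integrated band power in consecutive time bins
#'
#' Splits the trace into contiguous bins (5 s by default, the conventional
#' epoch for slice theta), computes the multitaper PSD of each and integrates
#' it over the requested band. `mean_power` is the grand mean over bins.
#'
#' @param trace a [trace()], at least two bins long.
#' @param band a [band_spec()].
#' @param bin_s bin duration in seconds.
#' @inheritParams multitaper_psd
#' @return A `band_power_series`: list with `bin_starts_s`, `power_per_bin`
#'   (units^2), `band`, `mean_power`.
#' @export
band_power_bins <- function(trace, band, bin_s = 5, n_tapers = 7, nw = 4) {
  stopifnot(inherits(trace, "trace"))
  check_band(band, trace$fs_hz)
  blen <- round(bin_s * trace$fs_hz)
  n <- length(trace$samples)
  nbins <- floor(n / blen)
  if (nbins < 2) stop("trace must span at least two bins")
  pw <- vapply(seq_len(nbins), function(i) {
    seg <- trace
    seg$samples <- trace$samples[((i - 1) * blen + 1):(i * blen)]
    integrate_psd(multitaper_psd(seg, n_tapers = n_tapers, nw = nw), band)
  }, numeric(1))
  structure(
    list(bin_starts_s = trace$t0_s + (seq_len(nbins) - 1) * bin_s,
         power_per_bin = pw, band = band, mean_power = mean(pw)),
    class = "band_power_series"
  )
}

#' Dominant frequency within a search band
#'
#' Frequency of the maximum spectral density inside the band (ties broken by
#' the lower frequency, as `which.max` scans upward).
#'
#' @param est a `spectral_estimate`.
#' @param search a [band_spec()] inside the estimate's range.
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(est, search) {
  stopifnot(inherits(search, "band_spec"))
  keep <- which(est$freqs_hz >= search$lo_hz & est$freqs_hz <= search$hi_hz)
  if (!length(keep)) stop("search band outside the frequency grid")
  est$freqs_hz[keep[which.max(est$psd[keep])]]
}
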