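# Theta rhythmicity scoring: the autocorrelogram of the theta-filtered trace
# and the "oscillation strength" scalar derived from it, plus the
# peak-triggered waveform average with its per-cycle amplitude SD.

#' Normalized autocorrelogram of a filtered trace
#'
#' Biased, normalized autocorrelation (`acf[lag 0] = 1`), computed via FFT.
#' Positive lags are returned; the definition is symmetric. The bias factor
#' `(1 - lag/N)` is negligible at theta lags for the 100 s epochs this is
#' meant for.
#'
#' @param trace a theta-band-filtered [trace()].
#' @param max_lag_s largest lag to return, seconds.
#' @return List with `lags_s` and `acf`.
#' @export
autocorrelogram <- function(trace, max_lag_s = 1) {
  stopifnot(inherits(trace, "trace"))
  x <- trace$samples
  x <- x - mean(x)
  if (stats::var(x) == 0) stop("zero-variance trace has no autocorrelogram")
  n <- length(x)
  maxlag <- min(n - 1, round(max_lag_s * trace$fs_hz))
  nfft <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  r <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / nfft
  r <- r[1:(maxlag + 1)] / r[1]
  list(lags_s = (0:maxlag) / trace$fs_hz, acf = r)
}

#' Oscillation strength (rhythmicity index)
#'
#' The height of the first positive side peak of the normalized
#' autocorrelogram, expressed in percent and clipped to [0, 100]. The side
#' peak is searched in the lag window `[0.5, 1.5] / theta_freq_hz`; a
#' perfectly periodic signal scores 100, broadband noise scores ~0. If no
#' positive local maximum exists in the window the strength is 0 and
#' `no_peak = TRUE` is flagged.
#'
#' @param lags_s,acf autocorrelogram as returned by [autocorrelogram()].
#' @param theta_freq_hz dominant theta frequency in Hz.
#' @return List with `strength_percent`, `peak_lag_s`, `no_peak`.
#' @export
oscillation_strength <- function(lags_s, acf, theta_freq_hz) {
  if (max(lags_s) < 1.5 / theta_freq_hz)
    stop("autocorrelogram must span at least 1.5 theta periods")
  win <- which(lags_s >= 0.5 / theta_freq_hz & lags_s <= 1.5 / theta_freq_hz)
  seg <- acf[win]
  # local maxima inside the window
  ismax <- c(FALSE, diff(seg) > 0) & c(diff(seg) <= 0, FALSE)
  cand <- which(ismax & seg > 0)
  if (!length(cand)) {
    # fall back to the window maximum if positive (peak may sit at an edge)
    j <- which.max(seg)
    if (seg[j] <= 0)
      return(list(strength_percent = 0, peak_lag_s = NA_real_, no_peak = TRUE))
    cand <- j
  }
  j <- cand[which.max(seg[cand])]
  list(strength_percent = min(100, max(0, 100 * seg[j])),
       peak_lag_s = lags_s[win[j]], no_peak = FALSE)
}

#' Full rhythmicity analysis of an LFP trace
#'
#' Convenience wrapper: finds the dominant theta frequency, filters the trace
#' to the theta band, and derives the autocorrelogram and oscillation
#' strength.
#'
#' @param trace an LFP [trace()].
#' @param theta_band [band_spec()] used both to search for the dominant
#'   frequency and to filter before autocorrelation.
#' @param max_lag_s autocorrelogram span.
#' @return A `rhythmicity_result`: list with `lags_s`, `acf`,
#'   `strength_percent`, `theta_freq_hz`, `no_peak`.
#' @export
rhythmicity <- function(trace, theta_band = band_spec(3, 8), max_lag_s = 1) {
  est <- multitaper_psd(trace)
  f0 <- dominant_frequency(est, theta_band)
  filt <- bandpass(trace, theta_band)
  keep <- edge_keep_idx(length(filt$samples), filt$fs_hz)
  filt$samples <- filt$samples[keep]
  ac <- autocorrelogram(filt, max_lag_s = max(max_lag_s, 2 / f0))
  os <- oscillation_strength(ac$lags_s, ac$acf, f0)
  structure(
    list(lags_s = ac$lags_s, acf = ac$acf,
         strength_percent = os$strength_percent, theta_freq_hz = f0,
         no_peak = os$no_peak),
    class = "rhythmicity_result"
  )
}

#' @export
print.rhythmicity_result <- function(x, ...) {
  cat(sprintf("<rhythmicity> strength %.1f%%, theta %.2f Hz\n",
              x$strength_percent, x$theta_freq_hz))
  invisible(x)
}

#' Peak-triggered cycle-averaged waveform
#'
#' Detects theta cycle peaks on the filtered trace (local maxima above zero
#' with a refractory period of half a theta cycle; ties broken by the earlier
#' sample), averages raw-trace windows of one theta period on each side of
#' every peak, and reports the per-cycle filtered peak amplitudes and their
#' standard deviation.
#'
#' @param trace the raw [trace()].
#' @param theta_freq_hz dominant theta frequency (Hz).
#' @param theta_band band used to filter before peak detection.
#' @return A `waveform_average`: list with `window_s`, `time_s`,
#'   `mean_waveform`, `peak_amplitudes`, `peak_sd`, `n_cycles`.
#' @export
cycle_average <- function(trace, theta_freq_hz,
                          theta_band = band_spec(3, 8)) {
  stopifnot(inherits(trace, "trace"))
  filt <- bandpass(trace, theta_band)
  fs <- trace$fs_hz
  keep <- edge_keep_idx(length(filt$samples), fs)
  xf <- filt$samples
  refr <- round(0.5 / theta_freq_hz * fs)
  pk <- find_peaks(xf, min_sep = refr, min_height = 0)
  pk <- pk[pk >= keep[1] & pk <= keep[length(keep)]]
  half <- round(fs / theta_freq_hz)
  pk <- pk[pk - half >= 1 & pk + half <= length(xf)]
  if (length(pk) < 10) stop("fewer than 10 theta cycles detected")
  wins <- vapply(pk, function(i) trace$samples[(i - half):(i + half)],
                 numeric(2 * half + 1))
  structure(
    list(window_s = half / fs, time_s = (-half:half) / fs,
         mean_waveform = rowMeans(wins), peak_amplitudes = xf[pk],
         peak_sd = stats::sd(xf[pk]), n_cycles = length(pk)),
    class = "waveform_average"
  )
}

# local maxima above min_height with a minimum separation (greedy from the
# largest; ties resolved to the earliest sample by which.max semantics)
find_peaks <- function(x, min_sep, min_height = -Inf) {
  n <- length(x)
  cand <- which(x > c(-Inf, x[-n]) & x >= c(x[-1], -Inf) & x > min_height)
  if (!length(cand)) return(integer(0))
  ord <- cand[order(x[cand], decreasing = TRUE)]
  taken <- logical(n)
  out <- integer(0)
  for (i in ord) {
    if (!taken[i]) {
      out <- c(out, i)
      lo <- max(1, i - min_sep); hi <- min(n, i + min_sep)
      taken[lo:hi] <- TRUE
    }
  }
  sort(out)
}
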