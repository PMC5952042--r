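# FFT-based analytic signal and the phase/amplitude accessors used by the
# coupling analysis.

hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited trace
#'
#' Phase of the analytic (Hilbert) signal, in degrees in `(-180, 180]`.
#' Convention: 0 deg at the oscillation peak, -180/+180 deg at the trough,
#' phase increasing with time (a quarter period after a peak the phase is
#' +90 deg). The input must already be band-limited (see [bandpass()]).
#'
#' @param trace a band-limited [trace()].
#' @return Numeric vector of phases in degrees, one per sample.
#' @export
analytic_phase <- function(trace) {
  stopifnot(inherits(trace, "trace"))
  x <- trace$samples
  if (stats::var(x) == 0) stop("cannot extract phase from a constant trace")
  ph <- Arg(hilbert_analytic(x)) * 180 / pi
  # Arg returns [-pi, pi]; map -180 to +180 to keep the half-open convention
  ph[ph <= -180] <- 180
  ph
}

#' Instantaneous amplitude envelope of a band-limited trace
#'
#' Modulus of the analytic (Hilbert) signal; the "filtered rectified"
#' amplitude used for phase-amplitude coupling.
#'
#' @param trace a band-limited [trace()].
#' @return Non-negative numeric vector, one value per sample.
#' @export
analytic_amplitude <- function(trace) {
  stopifnot(inherits(trace, "trace"))
  Mod(hilbert_analytic(trace$samples))
}

# index range excluding edge_s seconds at each end (filter/Hilbert transients
# are excluded from all downstream statistics)
edge_keep_idx <- function(n, fs_hz, edge_s = 2) {
  k <- floor(edge_s * fs_hz)
  if (2 * k >= n - 10) k <- max(0, floor((n - 10) / 2))
  (k + 1):(n - k)
}
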