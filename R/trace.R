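#' Uniformly sampled single-channel signal
#'
#' The basic container used throughout the package: a numeric sample vector
#' with its sampling rate, physical units and signal kind. Local field
#' potentials are conventionally in microvolts (`"uV"`), membrane potential in
#' millivolts (`"mV"`) and clamp current in picoamps (`"pA"`).
#'
#' @param samples numeric vector of samples; must be finite, length >= 2.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param units one of `"uV"`, `"mV"`, `"pA"`.
#' @param kind signal kind: `"lfp"` (field potential), `"vm"` (membrane
#'   potential) or `"im"` (membrane/clamp current).
#' @param t0_s start time of the first sample, seconds.
#' @return An object of class `trace`.
#' @examples
#' tr <- trace(sin(2 * pi * 6 * seq(0, 2, by = 1 / 1000)), fs_hz = 1000)
#' tr
#' @export
trace <- function(samples, fs_hz, units = c("uV", "mV", "pA"),
                  kind = c("lfp", "vm", "im"), t0_s = 0) {
  units <- match.arg(units)
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("trace needs at least 2 samples")
  if (!all(is.finite(samples))) stop("trace samples must be finite")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) ||
      fs_hz <= 0) {
    stop("fs_hz must be a positive finite scalar")
  }
  structure(
    list(samples = samples, fs_hz = fs_hz, units = units, kind = kind,
         t0_s = t0_s),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %s [%s], %d samples @ %g Hz (%.3f s)\n",
              x$kind, x$units, length(x$samples), x$fs_hz,
              length(x$samples) / x$fs_hz))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$samples)

#' Trace duration in seconds
#' @param trace a [trace()] object.
#' @return Duration in seconds.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$fs_hz

#' Sample time stamps of a trace
#' @param trace a [trace()] object.
#' @return Numeric vector of times (s), one per sample.
#' @export
trace_times <- function(trace) {
  trace$t0_s + (seq_along(trace$samples) - 1) / trace$fs_hz
}

#' Frequency band specification
#'
#' @param lo_hz,hi_hz band edges in Hz; `0 <= lo_hz < hi_hz`.
#' @return An object of class `band_spec`.
#' @examples
#' theta_band <- band_spec(3, 8)
#' slow_gamma <- band_spec(25, 45)
#' fast_gamma <- band_spec(150, 250)
#' @export
band_spec <- function(lo_hz, hi_hz) {
  if (!is.finite(lo_hz) || !is.finite(hi_hz) || lo_hz < 0 || hi_hz <= lo_hz)
    stop("band_spec requires 0 <= lo_hz < hi_hz")
  structure(list(lo_hz = lo_hz, hi_hz = hi_hz), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band> %g-%g Hz\n", x$lo_hz, x$hi_hz))
  invisible(x)
}

check_band <- function(band, fs_hz) {
  stopifnot(inherits(band, "band_spec"))
  if (band$hi_hz >= fs_hz / 2)
    stop(sprintf("band (%g, %g) Hz exceeds Nyquist frequency %g Hz",
                 band$lo_hz, band$hi_hz, fs_hz / 2))
  invisible(band)
}

#' Write a trace to CSV with a JSON metadata sidecar
#'
#' Writes `<path>` as a two-column CSV (`time_s`, `value`) with 17 significant
#' digits, plus `<path minus .csv>.json` holding `{fs_hz, units, kind, t0_s}`.
#' [read_trace()] round-trips the samples bit-exactly.
#'
#' @param trace a [trace()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,value", con)
  writeLines(paste(format(trace_times(trace), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   format(trace$samples, digits = 17, trim = TRUE),
                   sep = ","), con)
  meta <- list(fs_hz = trace$fs_hz, units = trace$units, kind = trace$kind,
               t0_s = trace$t0_s)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Read a trace written by [write_trace()]
#'
#' @param path CSV path; the JSON sidecar must sit next to it.
#' @return A [trace()] object.
#' @export
read_trace <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  trace(df$value, fs_hz = meta$fs_hz, units = meta$units, kind = meta$kind,
        t0_s = if (is.null(meta$t0_s)) 0 else meta$t0_s)
}
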