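# Section-wise analysis of chirp (ZAP) driven responses: the 0-12 Hz sweep is
# cut into six 2 Hz sections by instantaneous stimulus frequency; coupling
# (MI) and normalised drive-band power are evaluated per section.

#' Partition a ZAP response by instantaneous stimulus frequency
#'
#' Each sample is assigned to the section whose half-open frequency interval
#' `[lo, hi)` contains the stimulus frequency at that sample (a sample at
#' exactly 4 Hz belongs to the 4-6 Hz section); the final edge is inclusive.
#' The stimulus frequency must be monotone non-decreasing, so each section is
#' one contiguous span.
#'
#' @param trace the response [trace()].
#' @param stim_log list with `freq_hz` (instantaneous stimulus frequency per
#'   sample) and `fs_hz`, as produced by [generate_zap_response()].
#' @param edges_hz section boundaries (default `c(0, 2, 4, 6, 8, 10, 12)`).
#' @return A `zap_sections` object: list with `edges_hz`, `sections` (per
#'   section: `band`, `trace`, `idx`), `stim_log`.
#' @export
section_by_stimulus <- function(trace, stim_log,
                                edges_hz = c(0, 2, 4, 6, 8, 10, 12)) {
  stopifnot(inherits(trace, "trace"))
  f <- stim_log$freq_hz
  if (length(f) != length(trace$samples))
    stop("stimulus log does not cover the trace")
  if (any(diff(f) < 0)) stop("stimulus frequency must be non-decreasing")
  lo <- edges_hz[1]; hi <- edges_hz[length(edges_hz)]
  if (any(f < lo | f > hi))
    stop(sprintf("stimulus frequency outside %g-%g Hz", lo, hi))
  sec <- findInterval(f, edges_hz, rightmost.closed = TRUE)
  sections <- lapply(seq_len(length(edges_hz) - 1), function(k) {
    idx <- which(sec == k)
    if (!length(idx)) return(NULL)
    tr <- trace
    tr$samples <- trace$samples[idx]
    tr$t0_s <- trace$t0_s + (idx[1] - 1) / trace$fs_hz
    list(band = band_spec(edges_hz[k], edges_hz[k + 1]), trace = tr,
         idx = range(idx))
  })
  structure(list(edges_hz = edges_hz, sections = sections,
                 stim_log = stim_log),
            class = "zap_sections")
}

#' @export
print.zap_sections <- function(x, ...) {
  cat(sprintf("<zap_sections> %d sections over %g-%g Hz\n",
              length(x$sections), min(x$edges_hz), max(x$edges_hz)))
  invisible(x)
}

# phase of the driven oscillation within one section: band-limited to the
# section's drive band (floor 0.5 Hz so the lowest section remains filterable)
section_phase <- function(sec) {
  band <- band_spec(max(sec$band$lo_hz, 0.5), sec$band$hi_hz)
  analytic_phase(bandpass(sec$trace, band))
}

#' Per-section modulation index of a ZAP response
#'
#' For each section the drive phase is extracted from the section's own
#' frequency band (the drive frequency is known and nonstationary, so no
#' global dominant frequency is used) and the MI of the gamma-band amplitude
#' against that phase is computed. Sections with fewer than 3 driven cycles
#' are marked missing and excluded from the peak.
#'
#' @param sections a [section_by_stimulus()] result.
#' @param band gamma [band_spec()] (slow 25-45 Hz or fast 150-250 Hz).
#' @param n_bins phase bins.
#' @param edge_s seconds trimmed at each section end (filter transients).
#' @return List with `section_mi` (NA where missing), `peak_mi`,
#'   `peak_section` and `section_bands`.
#' @export
zap_mi <- function(sections, band, n_bins = 18, edge_s = 0.5) {
  stopifnot(inherits(sections, "zap_sections"))
  mis <- vapply(sections$sections, function(sec) {
    if (is.null(sec)) return(NA_real_)
    tr <- sec$trace
    check_band(band, tr$fs_hz)
    f_mid <- mean(c(sec$band$lo_hz, sec$band$hi_hz))
    n_cycles <- trace_duration(tr) * f_mid
    if (n_cycles < 3 || trace_duration(tr) < 4 * edge_s)
      return(NA_real_)
    phase <- section_phase(sec)
    amp <- analytic_amplitude(bandpass(tr, band))
    keep <- edge_keep_idx(length(phase), tr$fs_hz, edge_s)
    pair <- phase_amp_pair(phase[keep], amp[keep], tr$fs_hz)
    modulation_index(pair, n_bins = n_bins)$mi
  }, numeric(1))
  if (all(is.na(mis))) stop("no section long enough for MI")
  pk <- which.max(mis)
  list(section_mi = mis, peak_mi = mis[pk], peak_section = pk,
       section_bands = lapply(sections$sections,
                              function(s) if (is.null(s)) NULL else s$band))
}

#' Normalised drive-band power per ZAP section
#'
#' Integrated multitaper power of each section in its own drive band, divided
#' by the sum over sections (shares sum to 1).
#'
#' @param sections a [section_by_stimulus()] result with all six sections
#'   present.
#' @return List with `norm_power` (sums to 1) and `raw_power`.
#' @export
zap_theta_power <- function(sections) {
  stopifnot(inherits(sections, "zap_sections"))
  if (any(vapply(sections$sections, is.null, logical(1))))
    stop("all sections must be present")
  raw <- vapply(sections$sections, function(sec) {
    est <- multitaper_psd(sec$trace)
    integrate_psd(est, band_spec(max(sec$band$lo_hz, 0.1), sec$band$hi_hz))
  }, numeric(1))
  if (sum(raw) <= 0) stop("all-zero response")
  list(norm_power = raw / sum(raw), raw_power = raw)
}

#' Full ZAP analysis
#'
#' Sections the response, then computes per-section slow- and fast-gamma MI
#' (with their maxima over sections, the per-experiment "peak MI") and the
#' normalised drive-band power profile.
#'
#' @param trace the response [trace()].
#' @param stim_log stimulus log (see [section_by_stimulus()]).
#' @param sg_band,fg_band slow/fast gamma bands.
#' @return A `zap_result`: list with `per_section_mi_sg`,
#'   `per_section_mi_fg`, `peak_mi_sg`, `peak_mi_fg`, `norm_theta_power`.
#' @export
zap_analysis <- function(trace, stim_log, sg_band = band_spec(25, 45),
                         fg_band = band_spec(150, 250)) {
  sections <- section_by_stimulus(trace, stim_log)
  sg <- zap_mi(sections, sg_band)
  fg <- zap_mi(sections, fg_band)
  pw <- zap_theta_power(sections)
  structure(
    list(per_section_mi_sg = sg$section_mi, per_section_mi_fg = fg$section_mi,
         peak_mi_sg = sg$peak_mi, peak_mi_fg = fg$peak_mi,
         norm_theta_power = pw$norm_power),
    class = "zap_result"
  )
}

#' @export
print.zap_result <- function(x, ...) {
  cat(sprintf("<zap_result> peak MI: SG %.4g (s%d), FG %.4g (s%d)\n",
              x$peak_mi_sg, which.max(x$per_section_mi_sg),
              x$peak_mi_fg, which.max(x$per_section_mi_fg)))
  invisible(x)
}
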