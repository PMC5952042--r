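Package: oscillopipe
Title: Theta-Gamma Coupling and Intracellular Analysis of Hippocampal Recordings
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing in vitro hippocampal electrophysiology:
    multitaper power spectra of local field potentials, autocorrelogram-based
    theta rhythmicity scoring, theta-gamma phase-amplitude coupling via the
    Kullback-Leibler modulation index with circular-shift surrogate testing,
    section-wise coupling and resonance analysis of chirp (ZAP) driven
    responses, and patch-clamp sweep analysis (spike shape, f-I curves, evoked
    and spontaneous post-synaptic currents). Includes a seeded synthetic-data
    generator emulating the statistical structure of such recordings so that
    every analysis stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
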