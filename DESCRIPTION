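Package: pgrange
Title: Prompt-Gamma Range Verification by Time-of-Flight Torus Intersection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs in three dimensions the emission maximum of the
    2.741 & 6.128 MeV oxygen-16 de-excitation prompt-gamma couples produced
    during proton beam therapy, as seen by a 16-module LaBr3(Ce)
    time-of-flight spectrometer. Couples of coincident gamma rays are
    selected by energy windows, each couple is converted into the
    intersection circle of its two time-of-flight spheres and fattened into
    a 3 mm torus, all torus pairs are intersected by surface triangulation
    and a Moller triangle-triangle test, and the resulting virtual emission
    positions are histogrammed and Gaussian-fitted to report the beam
    end-of-range. Includes an analytic Bragg-Kleeman beam model, a seeded
    Monte-Carlo event generator standing in for a full transport
    simulation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
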