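Package: tiltprobe
Title: Design of Tilted-Fiber Diffuse Reflectance Probes in the Subdiffusive Regime
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo photon transport in semi-infinite turbid media with
    tilted source and detector fibers, together with the scattering-order
    machinery needed to design compact diffuse-reflectance-spectroscopy
    probes: analytic and sampled Henyey-Greenstein, modified
    Henyey-Greenstein and modified power-of-cosines phase functions, the
    Legendre-moment decay laws for multiply scattered light, the per-order
    weight Ws and the criterion F that fix the minimum source-detector
    separation, a reflectance look-up-table inverse solver whose noise
    robustness fixes the maximum separation, and the zv80 sampling-depth
    metric.  The three-step probe-design workflow is exposed as a single
    orchestration function and a thin command-line script.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    rlang,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
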