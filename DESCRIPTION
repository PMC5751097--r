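Package: mocapnet
Title: Centralized Oscillator-Satellite Networks for Motion-Capture Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models motion-capture marker trajectories with centralized
    networks in which a few oscillator centers drive many satellite units
    through a radial-basis-function map. Provides harmonic and nonlinear
    (pendulum, Duffing) center dynamics with energy and frequency
    diagnostics, three satellite basis families, linear least-squares
    weight fitting, exhaustive and random search over center frequencies,
    segmented fitting, corrected-AIC model-size selection, a multistable
    switching module that toggles the network between stored motions, a
    synthetic ground-truth generator, and readers and writers for a flat
    marker CSV dialect, TRC files, and a structured model file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
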