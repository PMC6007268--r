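Package: rnamelt
Title: RNA Nearest-Neighbor Parameter Estimation from Optical Melting Curves
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing UV optical melting experiments on short RNA
    duplexes and for estimating nearest-neighbor thermodynamic parameters
    directly from melting curves using a partition-function (ensemble) model
    of duplex pairing, rather than the classical two-state assumption.
    Includes baseline correction and fraction-paired transformation of
    absorbance curves, melting-temperature interpolation, a no-slip duplex
    partition function with per-pair probabilities, trust-region non-linear
    least-squares fitting of stack, initiation, terminal AU and disordered
    internal-loop enthalpies and entropies, the error-weighted two-state
    regression baseline, jackknife resampling, benchmarking with paired
    t-tests, and a seeded synthetic melting-experiment generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
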