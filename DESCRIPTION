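Package: quenchkit
Title: Critical Analysis of Fluorescence Quenching Titrations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the critical analysis of association constants
    obtained from fluorescence quenching titrations of host-guest
    systems. Implements inner-filter-effect (IFE) correction of
    measured intensities from absorbance data, Stern-Volmer fits on
    corrected and uncorrected intensities, exact 1:1 equilibrium
    speciation, global fitting of spectrophotometric titrations,
    multi-exponential reconvolution fitting of time-correlated
    single-photon-counting (TCSPC) decays, and a sequential diagnosis
    workflow that discriminates static quenching, dynamic quenching,
    and purely apparent quenching caused by the inner filter effect.
    A synthetic-data generator with known ground truth supports
    validation of every estimator by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
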