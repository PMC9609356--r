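Package: memfluor
Title: Fluorescence Analytics for Membrane Biophysics and Protein-Ligand
    Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for fluorescence-based membrane and
    protein-interaction studies: preprocessing of emission spectra
    (scan averaging, background subtraction, moving-average smoothing,
    peak location), DPH fluorescence anisotropy and Laurdan generalized
    polarization with Dunnett many-to-one dose-response comparison,
    percent hemolysis and osmotic-fragility curve summaries (logistic
    C50), erythrocyte shape-population statistics, and tryptophan
    quenching titration analysis via the modified Stern-Volmer and
    Scatchard double-log regressions with static/dynamic mechanism
    classification.  Includes seedable synthetic-data generators whose
    forward models invert exactly under each analysis at zero noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    mvtnorm,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse,
    withr
Config/testthat/edition: 3
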