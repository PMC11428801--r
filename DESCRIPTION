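Package: redoxspec
Title: Species-Specific Microspeciation and Thiol-Disulfide Redox Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for species-specific (microscopic) acid-base and redox
    chemistry of thiol and selenol antioxidants. Enumerates protonation
    microstates of polyprotic ligands, interconverts microscopic and
    macroscopic protonation constants, and computes pH-dependent microspecies
    mole fractions with overflow-safe log-space arithmetic. Predicts
    species-specific standard redox potentials of thiolates (and selenolates)
    from their log basicity via a calibrated linear model with delta-method
    uncertainty, builds pH-dependent apparent redox potential profiles of
    thiol-disulfide couples by abundance-weighted Nernst averaging, and
    computes a pH-dependent antioxidant-capacity score together with a
    basicity-by-pH design surface locating the optimal thiolate basicity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
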