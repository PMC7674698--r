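Package: pedidose
Title: Paediatric Internal Dosimetry for Dynamic Renal Scintigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the absorbed dose to abdominal organs and gonads of a
    five-year-old child during a Tc-99m DTPA dynamic kidney test. A stylized
    voxel phantom with reference organ compositions is combined with a
    minute-by-minute renal excretion model (kidneys draining to the bladder
    at a rate set by split kidney function), a photon Monte Carlo transport
    engine with Woodcock tracking and Klein-Nishina scattering, and a
    decay-weighted dose integrator. Organ doses per unit administered
    activity (mGy/mCi) are compared against ICRP reference coefficients for
    normal and impaired kidney function.
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
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
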