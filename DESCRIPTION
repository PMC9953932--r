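Package: bnctquant
Title: Quantitative Analysis for Boron Neutron Capture Therapy Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for preclinical boron neutron capture therapy
    (BNCT) experiments: four-component neutron dosimetry (boron, nitrogen,
    hydrogen recoil and gamma absorbed doses) with CBE/RBE-weighted
    photon-equivalent doses; linear-quadratic fitting of clonogenic survival
    with iso-effect inversion at a fixed surviving fraction to estimate the
    beam RBE and compound biological effectiveness (CBE); boron
    biodistribution summaries with tumor-to-brain and tumor-to-blood ratios;
    relative gene expression by the 2^-ddCt method; Kaplan-Meier survival,
    log-rank tests and percent increased lifespan; and seeded synthetic-data
    generators that emulate every input so the full pipeline runs and is
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
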