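Package: selexkit
Title: Analytics for Class-Specific Aptamer Selection Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis stack for SELEX aptamer selection studies of the
    parallel-and-serial kind: tracking motif-family enrichment across
    selection rounds from sequencing reads, gel-elution binding statistics
    with Langmuir affinity estimation, single-site and racemic-competitive
    isothermal titration calorimetry (ITC) binding models, and
    dye-displacement colorimetric assay calibration with detection limits.
    Includes seeded synthetic-data generators that emulate every input so
    the full pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
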