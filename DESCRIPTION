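Package: glcga
Title: Structure-Oriented Screening of Glucose-Conjugated Gibberellins from
    Isotope-Labeled LC-MS/MS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering glucose-conjugated gibberellins (Glc-GAs)
    in plant extracts analyzed by LC-MS/MS after carboxyl-directed chemical
    derivatization with an N,N-dimethylethylenediamine (DMED) / d4-DMED
    isotope reagent pair. Provides molecular-formula arithmetic and exact
    monoisotopic mass computation, construction of light/heavy candidate
    mass channels from a gibberellin registry, mzML reading, extracted-ion
    chromatogram generation and chromatographic peak detection, light/heavy
    peak-pair matching, five-class neutral-loss MS/MS rule screening with
    A-ring feature inference, retention-index calibration and a quantitative
    structure-retention relationship (QSRR) filter, a four-step candidate
    identification pipeline, and a ground-truthed synthetic LC-MS/MS run
    simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    mzR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'glcga-package.R'
    'AllClasses.R'
    'elements.R'
    'formula.R'
    'registry.R'
    'run-io.R'
    'peaks.R'
    'screen.R'
    'qsrr.R'
    'identify.R'
    'simulate.R'
    'fixtures.R'
    'show-methods.R'
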