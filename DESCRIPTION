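Package: icanseeg
Title: Qualitative and Quantitative EEG Biomarkers of CAR T-Cell Neurotoxicity Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the electroencephalogram (EEG) as a biomarker
    of immune effector cell-associated neurotoxicity syndrome (ICANS) after
    CAR T-cell therapy. Implements a rule-based 0-3 encephalopathy grading
    scale for structured visual-read evaluation forms, a quantitative EEG
    pipeline (band energies, amplitude entropy, Higuchi fractal dimension,
    broadband phase transfer entropy and directed-graph connectivity
    measures), fixed and time-dependent Cox proportional-hazards risk models
    with stepwise likelihood-ratio selection and tertile cut-off analysis,
    and a synthetic EEG/cohort generator that emulates the serial-EEG study
    design so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    survival,
    igraph,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
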