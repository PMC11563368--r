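Package: mtuaudit
Title: Strain-Injury Auditing of Hill-Type Musculoskeletal Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects unphysiological deformation and ill-tuned Hill-type
    muscle parameters in musculoskeletal models by treating every muscle
    element as a sensor. Implements tendon force-strain curve evaluation for
    the Thelen-type and extended Hill-type tendon families, derivation of
    tendon-specific minor strain-injury thresholds (TSIC) by intersecting a
    tendon's linearised force-strain curve with a yield line interpolated
    between positional and energy-storage boundary tendons, and grading of
    muscle-tendon-unit time series against force-based (MSIC) and
    strain-based (TSIC) injury criteria. Includes a quasi-static synthetic
    scenario generator for gait-like and over-stretch loading, readers for
    CSV and OpenSim-style storage traces, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
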