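Package: luthy
Title: Quantitative Analysis of LuTHy Double-Readout Protein Interaction Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scoring and interpretation of LuTHy double-readout two-hybrid
    experiments, in which binary protein-protein interactions are quantified
    in live mammalian cells by bioluminescence resonance energy transfer
    (BRET) and, after lysis, by luminescence-based co-precipitation (LuC).
    Provides readers and validators for plate-reader measurement tables,
    donor bleed-through and precipitation-reference corrections (Cf, PIR),
    corrected cBRET and cLuC interaction scores, localization-stratified
    cutoff calling with ROC-based calibration, donor-saturation (BRET50)
    and dose-response (EC50/IC50) curve fitting, mutant-versus-wild-type
    differential interaction profiling with resampling-based inference,
    pixel-wise ratiometric BRET imaging, and a generative simulator of
    complete screens with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
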