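Package: loopdep
Title: Retrieval Dependency and Cortical Reinstatement Analysis for
    Multi-Element Event Memory Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing holistic recollection in multi-element
    associative memory experiments that contrast fully overlapping
    ("closed-loop", AB-BC-CA) with partially overlapping ("open-loop",
    AB-BC-CD) event structures. Generates the combinatorial experimental
    design (encoding and bidirectional four-alternative forced-choice
    retrieval schedules), scores retrieval dependency against independent
    and guessing-corrected dependent null models via participant-specific
    contingency tables, computes cue/target/nontarget cortical
    reinstatement scores from region-of-interest parameter estimates,
    fits minimal first-level BOLD general linear models with canonical
    haemodynamic-response regressors and scan-outlier handling, and
    relates hippocampal-subfield activity differences to reinstatement
    with dependent-correlation z-tests. A latent-trace cohort simulator
    provides fully synthetic data with the statistical structure the
    analyses assume, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
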