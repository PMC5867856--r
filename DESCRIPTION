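Package: adnasex
Title: Biological Sexing and Authentication of Ancient Shotgun Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for authenticating ancient DNA shotgun sequencing data and
    determining the biological sex of degraded skeletal samples. Implements
    mapping-quality, duplicate and fragment-length read filtering, terminal
    deamination (C-to-T / G-to-A) damage profiling with a geometric-decay
    damage model, post-mortem-damage (PMD) likelihood-ratio read selection,
    the R_Y and R_X chromosomal read-ratio sex statistics with Wald 95%
    confidence intervals and published calling thresholds, mitochondrial
    pileup and consensus calling over a circular reference, and a
    two-component EM mixture estimator of modern mitochondrial contamination
    with bootstrap confidence intervals. A truth-tagged ancient-read
    simulator generates miniature XX/XY genomes with realistic fragment
    lengths, terminal damage and contaminant admixture so the whole pipeline
    is testable without access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
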