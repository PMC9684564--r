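Package: apmscall
Title: Presence/Absence Interactor Calling and Set Comparison for AP-MS
    Pull-Down Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for calling candidate bait interactors from affinity
    purification mass spectrometry (AP-MS / IP-MS) protein-group tables
    using a presence/absence approach: q-value quality filtering, removal
    of decoy and contaminant identifications, subtraction of proteins seen
    in isotype-control pull-downs, and an all-replicates detection rule.
    Downstream utilities compare interactor sets across conditions (Venn
    region counts, condition-common cores, group-unique sets), compute
    overlap statistics against reference interactome lists, run Fisher's
    exact overrepresentation tests against GMT annotation sets with
    multiple-testing correction, and assess replicate concordance through
    pairwise Pearson correlation of log2 intensities. A synthetic AP-MS
    generator with planted ground truth (bait, condition-specific
    interactors, nonspecific binders, decoys, contaminants) makes the full
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
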