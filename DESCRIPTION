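Package: funcyto
Title: Functional Cytometry of Time-Lapse Fluorescence Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Extracts per-cell fluorescence time courses from two-channel
    (FRET donor/acceptor) time-lapse microscopy of intact tissue, corrects
    slow baseline drift using recurrent returns to basal (agent-free)
    conditions, quantifies the reversible per-cell effects of sequentially
    applied pharmacological agents, and profiles the resulting
    multi-agonist response matrix into functional cell subpopulations via
    sorting statistics, correlation analysis, k-means with elbow-based
    model selection, Ward hierarchical clustering and principal component
    factor contributions.  Includes a synthetic-data generator emulating
    sensor-expression scaling, channel-wise photobleaching drift and
    reversible agonist responses, so the full pipeline is testable without
    recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    minpack.lm,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    ape
Config/testthat/edition: 3
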