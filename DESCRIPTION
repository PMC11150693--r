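Package: tsmoea
Title: Two-Stage Sparse Multi-Objective Evolutionary Channel Selection for EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Channel selection for multichannel EEG brain-computer interfaces
    posed as a sparse large-scale two-objective optimization problem over
    per-pair connectivity thresholds. Implements functional connectivity
    measures (Pearson correlation, phase-locking value, transfer entropy),
    threshold-based filtering and channel deletion, a two-stage evolutionary
    algorithm (TS-MOEA) with hybrid real/binary encoding, electrode-geometry
    score assignment, sparse initialization, score-based genetic operators,
    NSGA-II style environmental selection, the two-dimensional hypervolume
    indicator, a synthetic generator of windowed recordings with planted
    correlated channels, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    optparse,
    rlang,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
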