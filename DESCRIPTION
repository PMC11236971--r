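Package: stconnectome
Title: Spatiotemporal Connectome Analysis of Parcellated Brain Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts transient networks of brain activity from parcellated
    functional time series constrained by a structural connectome. Regional
    signals are reduced to a binary point process, joined into a multilayer
    spatiotemporal graph whose weakly connected components are transient
    co-activation events, and summarised with entropy-based System Diversity
    and cosine-based Spatiotemporal Diversity at global and functional-system
    scales. Includes subject-level permutation tests with FDR correction,
    ANCOVA of component characteristics on group and age, and a synthetic
    cohort generator with plantable group differences for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
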