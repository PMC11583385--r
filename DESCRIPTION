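Package: mtlflex
Title: Dynamic Medial Temporal Lobe Network Flexibility from Windowed
    Coherence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates dynamic network flexibility of the medial temporal
    lobe (MTL) from ROI-averaged resting-state time series. Builds windowed,
    band-averaged magnitude-squared coherence networks, links them into a
    multilayer network, partitions it with a Louvain-like greedy multilayer
    modularity optimizer, and summarises per-node and network flexibility.
    Also provides the Rutgers acquired equivalence task (schedule
    generation, simulated agents, automated scoring), RAVLT score
    derivation, covariate-adjusted standardized regression models linking
    flexibility, cognition and plasma biomarkers, an exact noncentral-t
    point-biserial sample-size calculation, and synthetic-data generators
    with planted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
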