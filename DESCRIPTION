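Package: cryptohot
Title: Cryptic Binding Site Prediction from Mixed-Solvent Simulation Hotspots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and ranks candidate cryptic ligand-binding sites on proteins
    from mixed-solvent molecular dynamics (MSMD) probe trajectories. Probe
    heavy-atom positions are binned into 1 Angstrom voxel occupancy grids,
    high-occupancy voxels are clustered with DBSCAN and merged across probes
    into hotspots, hotspots are labelled cryptic or non-cryptic by steric-clash
    analysis of superposed apo/holo structure pairs, surface-patch and
    probe-derived features are extracted per hotspot, and supervised
    classifiers (including an AdaBoost model evaluated by leave-one-out
    cross-validation) rank hotspots by their probability of being cryptic
    sites. Includes a synthetic-data generator for planted accumulation sites,
    apo/holo clash pairs and labelled feature tables, plus utilities to map
    residue-level scores from external predictors onto hotspots for
    head-to-head comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    rpart,
    e1071,
    randomForest,
    xgboost,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
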