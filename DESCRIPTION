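Package: fvrin
Title: Residue Interaction Network Analysis and Mutation-Risk Scoring for Coagulation Factor V
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a residue interaction network (RIN) from a protein
    structure in PDB format, quantifies per-residue importance with seven
    centrality measures, classifies residues into criticality groups by
    uniform binning of the degree/log-betweenness plane, extracts the
    Pareto-front "supercritical" set maximizing degree, betweenness and
    closeness, compares deficiency-associated residues to the remainder
    with a subsample-bootstrap median test, and trains an imbalance-aware
    ensemble of five classifiers that scores every residue's mutation
    risk from 0 to 5. Includes a synthetic-data module generating toy
    structures with known backbone geometry, random graphs, and feature
    tables with planted label effects, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    stats,
    utils,
    rpart,
    ranger,
    xgboost,
    e1071,
    class,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
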