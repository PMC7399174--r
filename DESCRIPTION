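Package: synlogic
Title: Cell-Line-Specific Drug Synergy Prediction with Calibrated Logical Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds multi-valued logical models from signed prior-knowledge
    signaling networks, calibrates them to per-cell-line baseline activity
    profiles by minimal link-operator changes, simulates single- and
    double-drug perturbations via exact stable-state computation (with
    asynchronous-attractor fallback after model reduction), and calls drug
    synergies from the model Viability readout. Observed dose-matrix screens
    are binarized by mean Highest Single Agent (HSA) excess and predictions
    are scored with confusion-matrix metrics including MCC, balanced
    accuracy and a seeded hypergeometric Monte-Carlo random baseline.
    Includes a node-influence sweep (fix/invert each node), mechanism
    subgraph construction for predicted synergies, structural node features
    (out-degree, betweenness, harmonic closeness, global efficiency and the
    pathway cross-talk inhibition index), random-forest feature-importance
    ranking, and synthetic-data generators with planted ground truth for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    randomForest,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
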