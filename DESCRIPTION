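Package: viewtox
Title: Structure-to-Toxicity Generators from Weighted Sets of Molecular Views
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vectorizes 3D chemical structures into weighted sets of canonical
    local-coordinate "views", trains a regression deep-network generator
    (Go-ZT) and a conditional least-squares-GAN generator (GAN-ZT) to emit
    18-endpoint zebrafish developmental-toxicity incidence matrices, scores
    matrices with an aggregate-entropy (AggE) summary thresholded at 9.35
    bits to call chemicals active or inactive, and evaluates calls with
    imbalance-aware metrics (sensitivity, specificity, positive predictive
    value, Cohen's kappa, balanced-accuracy AUROC), AND-consensus of two
    models, repeated random-split cross-validation, random-search tuning and
    a label-shuffle null. Includes a synthetic-data module that generates
    idealized-geometry molecules with planted structure-to-toxicity signal
    so the whole pipeline is testable without any external screen.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
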