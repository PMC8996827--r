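Package: drfp
Title: Differential Reaction Fingerprints for Reaction Classification and
    Yield Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes chemical reactions written as reaction SMILES
    (REACTANTS>REAGENTS>PRODUCTS) into fixed-length binary differential
    reaction fingerprints. Circular substructures (molecular n-grams) and
    SSSR rings are extracted as canonical fragment SMILES from both sides
    of the reaction, the symmetric difference of the two fragment sets is
    hashed to 32-bit integers and folded modulo the fingerprint dimension.
    Every bit maps back to the substructures that produced it. Includes
    downstream harnesses for reaction classification (exact 5-nearest
    neighbours, multilayer perceptron) and yield regression (gradient
    boosting), evaluation metrics (accuracy, multiclass Matthews
    correlation, confusion entropy, R squared), a template-based synthetic
    reaction generator for self-contained benchmarking, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Open Babel
Config/testthat/edition: 3
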