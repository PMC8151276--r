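Package: gpcrtracer
Title: Fingerprint-Based Prediction and NanoBRET Screening Analysis of
    Promiscuous GPCR Tracer Scaffolds
Version: 0.1.0
Authors@R:
    person("Artifact", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated analysis pipeline for discovering promiscuous
    fluorescent tracer scaffolds for G-protein coupled receptors (GPCRs).
    Builds balanced, stratified ligand-family datasets from GPCR-ligand
    interaction tables; encodes molecules as a 758-position concatenated
    fingerprint (MACCS keys, E-State atom-type counts, and a 512-slot
    functional-group substructure block) with near-zero-variance feature
    elimination; trains and evaluates a multiclass random-forest family
    classifier with repeated cross-validation and a randomized-label
    control; converts class probabilities into multi-family promiscuity
    profiles via a probability threshold; embeds chemical space in two
    dimensions with UMAP; computes NanoBRET competitive-screen statistics
    (BRET ratios, fold responses, signal-to-noise, saturation-binding
    fits); and quantifies concordance between model predictions and
    screen confirmations.  A synthetic-data module generates
    family-clustered chemistry and simulated BRET plates so the whole
    pipeline is testable without external downloads.  Molecule handling
    and random-forest training are delegated to a bundled Python backend
    (RDKit, scikit-learn).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    stats,
    uwot,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with rdkit, numpy, scikit-learn and
    joblib available on the PATH as 'python' (or set
    options(gpcrtracer.python=)).
Config/testthat/edition: 3
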