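Package: pocketeer
Title: Cryptic Surface-Pocket Detection, Biased Conformational Ensembles,
    and Exemplar-Based Inhibitor Selectivity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects deep surface pockets near protein-interaction sites on a
    Ligsite-style grid anchored at target residues, generates ensembles of
    pocket-containing conformations with a Metropolis Monte Carlo sampler
    biased by deep pocket volume, summarises each pocket as an "exemplar"
    pseudo-ligand (hydrogen-bond donor/acceptor probes plus greedy hydrophobic
    fill), compares exemplars by Gaussian shape and chemistry overlap with
    Tanimoto scoring, and turns the resulting exemplar distances into
    selectivity analytics: multidimensional-scaling pocket maps, pocket
    distinctness, per-ligand selectivity Z-score rows, ROC evaluation and
    rank-matrix correlations. Ships a deterministic synthetic-fixture
    generator (carved pseudo-proteins with known ground truth) so the whole
    pipeline runs without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ChemmineR,
    jsonlite,
    yaml,
    rlang,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
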