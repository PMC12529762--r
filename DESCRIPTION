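Package: pcmaudit
Title: Leakage-Aware Evaluation of Proteochemometric Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the rigorous evaluation of proteochemometric (PCM)
    models of kinase-ligand bioactivity. Provides MSA-guided padding and
    trimming of per-residue protein embeddings, amino-acid descriptor
    scales and one-hot encoding, a composite-loss autoencoder reduction,
    circular and path molecular fingerprints, leakage-controlled
    cross-validation splits (random, kinase-grouped, family-grouped),
    per-kinase stochastic negative addition for class rebalancing, X/Y
    permutation testing of protein blocks, ligand blocks and labels,
    block-wise protein feature importance, factorial ANOVA with Tukey HSD
    post-hoc reporting, and a fully seeded synthetic-data generator with
    known ground-truth signal structure so that every stage of the
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    xgboost,
    randomForest,
    car,
    seqinr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
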