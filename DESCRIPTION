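Package: drugwalker
Title: Two-Pass Random Walk with Restart for Drug Repositioning on
    Drug-Disease Heterogeneous Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts new indications for approved drugs by diffusion on a
    heterogeneous network that couples a drug-drug similarity network, a
    disease-disease similarity network and the known drug-disease
    association network. Drug similarity fuses chemical-fingerprint Jaccard
    scores with a bipartite network projection of the associations; disease
    similarity fuses phenotype concept-vector cosine scores with the dual
    projection. Every candidate drug-disease pair is scored by the mean of
    two restart walks, one seeded at the drug and one at the disease, and
    ranking performance is evaluated by 10-fold cross-validation with ROC,
    AUC and top-rank hit counts. Includes a synthetic planted-block
    generator for associations, fingerprints and concept vectors, tabular
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    methods,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
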