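Package: netonco
Title: Latent Oncogene Prioritization from Multi-Channel Protein Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes latent oncogenes from multi-channel protein-protein
    association networks. Builds one weighted network per STRING evidence
    channel, computes random-walk-with-restart diffusion profiles per node
    and channel, learns a joint low-dimensional node embedding by minimizing
    the Kullback-Leibler divergence between diffusion profiles and their
    softmax reconstructions, and scores unlabelled proteins with a
    negative-partition random-forest ensemble. Each unlabelled protein
    receives a "level value" (mean positive-class probability over the
    ensemble models not trained on it); positives are scored by a
    leave-one-out jackknife. Includes ROC/PR evaluation, an embedding
    dimension sweep, threshold/overlap reporting against external candidate
    lists, and a stochastic-block-model generator for multi-channel networks
    with planted label structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
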