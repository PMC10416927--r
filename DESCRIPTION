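Package: rinn
Title: Redundant-Input Neural Networks for Latent Causal Structure in
    Cancer Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits redundant-input neural networks (RINNs) and plain deep
    neural networks that predict binary differential-expression calls from
    binary somatic genomic alteration (SGA) profiles under an L1-sparsity
    penalty.  Provides sparsity-versus-error model selection by Euclidean
    distance from the origin, per-gene AUROC/AUPR evaluation with random
    and k-nearest-neighbor baselines, SGA weight-signature similarity
    analysis (neighbor tables, similarity graphs with Louvain communities,
    hierarchical clustering), extraction of thresholded latent causal
    graphs with ancestor-based hidden-node labeling, and a synthetic
    generator of layered SGA-to-expression causal structures for testing
    the whole pipeline at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    ape,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
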