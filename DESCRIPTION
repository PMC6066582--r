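Package: dtlconn
Title: Deep Transfer Learning for Functional Connectome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains stacked sparse autoencoder (SSAE) prototypes on large
    healthy resting-state functional-connectome corpora and transfers them to
    initialize deep neural-network classifiers for small-sample disease
    classification tasks. Provides a scaled conjugate gradient optimizer,
    L2-regularized sparse autoencoders with a KL-divergence sparsity penalty,
    greedy layer-wise stacking, softmax heads with joint fine-tuning, a
    conventionally pretrained deep-network baseline, Pearson functional
    connectivity construction and upper-triangle vectorization, multi-site
    confound harmonization by ordinary-least-squares residualization with
    site-mean adjustment, stratified cross-validated evaluation (accuracy,
    sensitivity, specificity, AUC), weight-product saliency ranking of
    discriminative connections, and a synthetic connectome-cohort generator
    with planted group effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
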