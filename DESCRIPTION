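Package: pcgfusion
Title: Phonocardiogram Denoising, Feature Selection and Fuzzy-Convolutional Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for heart-sound (phonocardiogram, PCG)
    disease classification on synthetic or recorded signals. Provides a
    parametric generator of cyclic S1/S2 heart sounds with disease-specific
    murmur bands, ensemble empirical mode decomposition with an adaptive
    least-mean-squares noise-cancellation stage for denoising, SMOTE class
    rebalancing, a soft-margin hyperplane "impact rate" feature score, particle
    swarm feature selection driven by learning-vector-quantization fitness with
    information-gain-weighted distances, a Sugeno fuzzy inference system fused
    into a small one-dimensional separable-convolution network, and
    cross-validated evaluation (precision, recall, F1, accuracy, Cohen's kappa,
    polygon area metric).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    purrr,
    rlang,
    readr,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    class,
    optparse
Config/testthat/edition: 3
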