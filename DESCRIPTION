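Package: trfpid
Title: Temporal Response Functions, Gaussian-Copula Information Theory and
    Partial Information Decomposition for Continuous Neural Responses
Version: 0.1.0
Authors@R:
    person("trfpid", "developers", email = "trfpid@example.org",
           role = c("aut", "cre"))
Description: Encoding-model comparison machinery for continuous neural
    responses to naturalistic speech. Builds acoustic and phoneme-annotation
    feature spaces (log-mel spectrograms, half-wave rectified derivatives,
    2D Gabor modulation filterbanks, Hilbert-envelope spectrograms, phoneme
    onset and articulatory-feature impulse trains), fits multivariate
    temporal response functions by closed-form ridge regression with
    per-subspace lag windows and regularization under nested cross-validation
    with black-box hyperparameter optimization, and compares model
    predictions with Gaussian-copula mutual information and partial
    information decomposition based on common change in surprisal (I_ccs).
    Includes iterative redundancy mapping over leakage-correlated sensor
    grids, phoneme-locked epoching and decoding analyses, hierarchical
    Bayesian performance comparison by Gibbs sampling, and a synthetic-data
    generator with known ground truth so that the entire pipeline is
    testable without neural recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
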