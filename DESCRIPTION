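Package: mipool
Title: Selective Subject Pooling for Subject-Independent Motor-Imagery BCI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and evaluating subject-independent
    motor-imagery brain-computer interface (BCI) decoders with selective
    subject pooling. Implements common spatial pattern (CSP) filtering via
    the generalized eigenproblem on class covariances, multi-resolution
    filter-bank CSP with mutual-information feature selection, linear
    discriminant analysis with analytic covariance shrinkage, chance-level
    confidence limits used as statistical pooling thresholds, and
    subject-specific, leave-one-subject-out and cross-dataset evaluation
    protocols. Ships a synthetic multi-subject EEG generator with
    controllable contralateral event-related desynchronization so that the
    full pipeline is testable without downloading public datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'chance.R'
    'csp.R'
    'epochs.R'
    'lda.R'
    'fbcsp.R'
    'pipeline.R'
    'eval.R'
    'io.R'
    'mipool-package.R'
    'preprocess.R'
    'synthetic.R'
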