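#' @include fbcsp.R lda.R
NULL

#' Evaluation configuration
#'
#' Bundles the tunable parameters of the decoding pipeline: the feature
#' extractor, broad band and analysis window, the number of CSP filter
#' pairs for subject-specific (m = 2) and subject-independent (m = 3)
#' training, and the MIBIFS pair count for filter-bank CSP.
#'
#' @param feature "csp" (broad-band CSP) or "fbcsp" (15-band filter bank
#'   with MIBIFS).
#' @param band broad band for plain CSP; default 8-30 Hz.
#' @param window analysis window \code{c(start, stop)} in seconds after
#'   stimulus onset; default 1.0-3.5 s.
#' @param mPairsSS CSP filter pairs for subject-specific training.
#' @param mPairsSI CSP filter pairs for pooled (subject-independent)
#'   training.
#' @param kPairs MIBIFS best feature pairs (6, 10 or 20 in typical use).
#' @param bins mutual-information discretization rule (NULL = default).
#' @param gamma LDA shrinkage: "auto" or a fixed value in [0, 1].
#' @return A named list of class settings used by the evaluation functions.
#' @export
miConfig <- function(feature = c("csp", "fbcsp"), band = bandSpec(8, 30),
                     window = c(1.0, 3.5), mPairsSS = 2L, mPairsSI = 3L,
                     kPairs = 10L, bins = NULL, gamma = "auto") {
  feature <- match.arg(feature)
  list(feature = feature, band = band, window = window,
       mPairsSS = as.integer(mPairsSS), mPairsSI = as.integer(mPairsSI),
       kPairs = as.integer(kPairs), bins = bins, gamma = gamma)
}

configBands <- function(config) {
  if (config$feature == "csp") list(config$band) else makeFilterBank()
}

#' Train a decoding pipeline on epochs
#'
#' Full training path on broadband epochs: band-pass filter, crop to the
#' analysis window, fit the spatial filters (CSP with \code{mPairs} pairs,
#' or filter-bank CSP with MIBIFS), extract log-variance features and fit
#' the shrinkage-LDA classifier.
#'
#' @param e broadband \linkS4class{Epochs} with both classes.
#' @param config a [miConfig()] list.
#' @param mPairs CSP filter pairs; defaults to \code{config$mPairsSS}.
#' @param trainedOn subject ids the epochs came from (kept as an audit
#'   trail).
#' @return An \linkS4class{MIPipeline}.
#' @export
trainPipeline <- function(e, config = miConfig(), mPairs = config$mPairsSS,
                          trainedOn = character(0)) {
  stopifnot(is(e, "Epochs"))
  w <- config$window
  if (config$feature == "csp") {
    eb <- cropEpochs(bandpass(e, config$band), w[1], w[2])
    fset <- selectFilters(fitCSP(eb), mPairs)
    X <- cspFeatures(fset, eb)
    lda <- fitSLDA(X, e@labels, gamma = config$gamma)
    new("MIPipeline", feature = "csp", band = config$band, window = w,
        csp = fset, fbcsp = NULL, lda = lda, montage = e@channels,
        trainedOn = trainedOn)
  } else {
    fb <- fitFBCSP(e, config$kPairs, window = w, bins = config$bins)
    X <- fbcspFeatures(fb, e, window = w)
    lda <- fitSLDA(X, e@labels, gamma = config$gamma)
    new("MIPipeline", feature = "fbcsp", band = config$band, window = w,
        csp = NULL, fbcsp = fb, lda = lda, montage = e@channels,
        trainedOn = trainedOn)
  }
}

#' Predict class labels for new epochs with a trained pipeline
#'
#' @param object an \linkS4class{MIPipeline}.
#' @param newdata broadband \linkS4class{Epochs} on the pipeline's montage.
#' @param ... ignored.
#' @return Integer vector of predicted labels (1 or 2).
#' @export
setMethod("predict", "MIPipeline", function(object, newdata, ...) {
  stopifnot(is(newdata, "Epochs"))
  if (!identical(newdata@channels, object@montage))
    stop("montage mismatch between pipeline and epochs")
  w <- object@window
  X <- if (object@feature == "csp") {
    eb <- cropEpochs(bandpass(newdata, object@band), w[1], w[2])
    cspFeatures(object@csp, eb)
  } else {
    fbcspFeatures(object@fbcsp, newdata, window = w)
  }
  predict(object@lda, X)
})

#' Score a trained pipeline on test epochs
#'
#' @param pipeline an \linkS4class{MIPipeline}.
#' @param e test \linkS4class{Epochs}.
#' @return Classification accuracy in [0, 1].
#' @export
evaluatePipeline <- function(pipeline, e) {
  accuracy(predict(pipeline, e), classLabels(e))
}
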