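#' @include AllGenerics.R
NULL

#' Epochs: one subject's segmented EEG
#'
#' Container for epoched multi-channel EEG of a single subject: a numeric
#' tensor of dimension [T time samples x C channels x N trials] together
#' with binary class labels, the sampling rate, channel names and the epoch
#' start time relative to stimulus onset. Sample k of a trial is located at
#' time \code{t0 + (k-1)/fs} seconds; windows are half-open \code{[start, stop)}.
#'
#' @slot data numeric array [T x C x N], amplitudes in arbitrary units.
#' @slot labels integer vector of length N with values in {1, 2}
#'   (1 = left hand, 2 = right hand motor imagery).
#' @slot fs sampling rate in Hz.
#' @slot channels character vector of C channel names (10-20 system).
#' @slot t0 epoch start relative to stimulus onset, seconds.
#' @export
setClass("Epochs",
  representation(
    data = "array",
    labels = "integer",
    fs = "numeric",
    channels = "character",
    t0 = "numeric"
  )
)

setValidity("Epochs", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3-d array [time x channels x trials]")
  if (d[2] != length(object@channels))
    return("channel dimension does not match length(channels)")
  if (d[3] != length(object@labels))
    return("trial dimension does not match length(labels)")
  if (!all(object@labels %in% c(1L, 2L)))
    return("labels must take values in {1, 2}")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a single positive number")
  if (anyDuplicated(object@channels))
    return("duplicated channel names")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    return("data contains non-finite samples")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    return("t0 must be a single finite number")
  TRUE
})

#' Construct an Epochs object
#'
#' @param data numeric array [T x C x N].
#' @param labels vector of N class identifiers in {1, 2}.
#' @param fs sampling rate, Hz.
#' @param channels character vector of C channel names.
#' @param t0 epoch start relative to stimulus onset, seconds (default 0).
#' @return A validated \linkS4class{Epochs} object.
#' @examples
#' e <- Epochs(array(rnorm(64 * 2 * 4), c(64, 2, 4)),
#'             labels = c(1, 1, 2, 2), fs = 128, channels = c("C3", "C4"))
#' nTrials(e)
#' @export
Epochs <- function(data, labels, fs, channels, t0 = 0) {
  new("Epochs", data = data, labels = as.integer(labels), fs = as.numeric(fs),
      channels = as.character(channels), t0 = as.numeric(t0))
}

#' MultiSubjectDataset: a named collection of subjects' train/test epochs
#'
#' All subjects share the montage, sampling rate and epoch window; each
#' subject carries a train and a test \linkS4class{Epochs} split with
#' identical label sets.
#'
#' @slot subjects named list; each element is \code{list(train = Epochs,
#'   test = Epochs)}. Names are subject ids, kept in lexicographic order.
#' @slot name dataset label.
#' @slot montage ordered channel list shared by all subjects.
#' @export
setClass("MultiSubjectDataset",
  representation(
    subjects = "list",
    name = "character",
    montage = "character"
  )
)

setValidity("MultiSubjectDataset", function(object) {
  subs <- object@subjects
  if (length(subs) == 0L) return("dataset contains no subjects")
  ids <- names(subs)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids))
    return("subjects must have unique non-empty ids")
  if (!identical(ids, sort(ids)))
    return("subject ids must be in lexicographic order")
  for (id in ids) {
    s <- subs[[id]]
    if (!is.list(s) || !all(c("train", "test") %in% names(s)))
      return(sprintf("subject '%s' lacks train/test splits", id))
    for (split in c("train", "test")) {
      e <- s[[split]]
      if (!is(e, "Epochs"))
        return(sprintf("subject '%s' %s split is not an Epochs object", id, split))
      if (!identical(e@channels, object@montage))
        return(sprintf("subject '%s' %s split montage differs from dataset montage", id, split))
      if (length(unique(e@labels)) != 2L)
        return(sprintf("subject '%s' %s split must contain both classes", id, split))
    }
    tr <- s$train; te <- s$test
    if (!isTRUE(all.equal(tr@fs, te@fs)) || !isTRUE(all.equal(tr@t0, te@t0)) ||
        dim(tr@data)[1] != dim(te@data)[1])
      return(sprintf("subject '%s' train/test splits disagree on fs/t0/window", id))
    if (!setequal(tr@labels, te@labels))
      return(sprintf("subject '%s' train and test label sets differ", id))
  }
  e1 <- subs[[1L]]$train
  for (id in ids) {
    e <- subs[[id]]$train
    if (!isTRUE(all.equal(e@fs, e1@fs)) || !isTRUE(all.equal(e@t0, e1@t0)) ||
        dim(e@data)[1] != dim(e1@data)[1])
      return("subjects disagree on fs/t0/epoch window")
  }
  TRUE
})

#' Construct a MultiSubjectDataset
#'
#' @param subjects named list of \code{list(train = Epochs, test = Epochs)}
#'   per subject id; reordered lexicographically by id.
#' @param name dataset label.
#' @param montage shared channel list; defaults to the first subject's.
#' @return A validated \linkS4class{MultiSubjectDataset}.
#' @export
multiSubjectDataset <- function(subjects, name = "dataset", montage = NULL) {
  if (length(subjects) == 0L) stop("dataset contains no subjects")
  subjects <- subjects[order(names(subjects))]
  if (is.null(montage)) montage <- subjects[[1L]]$train@channels
  new("MultiSubjectDataset", subjects = subjects, name = name,
      montage = as.character(montage))
}

#' BandSpec: a band-pass frequency band
#'
#' @slot low lower cutoff, Hz.
#' @slot high upper cutoff, Hz.
#' @slot name band label.
#' @export
setClass("BandSpec",
  representation(low = "numeric", high = "numeric", name = "character")
)

setValidity("BandSpec", function(object) {
  if (!(object@low > 0 && object@high > object@low))
    return("need 0 < low < high")
  TRUE
})

#' Construct a BandSpec
#'
#' @param low,high cutoff frequencies in Hz, 0 < low < high.
#' @param name optional label; defaults to "low-high".
#' @return A \linkS4class{BandSpec}.
#' @export
bandSpec <- function(low, high, name = sprintf("%g-%g", low, high)) {
  new("BandSpec", low = as.numeric(low), high = as.numeric(high), name = name)
}

#' CSPModel: common spatial pattern decomposition
#'
#' Solution of the generalized eigenproblem on the two class covariances
#' \eqn{\Sigma_1 w = \lambda (\Sigma_1 + \Sigma_2) w}, normalized so that
#' \eqn{W^T (\Sigma_1 + \Sigma_2) W = I} and \eqn{W^T \Sigma_1 W = diag(d)}
#' with d descending in [0, 1].
#'
#' @slot W projection matrix [C x C]; columns are spatial filters.
#' @slot d relative class-1 variances, descending, in [0, 1].
#' @slot patterns inverse-transpose of W; columns are the corresponding
#'   activation patterns for topographic export.
#' @slot channels montage the model was fitted on.
#' @slot classOrder integer(2): which label maximizes the first filter.
#' @export
setClass("CSPModel",
  representation(W = "matrix", d = "numeric", patterns = "matrix",
                 channels = "character", classOrder = "integer")
)

setValidity("CSPModel", function(object) {
  C <- ncol(object@W)
  if (nrow(object@W) != C) return("W must be square")
  if (length(object@d) != C) return("length(d) != ncol(W)")
  if (is.unsorted(rev(object@d))) return("d must be sorted descending")
  if (any(object@d < -1e-8 | object@d > 1 + 1e-8))
    return("d must lie in [0, 1]")
  TRUE
})

#' SpatialFilterSet: a selected subset of CSP filters
#'
#' The first m and last m columns of a parent CSP projection matrix.
#'
#' @slot filters matrix [C x 2m].
#' @slot m number of filter pairs.
#' @slot channels montage the filters apply to.
#' @export
setClass("SpatialFilterSet",
  representation(filters = "matrix", m = "integer", channels = "character")
)

setValidity("SpatialFilterSet", function(object) {
  if (ncol(object@filters) != 2L * object@m)
    return("filters must have 2m columns")
  TRUE
})

#' FBCSPModel: filter-bank CSP with mutual-information feature selection
#'
#' Per-band CSP filter sets (m = 2 pairs per band) over the 15-band
#' multi-resolution filter bank, with the feature indices retained by
#' mutual-information best-individual-feature selection (MIBIFS).
#'
#' @slot bands list of \linkS4class{BandSpec}.
#' @slot filters list of \linkS4class{SpatialFilterSet}, one per band.
#' @slot selected integer indices into the concatenated feature vector
#'   (width 4 x number of bands) retained after MIBIFS + pair closure.
#' @slot kPairs number of best feature pairs requested.
#' @slot mi mutual information (bits) of each candidate feature.
#' @export
setClass("FBCSPModel",
  representation(bands = "list", filters = "list", selected = "integer",
                 kPairs = "integer", mi = "numeric")
)

setValidity("FBCSPModel", function(object) {
  if (length(object@bands) != length(object@filters))
    return("one filter set per band required")
  if (anyDuplicated(object@selected)) return("selected indices must be unique")
  F <- 4L * length(object@bands)
  if (any(object@selected < 1L | object@selected > F))
    return("selected indices out of range")
  TRUE
})

#' LDAModel: shrinkage-regularized linear discriminant
#'
#' Binary LDA on a pooled within-class covariance shrunk toward nu*I
#' (nu = trace/F) with analytically selected intensity gamma.
#'
#' @slot w weight vector [F].
#' @slot b bias; decision score is w.x + b, boundary at the midpoint of
#'   the projected class means.
#' @slot gamma shrinkage coefficient in [0, 1].
#' @slot classOrder integer(2): c(label on the negative side, label on the
#'   positive side); scores of exactly 0 go to the first.
#' @export
setClass("LDAModel",
  representation(w = "numeric", b = "numeric", gamma = "numeric",
                 classOrder = "integer")
)

setValidity("LDAModel", function(object) {
  if (object@gamma < 0 || object@gamma > 1) return("gamma must be in [0, 1]")
  if (any(!is.finite(object@w)) || !is.finite(object@b))
    return("non-finite coefficients")
  TRUE
})

#' SubjectPool: the selective subject pool
#'
#' Subjects whose subject-specific accuracy strictly exceeds the upper
#' chance-level confidence limit for the given trial count and significance.
#'
#' @slot memberIds ordered character vector of pooled subject ids.
#' @slot threshold the pooling threshold (upper chance limit).
#' @slot alpha significance level used.
#' @slot n number of test trials the threshold was computed for.
#' @export
setClass("SubjectPool",
  representation(memberIds = "character", threshold = "numeric",
                 alpha = "numeric", n = "integer")
)

#' EvalTable: per-subject accuracies under a named evaluation strategy
#'
#' @slot strategy one of "SS", "SI-All", "SI-alpha", "CROSS-All",
#'   "CROSS-alpha".
#' @slot perSubject named numeric vector, subject id -> accuracy; NA marks a
#'   fold whose effective pool was empty.
#' @slot mean arithmetic mean of the non-missing per-subject accuracies.
#' @slot config snapshot of the evaluation configuration (feature method,
#'   filter pairs, alpha, seeds, pool membership, audit log).
#' @export
setClass("EvalTable",
  representation(strategy = "character", perSubject = "numeric",
                 mean = "numeric", config = "list")
)

setValidity("EvalTable", function(object) {
  v <- object@perSubject[!is.na(object@perSubject)]
  if (length(v) && abs(object@mean - mean(v)) > 1e-12)
    return("stored mean does not equal the mean of per-subject accuracies")
  if (length(v) && (any(v < 0) || any(v > 1)))
    return("accuracies must lie in [0, 1]")
  TRUE
})

#' MIPipeline: a trained spatial-filter + classifier pipeline
#'
#' Bundles the preprocessing configuration, the fitted spatial filters
#' (plain CSP or filter-bank CSP) and the shrinkage-LDA classifier, plus an
#' audit trail of the subjects whose trials were used for training.
#'
#' @slot feature "csp" or "fbcsp".
#' @slot band broad band used for plain CSP (\linkS4class{BandSpec}).
#' @slot window numeric(2), analysis window [start, stop) in seconds.
#' @slot csp \linkS4class{SpatialFilterSet} (feature == "csp").
#' @slot fbcsp \linkS4class{FBCSPModel} (feature == "fbcsp").
#' @slot lda \linkS4class{LDAModel}.
#' @slot montage channels the pipeline expects, in order.
#' @slot trainedOn subject ids whose trials entered training (audit).
#' @export
setClass("MIPipeline",
  representation(feature = "character", band = "BandSpec", window = "numeric",
                 csp = "ANY", fbcsp = "ANY", lda = "LDAModel",
                 montage = "character", trainedOn = "character")
)
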