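#' @include AllClasses.R
NULL

#' @describeIn Epochs number of trials N.
#' @param x an \linkS4class{Epochs} object.
#' @export
setMethod("nTrials", "Epochs", function(x) dim(x@data)[3])

#' @describeIn Epochs number of channels C.
#' @export
setMethod("nChannels", "Epochs", function(x) dim(x@data)[2])

#' @describeIn Epochs number of time samples per trial T.
#' @export
setMethod("nSamples", "Epochs", function(x) dim(x@data)[1])

#' @describeIn Epochs sampling rate in Hz.
#' @export
setMethod("samplingRate", "Epochs", function(x) x@fs)

#' @describeIn Epochs channel names.
#' @export
setMethod("channelNames", "Epochs", function(x) x@channels)

#' @describeIn Epochs integer class labels, one per trial.
#' @export
setMethod("classLabels", "Epochs", function(x) x@labels)

setMethod("show", "Epochs", function(object) {
  cnt <- table(factor(object@labels, levels = c(1L, 2L)))
  cat(sprintf("Epochs: %d samples x %d channels x %d trials\n",
              nSamples(object), nChannels(object), nTrials(object)))
  cat(sprintf("  fs: %g Hz | window: [%.3f, %.3f) s | classes: %d/%d (left/right)\n",
              object@fs, object@t0, object@t0 + nSamples(object) / object@fs,
              cnt[1], cnt[2]))
  cat("  channels:", paste(utils::head(object@channels, 8), collapse = " "),
      if (nChannels(object) > 8) "..." else "", "\n")
})

#' @describeIn Epochs keep and reorder channels to exactly \code{names}.
#' @param names ordered channel list to keep.
#' @export
setMethod("selectChannels", "Epochs", function(x, names) {
  missing <- setdiff(names, x@channels)
  if (length(missing))
    stop("channels not in montage: ", paste(missing, collapse = ", "))
  idx <- match(names, x@channels)
  Epochs(x@data[, idx, , drop = FALSE], x@labels, x@fs,
         x@channels[idx], x@t0)
})

#' @describeIn MultiSubjectDataset apply the channel selection to every
#'   subject and to the montage.
#' @param x a \linkS4class{MultiSubjectDataset}.
#' @param names ordered channel list to keep.
#' @export
setMethod("selectChannels", "MultiSubjectDataset", function(x, names) {
  subs <- lapply(x@subjects, function(s)
    list(train = selectChannels(s$train, names),
         test = selectChannels(s$test, names)))
  multiSubjectDataset(subs, name = x@name, montage = names)
})

#' @describeIn MultiSubjectDataset subject ids in lexicographic order.
#' @export
setMethod("subjectIds", "MultiSubjectDataset", function(x) names(x@subjects))

#' @describeIn MultiSubjectDataset number of subjects.
#' @export
setMethod("length", "MultiSubjectDataset", function(x) length(x@subjects))

#' Extract one subject's train/test splits
#'
#' @param d a \linkS4class{MultiSubjectDataset}.
#' @param id subject identifier.
#' @return \code{list(train = Epochs, test = Epochs)}.
#' @export
getSubject <- function(d, id) {
  if (!id %in% names(d@subjects)) stop("unknown subject id: ", id)
  d@subjects[[id]]
}

setMethod("show", "MultiSubjectDataset", function(object) {
  e <- object@subjects[[1L]]$train
  cat(sprintf("MultiSubjectDataset '%s': %d subjects, %d channels, fs %g Hz\n",
              object@name, length(object@subjects), length(object@montage),
              e@fs))
  cat("  montage:", paste(utils::head(object@montage, 10), collapse = " "),
      if (length(object@montage) > 10) "..." else "", "\n")
})

setMethod("show", "CSPModel", function(object) {
  cat(sprintf("CSPModel: %d channels; relative class-1 variances d:\n",
              ncol(object@W)))
  print(round(object@d, 4))
})

setMethod("show", "FBCSPModel", function(object) {
  cat(sprintf("FBCSPModel: %d bands, %d candidate features, %d selected (k = %d pairs)\n",
              length(object@bands), 4L * length(object@bands),
              length(object@selected), object@kPairs))
})

setMethod("show", "LDAModel", function(object) {
  cat(sprintf("LDAModel: %d features, shrinkage gamma = %.4f\n",
              length(object@w), object@gamma))
})

setMethod("show", "SubjectPool", function(object) {
  cat(sprintf("SubjectPool: %d members (threshold %.4f, alpha %g, n = %d)\n",
              length(object@memberIds), object@threshold, object@alpha,
              object@n))
  if (length(object@memberIds))
    cat("  ", paste(object@memberIds, collapse = " "), "\n")
})

setMethod("show", "EvalTable", function(object) {
  cat(sprintf("EvalTable [%s]: %d subjects, mean accuracy %.4f\n",
              object@strategy, length(object@perSubject), object@mean))
})

setMethod("show", "MIPipeline", function(object) {
  cat(sprintf("MIPipeline: %s features, band %s Hz, window [%g, %g) s\n",
              object@feature, object@band@name, object@window[1],
              object@window[2]))
  cat(sprintf("  trained on %d subject(s): %s\n", length(object@trainedOn),
              paste(utils::head(object@trainedOn, 10), collapse = " ")))
})

#' Convert an EvalTable to a data frame
#'
#' @param x an \linkS4class{EvalTable}.
#' @param ... ignored.
#' @return data.frame with columns subject_id, strategy, accuracy.
#' @export
setMethod("as.data.frame", "EvalTable", function(x, ...) {
  data.frame(subject_id = names(x@perSubject),
             strategy = x@strategy,
             accuracy = unname(x@perSubject),
             stringsAsFactors = FALSE, row.names = NULL)
})

# internal: concatenate trials of several Epochs along the trial axis;
# all inputs must share T, C, fs, channels.
concatEpochs <- function(es) {
  stopifnot(length(es) >= 1L)
  e1 <- es[[1L]]
  dat <- array(0, c(nSamples(e1), nChannels(e1),
                    sum(vapply(es, nTrials, 1L))))
  labs <- integer(0)
  at <- 0L
  for (e in es) {
    if (!identical(e@channels, e1@channels) || nSamples(e) != nSamples(e1))
      stop("epochs to concatenate disagree on montage or window")
    n <- nTrials(e)
    dat[, , at + seq_len(n)] <- e@data
    labs <- c(labs, e@labels)
    at <- at + n
  }
  Epochs(dat, labs, e1@fs, e1@channels, e1@t0)
}
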