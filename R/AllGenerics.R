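#' @include AllGenerics.R
NULL

#' Number of trials in an object
#'
#' @param x an object holding epoched trials.
#' @return Integer trial count.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Number of channels
#'
#' @param x an object with an EEG montage.
#' @return Integer channel count.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of time samples per trial
#'
#' @param x an object holding epoched trials.
#' @return Integer samples-per-trial count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Sampling rate in Hz
#'
#' @param x an object recorded at a fixed rate.
#' @return Sampling rate (Hz).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel names
#'
#' @param x an object with an EEG montage.
#' @return Character vector of channel names (10-20 system).
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Class labels of the trials
#'
#' @param x an object holding labelled trials.
#' @return Integer vector of class identifiers (1 = left hand, 2 = right hand).
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Restrict and reorder the montage
#'
#' @param x an object with channel-indexed data.
#' @param names ordered character vector of channel names to keep.
#' @return Object of the same class with channels reordered to \code{names}.
#' @export
setGeneric("selectChannels", function(x, names) standardGeneric("selectChannels"))

#' Subject identifiers
#'
#' @param x a multi-subject container.
#' @return Character vector of subject ids, lexicographic order.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
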