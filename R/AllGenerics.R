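#' Channel labels of an object
#' @param x a Montage, EpochedData or ContinuousRecording.
#' @return character vector of channel labels in axis order.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "Montage", function(x) x@labels)
#' @rdname channelNames
#' @export
setMethod("channelNames", "EpochedData", function(x) x@channelNames)
#' @rdname channelNames
#' @export
setMethod("channelNames", "ContinuousRecording", function(x) x@channelNames)

#' Number of trials
#' @param x an EpochedData object.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname nTrials
#' @export
setMethod("nTrials", "EpochedData", function(x) dim(x@signal)[1])

#' Number of channels
#' @param x an EpochedData, ContinuousRecording or Montage object.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname nChannels
#' @export
setMethod("nChannels", "EpochedData", function(x) dim(x@signal)[2])
#' @rdname nChannels
#' @export
setMethod("nChannels", "ContinuousRecording", function(x) nrow(x@signal))
#' @rdname nChannels
#' @export
setMethod("nChannels", "Montage", function(x) length(x@labels))

#' Sampling rate in Hz
#' @param x an EpochedData or ContinuousRecording object.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EpochedData", function(x) x@sfreq)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "ContinuousRecording", function(x) x@sfreq)

#' Per-trial class labels
#' @param x an EpochedData object.
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))
#' @rdname trialLabels
#' @export
setMethod("trialLabels", "EpochedData", function(x) x@labels)

#' Hemisphere tag per channel
#' @param x a Montage.
#' @return character vector in \{left, right, midline\}.
#' @export
setGeneric("channelSide", function(x) standardGeneric("channelSide"))
#' @rdname channelSide
#' @export
setMethod("channelSide", "Montage", function(x) {
  stats::setNames(x@side, x@labels)
})

#' Removal order of a reduction trace
#' @param x a ReductionTrace.
#' @export
setGeneric("removalOrder", function(x) standardGeneric("removalOrder"))
#' @rdname removalOrder
#' @export
setMethod("removalOrder", "ReductionTrace", function(x) x@removalOrder)

#' Accuracy at every elimination step
#' @param x a ReductionTrace.
#' @return numeric vector of length C; element k+1 is the held-out accuracy
#'   with k channels removed.
#' @export
setGeneric("accuracyByRemoved", function(x) standardGeneric("accuracyByRemoved"))
#' @rdname accuracyByRemoved
#' @export
setMethod("accuracyByRemoved", "ReductionTrace", function(x) x@accuracyByRemoved)

#' Held-out accuracy of an evaluation
#' @param x an EvalResult or TopSet.
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @rdname accuracy
#' @export
setMethod("accuracy", "EvalResult", function(x) x@accuracy)
#' @rdname accuracy
#' @export
setMethod("accuracy", "TopSet", function(x) x@accuracy)

#' Confusion matrix of an evaluation
#' @param x an EvalResult.
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))
#' @rdname confusion
#' @export
setMethod("confusion", "EvalResult", function(x) x@confusion)

#' Restrict an object to a channel subset
#'
#' @param x an EpochedData or ContinuousRecording object.
#' @param channels labels to keep; order is taken from \code{channels}.
#' @return object of the same class with only the requested channels.
#' @export
setGeneric("selectChannels", function(x, channels) standardGeneric("selectChannels"))

#' @rdname selectChannels
#' @export
setMethod("selectChannels", "EpochedData", function(x, channels) {
  idx <- match(channels, x@channelNames)
  if (anyNA(idx))
    stop("channels not present: ",
         paste(channels[is.na(idx)], collapse = ", "))
  new("EpochedData",
      signal = x@signal[, idx, , drop = FALSE],
      labels = x@labels, sfreq = x@sfreq,
      channelNames = x@channelNames[idx], epochLength = x@epochLength)
})

#' @rdname selectChannels
#' @export
setMethod("selectChannels", "ContinuousRecording", function(x, channels) {
  idx <- match(channels, x@channelNames)
  if (anyNA(idx))
    stop("channels not present: ",
         paste(channels[is.na(idx)], collapse = ", "))
  new("ContinuousRecording",
      signal = x@signal[idx, , drop = FALSE], sfreq = x@sfreq,
      channelNames = x@channelNames[idx], events = x@events)
})
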