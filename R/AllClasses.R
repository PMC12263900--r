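#' @import methods
NULL

#' Montage: a named electrode layout
#'
#' Describes an EEG electrode montage: ordered channel labels from the
#' extended 10-20 system, a hemisphere tag per channel (odd digits left,
#' even digits right, trailing 'z' midline), schematic 2-D head coordinates,
#' and a registry of named anatomical comparison subsets.
#'
#' @slot labels character vector of unique channel labels.
#' @slot side character vector, one of \code{"left"}, \code{"right"},
#'   \code{"midline"} per channel.
#' @slot coords numeric matrix (channels x 2) of schematic x/y head positions.
#' @slot subsets named list of character vectors; each entry is an anatomical
#'   subset of \code{labels}.
#' @seealso [standardMontage()], [anatomicalSubset()]
#' @export
setClass("Montage",
  representation(labels = "character", side = "character",
                 coords = "matrix", subsets = "list"))

setValidity("Montage", function(object) {
  msg <- character()
  if (anyDuplicated(object@labels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@side) != length(object@labels))
    msg <- c(msg, "side tag required for every label")
  if (!all(object@side %in% c("left", "right", "midline")))
    msg <- c(msg, "side tags must be left/right/midline")
  expected <- hemisphereFromLabel(object@labels)
  bad <- which(object@side != expected)
  if (length(bad))
    msg <- c(msg, paste0("side tag inconsistent with 10-20 naming for: ",
                         paste(object@labels[bad], collapse = ", ")))
  if (nrow(object@coords) != length(object@labels) || ncol(object@coords) != 2)
    msg <- c(msg, "coords must be channels x 2")
  for (nm in names(object@subsets)) {
    missing <- setdiff(object@subsets[[nm]], object@labels)
    if (length(missing))
      msg <- c(msg, paste0("subset '", nm, "' contains unknown labels: ",
                           paste(missing, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' EpochedData: trials x channels x samples EEG tensor
#'
#' Epoched multi-channel EEG with one class label per trial. The third array
#' dimension is time; \code{samples == round(epochLength * sfreq)}.
#'
#' @slot signal numeric array, trials x channels x samples (microvolts).
#' @slot labels character vector of per-trial class identifiers.
#' @slot sfreq sampling rate in Hz.
#' @slot channelNames ordered channel labels matching the channel axis.
#' @slot epochLength epoch duration in seconds.
#' @export
setClass("EpochedData",
  representation(signal = "array", labels = "character", sfreq = "numeric",
                 channelNames = "character", epochLength = "numeric"))

setValidity("EpochedData", function(object) {
  msg <- character()
  d <- dim(object@signal)
  if (length(d) != 3)
    return("signal must be a 3-d array (trials x channels x samples)")
  if (length(object@labels) != d[1])
    msg <- c(msg, "one label per trial required")
  if (length(object@channelNames) != d[2])
    msg <- c(msg, "channelNames must match the channel axis")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channelNames must be unique")
  if (d[3] != round(object@epochLength * object@sfreq))
    msg <- c(msg, "samples must equal round(epochLength * sfreq)")
  if (d[1] > 0) {
    tab <- table(object@labels)
    if (length(tab) > 0 && any(tab < 2))
      msg <- c(msg, "every class needs at least 2 trials")
  }
  if (length(msg)) msg else TRUE
})

#' ContinuousRecording: unsegmented multi-channel EEG
#'
#' @slot signal numeric matrix, channels x samples (microvolts).
#' @slot sfreq sampling rate in Hz; must exceed 120 Hz so that the 60 Hz
#'   band edge stays below Nyquist.
#' @slot channelNames ordered channel labels.
#' @slot events data.frame with columns \code{sample} (1-based sample index)
#'   and \code{label} (class identifier).
#' @export
setClass("ContinuousRecording",
  representation(signal = "matrix", sfreq = "numeric",
                 channelNames = "character", events = "data.frame"))

setValidity("ContinuousRecording", function(object) {
  msg <- character()
  if (nrow(object@signal) != length(object@channelNames))
    msg <- c(msg, "channelNames must match signal rows")
  if (object@sfreq <= 120)
    msg <- c(msg, "sfreq must exceed 120 Hz (Nyquist above the 60 Hz band edge)")
  if (!all(c("sample", "label") %in% names(object@events)))
    msg <- c(msg, "events needs 'sample' and 'label' columns")
  else if (nrow(object@events) &&
           (any(object@events$sample < 1) ||
            any(object@events$sample > ncol(object@signal))))
    msg <- c(msg, "event sample indices must lie within the recording")
  if (length(msg)) msg else TRUE
})

#' SplitSpec: a frozen train/test split
#'
#' Trial indices are fixed once per subject and reused at every elimination
#' step, so the reduction loop never re-randomizes its evaluation data.
#'
#' @slot trainIdx,testIdx integer trial indices; disjoint, jointly covering
#'   all trials.
#' @slot seed integer seed the split was drawn from (NA for predefined splits).
#' @export
setClass("SplitSpec",
  representation(trainIdx = "integer", testIdx = "integer", seed = "integer"))

setValidity("SplitSpec", function(object) {
  if (length(intersect(object@trainIdx, object@testIdx)))
    return("train and test indices must be disjoint")
  if (length(object@trainIdx) < 1 || length(object@testIdx) < 1)
    return("both partitions must be non-empty")
  TRUE
})

#' ReductionTrace: one full elimination run
#'
#' @slot comboId character identifier "feature+classifier+reducer".
#' @slot channels starting channel set (montage order).
#' @slot removalOrder channel labels in removal order, length C-1.
#' @slot accuracyByRemoved numeric vector of length C; element k+1 is the
#'   held-out accuracy with k channels removed.
#' @export
setClass("ReductionTrace",
  representation(comboId = "character", channels = "character",
                 removalOrder = "character", accuracyByRemoved = "numeric"))

setValidity("ReductionTrace", function(object) {
  msg <- character()
  C <- length(object@channels)
  if (anyDuplicated(object@removalOrder))
    msg <- c(msg, "removalOrder must not repeat channels")
  if (length(object@removalOrder) != C - 1)
    msg <- c(msg, "removalOrder must have C-1 entries")
  if (!all(object@removalOrder %in% object@channels))
    msg <- c(msg, "removalOrder must stay within the starting channel set")
  if (length(object@accuracyByRemoved) != C)
    msg <- c(msg, "accuracyByRemoved must have C entries")
  if (any(object@accuracyByRemoved < 0 | object@accuracyByRemoved > 1))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' TopSet: the FIS-selected operating point of one trace
#'
#' @slot subject subject identifier.
#' @slot comboId combination identifier of the originating trace.
#' @slot nRemoved number of electrodes removed at the operating point.
#' @slot kept surviving channel labels.
#' @slot accuracy held-out accuracy at the operating point.
#' @slot fisScore fuzzy-inference score in [0, 1].
#' @export
setClass("TopSet",
  representation(subject = "character", comboId = "character",
                 nRemoved = "integer", kept = "character",
                 accuracy = "numeric", fisScore = "numeric"))

#' EvalResult: accuracy plus confusion counts of one train/test run
#'
#' @slot accuracy proportion of correct test classifications.
#' @slot confusion integer matrix, true class x predicted class.
#' @slot nTest number of test trials.
#' @export
setClass("EvalResult",
  representation(accuracy = "numeric", confusion = "matrix", nTest = "integer"))

setValidity("EvalResult", function(object) {
  correct <- sum(diag(object@confusion))
  if (object@nTest > 0 &&
      abs(object@accuracy - correct / object@nTest) > 1e-12)
    return("accuracy must equal trace(confusion)/nTest")
  TRUE
})

#' SynthGroundTruth: generator parameters behind a synthetic dataset
#'
#' @slot informativeChannels channels carrying class-discriminative sources.
#' @slot classFreqs named numeric vector: per-class source center frequency (Hz).
#' @slot channelGains numeric matrix (class x informative channel) of mixing
#'   gains: each class's source is expressed primarily on its own informative
#'   channel, with a weaker secondary projection on a neighbour.
#' @slot snr linear source-to-noise amplitude ratio used.
#' @slot seed integer seed of the generating stream.
#' @export
setClass("SynthGroundTruth",
  representation(informativeChannels = "character", classFreqs = "numeric",
                 channelGains = "matrix", snr = "numeric", seed = "integer"))

setMethod("show", "Montage", function(object) {
  cat("Montage with", length(object@labels), "channels (",
      sum(object@side == "left"), "left /", sum(object@side == "right"),
      "right /", sum(object@side == "midline"), "midline )\n")
  cat("subsets:", paste(names(object@subsets), collapse = ", "), "\n")
})

setMethod("show", "EpochedData", function(object) {
  d <- dim(object@signal)
  cat(sprintf("EpochedData: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@sfreq))
  if (d[1] > 0) {
    tab <- table(object@labels)
    cat("classes:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
        "\n")
  }
})

setMethod("show", "ContinuousRecording", function(object) {
  cat(sprintf("ContinuousRecording: %d channels x %d samples @ %g Hz, %d events\n",
              nrow(object@signal), ncol(object@signal), object@sfreq,
              nrow(object@events)))
})

setMethod("show", "ReductionTrace", function(object) {
  cat(sprintf("ReductionTrace [%s]: %d -> 1 channels, peak accuracy %.3f (%d removed)\n",
              object@comboId, length(object@channels),
              max(object@accuracyByRemoved),
              which.max(object@accuracyByRemoved) - 1L))
})

setMethod("show", "TopSet", function(object) {
  cat(sprintf("TopSet [%s/%s]: accuracy %.3f with %d removed (%d kept), FIS %.3f\n",
              object@subject, object@comboId, object@accuracy,
              object@nRemoved, length(object@kept), object@fisScore))
})
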