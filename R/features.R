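#' FeatureSpec: one of the five feature configurations
#'
#' \describe{
#'   \item{wav}{per-channel wavelet feature vector (raw-series max/min/mean/sd
#'     plus relative wavelet energy of a bior2.2 decomposition).}
#'   \item{featvec}{per-channel time/frequency feature vector
#'     ([featvecChannelFeatures()]).}
#'   \item{csp}{log-variance of CSP source signals.}
#'   \item{cspwav}{wavelet feature vector of each CSP source signal.}
#'   \item{cspfv}{time/frequency feature vector of each CSP source signal.}
#' }
#'
#' @slot kind one of wav, featvec, csp, cspwav, cspfv.
#' @slot wavelet mother wavelet name (bior2.2 is the implemented bank).
#' @slot levels wavelet decomposition depth.
#' @slot nCspComponents number of CSP spatial filters (even).
#' @slot bandEdges named list of band edges for the featvec bands.
#' @export
setClass("FeatureSpec",
  representation(kind = "character", wavelet = "character",
                 levels = "integer", nCspComponents = "integer",
                 bandEdges = "list"))

setValidity("FeatureSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("wav", "featvec", "csp", "cspwav", "cspfv"))
    msg <- c(msg, "kind must be one of wav/featvec/csp/cspwav/cspfv")
  if (object@wavelet != "bior2.2")
    msg <- c(msg, "only the bior2.2 analysis bank is implemented")
  if (object@levels < 1) msg <- c(msg, "levels must be >= 1")
  if (object@nCspComponents %% 2 != 0)
    msg <- c(msg, "nCspComponents must be even")
  edges <- unlist(object@bandEdges)
  if (any(diff(vapply(object@bandEdges, function(b) b[1], numeric(1))) <= 0))
    msg <- c(msg, "band edges must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Build a FeatureSpec
#' @param kind feature configuration name.
#' @param wavelet mother wavelet (default \code{"bior2.2"}).
#' @param levels decomposition depth (default 4).
#' @param nCspComponents CSP filter count (default 4, even).
#' @param bandEdges band edges for featvec features.
#' @return a [FeatureSpec].
#' @export
featureSpec <- function(kind, wavelet = "bior2.2", levels = 4,
                        nCspComponents = 4, bandEdges = defaultBandEdges()) {
  new("FeatureSpec", kind = kind, wavelet = wavelet,
      levels = as.integer(levels), nCspComponents = as.integer(nCspComponents),
      bandEdges = bandEdges)
}

#' FeatureMatrix: trials x features with column provenance
#'
#' @slot values numeric matrix, trials x features; finite values only.
#' @slot blockMap data.frame with columns \code{column}, \code{source}
#'   (channel label or \code{"csp<k>"}) and \code{family}.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", blockMap = "data.frame"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!all(is.finite(object@values)))
    msg <- c(msg, "feature values must be finite")
  if (nrow(object@blockMap) != ncol(object@values))
    msg <- c(msg, "blockMap must cover every column")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d trials x %d features (%d sources)\n",
              nrow(object@values), ncol(object@values),
              length(unique(object@blockMap$source))))
})

#' Extract the numeric matrix / block map of a FeatureMatrix
#' @param x a [FeatureMatrix].
#' @export
featureValues <- function(x) x@values

#' @rdname featureValues
#' @export
blockMap <- function(x) x@blockMap

#' Fit the trainable state of a feature configuration
#'
#' CSP-based kinds fit spatial filters on the training epochs; wav/featvec
#' only record the channel set. The fitted state is bound to the exact
#' channel set it was fitted on.
#'
#' @param spec a [FeatureSpec].
#' @param train training [EpochedData].
#' @return a FeatureFit list (spec, channels, sfreq, csp).
#' @export
fitFeatures <- function(spec, train) {
  stopifnot(is(spec, "FeatureSpec"), is(train, "EpochedData"))
  validObject(spec)
  csp <- NULL
  if (spec@kind %in% c("csp", "cspwav", "cspfv"))
    csp <- fitCSP(train, nComponents = min(spec@nCspComponents,
                                           nChannels(train)))
  structure(list(spec = spec, channels = channelNames(train),
                 sfreq = samplingRate(train), csp = csp),
            class = "FeatureFit")
}

sourceSignals <- function(fit, epochs) {
  W <- fit$csp$filters
  n <- nTrials(epochs)
  out <- array(0, dim = c(n, nrow(W), dim(epochs@signal)[3]))
  for (tr in seq_len(n))
    out[tr, , ] <- W %*% epochs@signal[tr, , ]
  out
}

#' Transform epochs into a feature matrix
#'
#' wav/featvec concatenate per-channel feature vectors in channel order;
#' csp returns the log-variance of each CSP source signal; cspwav/cspfv pass
#' each CSP source signal through the respective per-channel extractor.
#' Deterministic given (spec, fitted state, epochs).
#'
#' @param fit a FeatureFit from [fitFeatures()].
#' @param epochs an [EpochedData] with exactly the channel set of the fit.
#' @return a [FeatureMatrix].
#' @export
transformFeatures <- function(fit, epochs) {
  stopifnot(inherits(fit, "FeatureFit"), is(epochs, "EpochedData"))
  if (!identical(fit$channels, channelNames(epochs)))
    stop("channel set differs between fit and transform")
  spec <- fit$spec
  kind <- spec@kind
  n <- nTrials(epochs)
  perSeries <- function(x) {
    switch(kind,
      wav = , cspwav = dwtChannelFeatures(x, levels = spec@levels),
      featvec = , cspfv = featvecChannelFeatures(x, fit$sfreq,
                                                 spec@bandEdges))
  }
  if (kind %in% c("wav", "featvec")) {
    sources <- channelNames(epochs)
    getSeries <- function(tr, j) epochs@signal[tr, j, ]
  } else {
    src <- sourceSignals(fit, epochs)
    sources <- paste0("csp", seq_len(dim(src)[2]))
    getSeries <- function(tr, j) src[tr, j, ]
  }
  if (kind == "csp") {
    vals <- matrix(0, n, length(sources))
    for (tr in seq_len(n))
      vals[tr, ] <- vapply(seq_along(sources),
                           function(j) log(stats::var(getSeries(tr, j))),
                           numeric(1))
    fam <- rep("logvar", length(sources))
    colnames(vals) <- paste0(sources, ".logvar")
    bm <- data.frame(column = colnames(vals), source = sources, family = fam,
                     stringsAsFactors = FALSE)
  } else {
    proto <- perSeries(getSeries(1, 1))
    vals <- matrix(0, n, length(sources) * length(proto))
    for (tr in seq_len(n)) {
      row <- unlist(lapply(seq_along(sources),
                           function(j) perSeries(getSeries(tr, j))))
      vals[tr, ] <- row
    }
    colnames(vals) <- as.vector(vapply(sources, function(s)
      paste0(s, ".", names(proto)), character(length(proto))))
    bm <- data.frame(column = colnames(vals),
                     source = rep(sources, each = length(proto)),
                     family = rep(names(proto), times = length(sources)),
                     stringsAsFactors = FALSE)
  }
  if (n == 0) vals <- matrix(numeric(0), 0, nrow(bm),
                             dimnames = list(NULL, bm$column))
  new("FeatureMatrix", values = vals, blockMap = bm)
}

#' Write a FeatureMatrix to CSV
#'
#' First header row carries the block map (\code{source:family}) and the
#' remaining rows the values.
#' @param x a [FeatureMatrix].
#' @param path output file.
#' @export
writeFeatureCSV <- function(x, path) {
  df <- as.data.frame(x@values)
  names(df) <- paste0(x@blockMap$source, ":", x@blockMap$family)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
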