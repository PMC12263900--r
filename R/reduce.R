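#' ReducerSpec: one of the four electrode-reduction algorithms
#'
#' \describe{
#'   \item{gwo}{greedy wrapper backward elimination: at every round each
#'     surviving electrode is left out in turn, the full downstream pipeline
#'     (feature fit/transform + classifier train/eval) is re-run, and the
#'     electrode whose exclusion yields the highest held-out accuracy is
#'     rejected. Ties remove the candidate earliest in montage order.}
#'   \item{csp_rank}{multiclass CSP filter matrix; the two most
#'     class-informative filter vectors are extracted and the channel with
#'     the smallest summed absolute coefficient across those two vectors is
#'     rejected.}
#'   \item{ocsp_rank}{one-vs-all CSP: extreme eigenvectors of every
#'     class-vs-rest fit are pooled; channels are selected by repeated global
#'     argmax of absolute pooled coefficients (masking each selected channel)
#'     until one channel is left unselected, which is rejected.}
#'   \item{ica_score}{FastICA on the training epochs; each component votes for
#'     the channel holding its maximum loading, with weight 2 if the component
#'     is among the 13\% largest (by back-projection norm), else 1; the
#'     lowest-scoring channel is rejected (ties remove the channel latest in
#'     montage order).}
#' }
#'
#' @slot kind one of gwo, csp_rank, ocsp_rank, ica_score.
#' @slot icaLFraction fraction of components forming the high-weight set L
#'   (default 0.13).
#' @export
setClass("ReducerSpec",
  representation(kind = "character", icaLFraction = "numeric"))

setValidity("ReducerSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("gwo", "csp_rank", "ocsp_rank", "ica_score"))
    msg <- c(msg, "kind must be one of gwo/csp_rank/ocsp_rank/ica_score")
  if (object@icaLFraction <= 0 || object@icaLFraction >= 1)
    msg <- c(msg, "icaLFraction must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Build a ReducerSpec
#' @param kind reducer name.
#' @param icaLFraction high-weight component fraction for \code{ica_score}.
#' @return a [ReducerSpec].
#' @export
reducerSpec <- function(kind, icaLFraction = 0.13) {
  new("ReducerSpec", kind = kind, icaLFraction = icaLFraction)
}

# Full downstream pipeline accuracy on a channel subset under a frozen split.
# For the per-channel feature kinds (wav, featvec) an optional cache
# environment holds the full-montage feature matrix; the channel subset is a
# column subset of it, bit-identical to re-extracting features on the subset
# because those features are computed channel by channel.
pipelineAccuracy <- function(epochs, split, featureSpec, classifierSpec,
                             channels, cache = NULL) {
  if (!is.null(cache) && featureSpec@kind %in% c("wav", "featvec")) {
    key <- featureSpec@kind
    if (is.null(cache[[key]])) {
      fitAll <- fitFeatures(featureSpec, epochs)
      cache[[key]] <- transformFeatures(fitAll, epochs)
    }
    fm <- cache[[key]]
    cols <- unlist(lapply(channels,
                          function(ch) which(fm@blockMap$source == ch)))
    res <- trainEval(classifierSpec,
                     fm@values[split@trainIdx, cols, drop = FALSE],
                     epochs@labels[split@trainIdx],
                     fm@values[split@testIdx, cols, drop = FALSE],
                     epochs@labels[split@testIdx])
    return(accuracy(res))
  }
  sub <- selectChannels(epochs, channels)
  tr <- new("EpochedData",
            signal = sub@signal[split@trainIdx, , , drop = FALSE],
            labels = sub@labels[split@trainIdx], sfreq = sub@sfreq,
            channelNames = sub@channelNames, epochLength = sub@epochLength)
  te <- new("EpochedData",
            signal = sub@signal[split@testIdx, , , drop = FALSE],
            labels = sub@labels[split@testIdx], sfreq = sub@sfreq,
            channelNames = sub@channelNames, epochLength = sub@epochLength)
  fit <- fitFeatures(featureSpec, tr)
  res <- trainEval(classifierSpec,
                   transformFeatures(fit, tr), trialLabels(tr),
                   transformFeatures(fit, te), trialLabels(te))
  accuracy(res)
}

#' One greedy-elimination step
#'
#' Evaluates the full downstream pipeline once per candidate (every surviving
#' channel left out in turn) and removes the candidate whose exclusion gives
#' the highest held-out accuracy. The complete per-candidate accuracy table is
#' returned for audit. Ties remove the candidate earliest in montage order
#' (i.e. first in \code{kept}).
#'
#' @param epochs an [EpochedData] over the current channel superset.
#' @param split frozen [SplitSpec].
#' @param featureSpec a [FeatureSpec].
#' @param classifierSpec a [ClassifierSpec].
#' @param kept surviving channel labels (montage order), length >= 2.
#' @param evaluator optional function(channels) -> accuracy overriding the
#'   default pipeline evaluation (used for stubbing).
#' @return list with \code{removed} (label) and \code{table}
#'   (data.frame channel/accuracy).
#' @export
gwoStep <- function(epochs, split, featureSpec, classifierSpec, kept,
                    evaluator = NULL) {
  if (length(kept) < 2) stop("cannot step with fewer than 2 channels")
  if (is.null(evaluator))
    evaluator <- function(channels)
      pipelineAccuracy(epochs, split, featureSpec, classifierSpec, channels)
  acc <- vapply(seq_along(kept),
                function(i) evaluator(kept[-i]), numeric(1))
  best <- which.max(acc)   # first maximum = earliest in montage order
  list(removed = kept[best],
       table = data.frame(channel = kept, accuracy = acc,
                          stringsAsFactors = FALSE))
}

#' One CSP-rank elimination step
#'
#' Fits multiclass CSP on the training epochs restricted to \code{kept} and
#' extracts the two extreme filter vectors — the most class-informative pair
#' (eigenvalue extremes for two classes, the top two separation-ranked
#' filters otherwise). Absolute coefficients are summed per channel across
#' those two vectors and the channel with the smallest combined magnitude
#' (the electrode least represented in the discriminative filters) is
#' removed. The choice is invariant to positive rescaling of the filter
#' matrix.
#'
#' @inheritParams gwoStep
#' @param filterMatrix optional precomputed, importance-ordered filter
#'   matrix (filters x channels) overriding the CSP fit (used for
#'   stubbing); its first and last rows are taken as the extreme pair.
#' @return removed channel label.
#' @export
cspRankStep <- function(epochs, split, kept, filterMatrix = NULL) {
  if (length(kept) < 2) stop("cannot step with fewer than 2 channels")
  if (is.null(filterMatrix)) {
    tr <- trainEpochs(epochs, split, kept)
    extreme <- fitCSP(tr, nComponents = 2)$extremePair
  } else {
    extreme <- filterMatrix[c(1, nrow(filterMatrix)), , drop = FALSE]
  }
  combined <- colSums(abs(extreme))
  kept[which.min(combined)]   # first minimum = earliest in montage order
}

#' One one-vs-all CSP-rank elimination step
#'
#' For each class fits a two-class CSP of class-vs-rest, takes the
#' eigenvectors with the largest and smallest eigenvalue from each fit, pools
#' them, and iteratively selects the channel holding the globally largest
#' absolute coefficient (masking that channel afterwards) until all but one
#' channel is selected; the unselected channel is removed.
#'
#' @inheritParams cspRankStep
#' @param pooled optional precomputed pooled vector matrix
#'   (vectors x channels) overriding the CSP fits (used for stubbing).
#' @return removed channel label.
#' @export
ocspRankSelect <- function(epochs, split, kept, pooled = NULL) {
  if (length(kept) < 2) stop("cannot step with fewer than 2 channels")
  if (is.null(pooled)) {
    tr <- trainEpochs(epochs, split, kept)
    cc <- classCovariances(tr)
    K <- length(cc$classes)
    nCh <- length(kept)
    pooled <- matrix(0, 0, nCh)
    for (ci in seq_len(K)) {
      Crest <- apply(cc$covs[-ci, , , drop = FALSE], c(2, 3), mean)
      Wi <- cspTwoClass(cc$covs[ci, , ], Crest)$W
      pooled <- rbind(pooled, Wi[c(1, nrow(Wi)), , drop = FALSE])
    }
  }
  A <- abs(pooled)
  selected <- logical(ncol(A))
  for (iter in seq_len(ncol(A) - 1)) {
    masked <- A
    masked[, selected] <- -Inf
    j <- arrayInd(which.max(masked), dim(masked))[2]
    selected[j] <- TRUE
  }
  kept[!selected]
}

#' Per-channel ICA scores
#'
#' Each component votes for the channel holding its maximum coefficient:
#' weight 2 if the component belongs to L (the \code{max(1,
#' round(lFraction * N))} components with the largest row L2 norm, boundary
#' ties broken by component index), weight 1 otherwise; all other channels
#' get 0 from that component. Ties inside a component's maximum go to the
#' lowest channel index. Under unique maxima the scores sum to
#' \code{2|L| + (N - |L|)}.
#'
#' @param components numeric matrix, components (rows) x channels.
#' @param lFraction fraction of components forming L (default 0.13).
#' @return integer vector of per-channel scores.
#' @export
icaChannelScores <- function(components, lFraction = 0.13) {
  if (!is.matrix(components) || nrow(components) < 1 || ncol(components) < 1)
    stop("components must be a non-empty matrix")
  N <- nrow(components)
  norms <- sqrt(rowSums(components^2))
  nL <- max(1L, round(lFraction * N))
  inL <- logical(N)
  inL[order(-norms, seq_len(N))[seq_len(nL)]] <- TRUE
  scores <- integer(ncol(components))
  for (n in seq_len(N)) {
    i <- which.max(components[n, ])   # lowest channel index wins ties
    scores[i] <- scores[i] + if (inL[n]) 2L else 1L
  }
  scores
}

#' One ICA-score elimination step
#'
#' Runs FastICA on the concatenated training epochs restricted to
#' \code{kept}, scores channels with [icaChannelScores()] on the
#' back-projection (mixing) vectors, keeps the highest-scoring
#' \code{|kept| - 1} channels and removes the minimum-score channel; score
#' ties remove the channel latest in montage order. Non-convergence retries
#' once with a fresh seed, then errors.
#'
#' @inheritParams cspRankStep
#' @param lFraction high-weight component fraction.
#' @param seed integer seed for the ICA initialization.
#' @param scores optional precomputed per-channel scores (used for stubbing).
#' @return removed channel label.
#' @export
icaStep <- function(epochs, split, kept, lFraction = 0.13, seed = 1,
                    scores = NULL) {
  if (length(kept) < 2) stop("cannot step with fewer than 2 channels")
  if (is.null(scores)) {
    tr <- trainEpochs(epochs, split, kept)
    X <- matrix(aperm(tr@signal, c(2, 3, 1)), nrow = nChannels(tr))
    fit <- fastICA(X, seed = childSeed(seed, "ica"))
    if (!fit$converged) {
      fit <- fastICA(X, seed = childSeed(seed, "ica-retry"))
      # a Gaussian noise subspace makes the contrast rotation-invariant, so
      # strict convergence can be unattainable; the final iterate still
      # yields a deterministic loading ranking
      if (!fit$converged)
        warning("FastICA did not strictly converge after one retry; ",
                "using the final iterate")
    }
    comps <- t(fit$mixing)              # rows = component loading vectors
    scores <- icaChannelScores(comps, lFraction)
  }
  minScore <- min(scores)
  kept[max(which(scores == minScore))]  # latest in montage order on ties
}

trainEpochs <- function(epochs, split, kept) {
  sub <- selectChannels(epochs, kept)
  new("EpochedData",
      signal = sub@signal[split@trainIdx, , , drop = FALSE],
      labels = sub@labels[split@trainIdx], sfreq = sub@sfreq,
      channelNames = sub@channelNames, epochLength = sub@epochLength)
}

#' Run a full electrode-reduction loop
#'
#' Starting from the full channel set of \code{epochs}, removes one channel
#' per iteration with the requested reducer until a single channel remains
#' (C - 1 iterations). The held-out accuracy of the surviving set is recorded
#' before any removal and after every removal, always under the frozen
#' \code{split}; features are re-fitted on the surviving channels' training
#' trials each time. For the greedy wrapper the winning candidate's accuracy
#' from the elimination table is reused as the post-removal accuracy (it is
#' the identical computation).
#'
#' @inheritParams gwoStep
#' @param reducerSpec a [ReducerSpec].
#' @param seed integer seed (ICA initialization); defaults to the classifier
#'   spec seed.
#' @return a [ReductionTrace].
#' @export
runReduction <- function(epochs, split, featureSpec, classifierSpec,
                         reducerSpec, seed = classifierSpec@seed) {
  stopifnot(is(reducerSpec, "ReducerSpec"))
  validObject(reducerSpec)
  channels <- channelNames(epochs)
  C <- length(channels)
  if (C < 2) stop("need a montage with at least 2 channels")
  comboId <- paste(featureSpec@kind, classifierSpec@kind, reducerSpec@kind,
                   sep = "+")
  cache <- new.env(parent = emptyenv())
  evalAcc <- function(chs)
    pipelineAccuracy(epochs, split, featureSpec, classifierSpec, chs,
                     cache = cache)
  kept <- channels
  removal <- character(0)
  accs <- numeric(C)
  accs[1] <- evalAcc(kept)
  for (k in seq_len(C - 1)) {
    res <- withCallingHandlers(
      switch(reducerSpec@kind,
        gwo = gwoStep(epochs, split, featureSpec, classifierSpec, kept,
                      evaluator = evalAcc),
        csp_rank = list(removed = cspRankStep(epochs, split, kept)),
        ocsp_rank = list(removed = ocspRankSelect(epochs, split, kept)),
        ica_score = list(removed = icaStep(epochs, split, kept,
                                           reducerSpec@icaLFraction,
                                           seed = childSeed(seed, k)))),
      error = function(e)
        stop("reduction failed at iteration ", k, ": ",
             conditionMessage(e), call. = FALSE))
    removed <- res$removed
    kept <- setdiff(kept, removed)
    removal <- c(removal, removed)
    accs[k + 1] <- if (reducerSpec@kind == "gwo")
      res$table$accuracy[res$table$channel == removed]
    else if (length(kept) >= 1) evalAcc(kept) else NA_real_
  }
  new("ReductionTrace", comboId = comboId, channels = channels,
      removalOrder = removal, accuracyByRemoved = accs)
}

#' Serialize / deserialize a ReductionTrace as JSON
#' @param trace a [ReductionTrace].
#' @param path output file.
#' @export
writeTraceJSON <- function(trace, path) {
  jsonlite::write_json(
    list(comboId = trace@comboId, channels = trace@channels,
         removalOrder = trace@removalOrder,
         accuracyByRemoved = trace@accuracyByRemoved),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTraceJSON
#' @export
readTraceJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ReductionTrace", comboId = obj$comboId, channels = obj$channels,
      removalOrder = obj$removalOrder,
      accuracyByRemoved = as.numeric(obj$accuracyByRemoved))
}
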