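#' Electrode occurrence map over top sets
#'
#' For every montage channel, the percentage of top sets whose kept list
#' contains it.
#'
#' @param topSets non-empty list of [TopSet] objects.
#' @param montage the shared [Montage].
#' @return data.frame with columns \code{channel}, \code{percent}, and the
#'   denominator as attribute \code{"denominator"}.
#' @export
electrodeOccurrence <- function(topSets, montage) {
  if (!length(topSets)) stop("need at least one top set")
  labels <- channelNames(montage)
  for (ts in topSets)
    if (!all(ts@kept %in% labels))
      stop("top set contains channels outside the montage: ",
           paste(setdiff(ts@kept, labels), collapse = ", "))
  counts <- vapply(labels, function(ch)
    sum(vapply(topSets, function(ts) ch %in% ts@kept, logical(1))),
    numeric(1))
  out <- data.frame(channel = labels,
                    percent = 100 * counts / length(topSets),
                    stringsAsFactors = FALSE)
  attr(out, "denominator") <- length(topSets)
  out
}

# k-means++ initialization (1-D), deterministic under the local seed.
# Seeds are drawn from the distinct values so initial centers never collide.
kmeansPP <- function(x, k) {
  ux <- unique(x)
  centers <- numeric(k)
  centers[1] <- ux[sample.int(length(ux), 1)]
  if (k > 1) for (j in 2:k) {
    d2 <- vapply(ux, function(v) min((v - centers[seq_len(j - 1)])^2),
                 numeric(1))
    centers[j] <- if (sum(d2) == 0) setdiff(ux, centers[seq_len(j - 1)])[1]
                  else ux[sample.int(length(ux), 1, prob = d2)]
  }
  centers
}

#' Cluster removed-electrode counts with the elbow rule
#'
#' Runs 1-D k-means for k = 1..kMax (k-means++ seeding, 25 restarts, best
#' SSE kept) and picks the elbow as the interior k maximizing the discrete
#' second difference of the log-SSE curve. The log scale makes the rule
#' locate the last large *relative* drop; on raw SSE the first drop always
#' dominates the curvature and the rule would collapse to k = 2. Fewer than
#' 2 distinct values degenerate to k = 1.
#'
#' @param values numeric vector of removed-electrode counts (>= 2 values).
#' @param kMax largest k scanned (default 10).
#' @param seed integer seed for the k-means restarts.
#' @return list with \code{k}, \code{assignments} (cluster id per value,
#'   clusters ordered by center), \code{centers}, \code{sse} (SSE per k).
#' @export
clusterRemovedCounts <- function(values, kMax = 10, seed = 1) {
  if (length(values) < 2) stop("need at least 2 values")
  if (length(unique(values)) < 2) {
    return(list(k = 1L, assignments = rep(1L, length(values)),
                centers = unique(values), sse = rep(0, min(kMax, 1))))
  }
  kMax <- min(kMax, length(unique(values)))
  fits <- vector("list", kMax)
  sse <- numeric(kMax)
  withSeed(seed, {
    for (k in seq_len(kMax)) {
      if (k == 1) {
        fits[[k]] <- list(cluster = rep(1L, length(values)),
                          centers = matrix(mean(values)),
                          tot.withinss = sum((values - mean(values))^2))
        sse[k] <- fits[[k]]$tot.withinss
        next
      }
      best <- NULL
      for (rep in seq_len(25)) {
        fit <- suppressWarnings(
          stats::kmeans(values, centers = matrix(kmeansPP(values, k)),
                        iter.max = 50))
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
      fits[[k]] <- best
      sse[k] <- best$tot.withinss
    }
  })
  k <- if (kMax < 3) kMax else {
    logSse <- log(pmax(sse, 1e-12 * max(sse, 1)))
    d2 <- diff(logSse, differences = 2)   # indexed by interior k = 2..kMax-1
    which.max(d2) + 1L
  }
  fit <- fits[[k]]
  ord <- order(fit$centers)
  remap <- match(seq_len(k), ord)
  list(k = as.integer(k), assignments = remap[fit$cluster],
       centers = sort(as.vector(fit$centers)), sse = sse)
}

#' Benchmark an anatomical electrode subset
#'
#' Restricts the recording to a registered anatomical subset and runs the
#' feature fit/transform + train/eval pipeline for each feature spec under
#' the frozen split, reporting per-feature accuracies and the best one.
#'
#' @param epochs an [EpochedData].
#' @param split frozen [SplitSpec].
#' @param montage the [Montage] carrying the subset registry.
#' @param subsetName registered subset name.
#' @param featureSpecs list of [FeatureSpec] objects.
#' @param classifierSpec a [ClassifierSpec].
#' @return list with \code{accuracies} (named per feature kind),
#'   \code{best} (feature kind), \code{bestAccuracy}, \code{nChannels}.
#' @export
anatomicalBenchmark <- function(epochs, split, montage, subsetName,
                                featureSpecs, classifierSpec) {
  subset <- anatomicalSubset(montage, subsetName)
  missing <- setdiff(subset, channelNames(epochs))
  if (length(missing))
    stop("subset channels missing from the recording: ",
         paste(missing, collapse = ", "))
  acc <- vapply(featureSpecs, function(fs)
    pipelineAccuracy(epochs, split, fs, classifierSpec, subset), numeric(1))
  names(acc) <- vapply(featureSpecs, function(fs) fs@kind, character(1))
  best <- which.max(acc)
  list(accuracies = acc, best = names(acc)[best],
       bestAccuracy = unname(acc[best]), nChannels = length(subset))
}

#' Write an occurrence map as CSV
#' @param map data.frame from [electrodeOccurrence()].
#' @param path output file.
#' @export
writeOccurrenceCSV <- function(map, path) {
  utils::write.csv(map, path, row.names = FALSE)
  invisible(path)
}

#' Topographic occurrence plot
#'
#' Schematic head plot of an occurrence map, with an optional highlight level
#' (default 80 percent).
#'
#' @param map data.frame from [electrodeOccurrence()].
#' @param montage the [Montage] providing head coordinates.
#' @param highlight occurrence percentage highlighted in the plot.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plotOccurrenceMap <- function(map, montage, highlight = 80) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  xy <- montage@coords[map$channel, , drop = FALSE]
  df <- cbind(map, x = xy[, 1], y = xy[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::annotate("path",
                      x = cos(seq(0, 2 * pi, length.out = 200)) * 1.05,
                      y = sin(seq(0, 2 * pi, length.out = 200)) * 1.05) +
    ggplot2::geom_point(ggplot2::aes(color = percent), size = 5) +
    ggplot2::geom_point(data = df[df$percent >= highlight, , drop = FALSE],
                        shape = 1, size = 6, stroke = 1.2) +
    ggplot2::geom_text(ggplot2::aes(label = channel), size = 2,
                       vjust = -1.4) +
    ggplot2::scale_color_gradient(low = "grey85", high = "red",
                                  limits = c(0, 100),
                                  name = "% of top sets") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
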