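# Mamdani fuzzy inference: two inputs (held-out accuracy, bounded above by
# the subject's maximum accuracy; electrodes removed, bounded by C - 1), a
# total rule table, min-conjunction, max-aggregation, centroid
# defuzzification on a fine fixed grid.

trapMembership <- function(x, p) {
  # p = (a, b, c, d): 0 outside [a, d], 1 on [b, c], linear shoulders
  ifelse(x <= p[1] | x >= p[4],
         ifelse((x == p[1] & p[1] == p[2]) | (x == p[4] & p[3] == p[4]), 1, 0),
  ifelse(x < p[2], (x - p[1]) / (p[2] - p[1]),
  ifelse(x <= p[3], 1, (p[4] - x) / (p[4] - p[3]))))
}

#' Build a fuzzy-inference configuration
#'
#' Membership functions are trapezoids given as corner fractions of their
#' domain: accuracy trapezoids live on [0, subjectMax], removal trapezoids on
#' [0, C - 1], output trapezoids on [0, 1]. The default rule table maps high
#' accuracy with many/medium removals to \emph{excellent}, high with few to
#' \emph{good}, medium with many to \emph{good}, medium otherwise to
#' \emph{acceptable}, and low accuracy always to \emph{poor}.
#'
#' @param accuracyShapes named list (low/medium/high) of 4-vectors of
#'   fractions of the accuracy domain.
#' @param removalShapes named list (few/medium/many) of 4-vectors of
#'   fractions of the removal domain.
#' @param outputShapes named list (poor/acceptable/good/excellent) of
#'   4-vectors on [0, 1].
#' @param rules data.frame with columns \code{accuracy}, \code{removal},
#'   \code{output}; must cover all 9 input combinations.
#' @param gridN number of grid points for centroid defuzzification.
#' @return a list of class \code{FISConfig}.
#' @export
fisConfig <- function(
    accuracyShapes = list(low = c(0, 0, 0.5, 0.7),
                          medium = c(0.5, 0.7, 0.8, 0.9),
                          high = c(0.8, 0.9, 1, 1)),
    removalShapes = list(few = c(0, 0, 0.3, 0.5),
                         medium = c(0.3, 0.5, 0.6, 0.8),
                         many = c(0.6, 0.8, 1, 1)),
    outputShapes = list(poor = c(0, 0, 0.2, 0.4),
                        acceptable = c(0.2, 0.4, 0.5, 0.65),
                        good = c(0.5, 0.65, 0.75, 0.9),
                        excellent = c(0.75, 0.9, 1, 1)),
    rules = data.frame(
      accuracy = rep(c("low", "medium", "high"), each = 3),
      removal = rep(c("few", "medium", "many"), times = 3),
      output = c("poor", "poor", "poor",
                 "acceptable", "acceptable", "good",
                 "good", "excellent", "excellent"),
      stringsAsFactors = FALSE),
    gridN = 20001) {
  cfg <- list(accuracyShapes = accuracyShapes, removalShapes = removalShapes,
              outputShapes = outputShapes, rules = rules, gridN = gridN)
  class(cfg) <- "FISConfig"
  validateFISConfig(cfg)
  cfg
}

validateFISConfig <- function(cfg) {
  stopifnot(setequal(names(cfg$accuracyShapes), c("low", "medium", "high")),
            setequal(names(cfg$removalShapes), c("few", "medium", "many")),
            setequal(names(cfg$outputShapes),
                     c("poor", "acceptable", "good", "excellent")))
  combos <- paste(cfg$rules$accuracy, cfg$rules$removal)
  need <- paste(rep(c("low", "medium", "high"), each = 3),
                rep(c("few", "medium", "many"), times = 3))
  if (!all(need %in% combos)) stop("rule table must be total")
  if (!all(cfg$rules$output %in% names(cfg$outputShapes)))
    stop("rules reference unknown output levels")
  for (shapes in list(cfg$accuracyShapes, cfg$removalShapes,
                      cfg$outputShapes)) {
    for (p in shapes) stopifnot(length(p) == 4, !is.unsorted(p))
    grid <- seq(0, 1, length.out = 201)
    total <- Reduce(`+`, lapply(shapes, function(p) trapMembership(grid, p)))
    if (any(total <= 0)) stop("membership functions must cover their domain")
  }
  invisible(cfg)
}

#' Fuzzy-inference score of one operating point
#'
#' Fuzzifies the accuracy (relative to the subject's maximum) and the number
#' of removed electrodes (relative to C - 1), fires all rules with
#' min-conjunction, aggregates the clipped output trapezoids with max, and
#' defuzzifies by centroid on a fixed fine grid. Deterministic.
#'
#' @param accuracy held-out accuracy of the operating point.
#' @param nRemoved electrodes removed (0 .. C - 1).
#' @param subjectMax the subject's maximum accuracy (upper bound of the
#'   accuracy domain).
#' @param C starting channel count.
#' @param config a [fisConfig()].
#' @return score in [0, 1].
#' @export
fisScore <- function(accuracy, nRemoved, subjectMax, C,
                     config = fisConfig()) {
  stopifnot(inherits(config, "FISConfig"), subjectMax > 0, C >= 2,
            nRemoved >= 0, nRemoved <= C - 1)
  accFrac <- min(max(accuracy / subjectMax, 0), 1)
  remFrac <- min(max(nRemoved / (C - 1), 0), 1)
  muAcc <- vapply(config$accuracyShapes,
                  function(p) trapMembership(accFrac, p), numeric(1))
  muRem <- vapply(config$removalShapes,
                  function(p) trapMembership(remFrac, p), numeric(1))
  grid <- seq(0, 1, length.out = config$gridN)
  agg <- numeric(config$gridN)
  for (r in seq_len(nrow(config$rules))) {
    strength <- min(muAcc[[config$rules$accuracy[r]]],
                    muRem[[config$rules$removal[r]]])
    if (strength <= 0) next
    out <- pmin(strength,
                trapMembership(grid, config$outputShapes[[config$rules$output[r]]]))
    agg <- pmax(agg, out)
  }
  if (all(agg == 0)) return(0)
  w <- c(0.5, rep(1, config$gridN - 2), 0.5)   # trapezoid quadrature
  sum(w * grid * agg) / sum(w * agg)
}

#' Select the FIS operating point of a trace
#'
#' Scores every elimination step of a [ReductionTrace] with [fisScore()] and
#' returns the argmax as a [TopSet]; ties go to the larger number of removed
#' electrodes (fewer electrodes kept).
#'
#' @param trace a [ReductionTrace].
#' @param subjectMax the subject's maximum accuracy (default: the trace's own
#'   maximum).
#' @param config a [fisConfig()].
#' @param subject subject identifier stored in the TopSet.
#' @return a [TopSet].
#' @export
selectTopSet <- function(trace, subjectMax = max(trace@accuracyByRemoved),
                         config = fisConfig(), subject = "s1") {
  stopifnot(is(trace, "ReductionTrace"))
  C <- length(trace@channels)
  scores <- vapply(seq_len(C) - 1, function(k)
    fisScore(trace@accuracyByRemoved[k + 1], k, subjectMax, C, config),
    numeric(1))
  best <- max(scores)
  k <- max(which(scores >= best - 1e-12)) - 1L  # ties: more removed wins
  kept <- if (k == 0) trace@channels
          else setdiff(trace@channels, trace@removalOrder[seq_len(k)])
  new("TopSet", subject = subject, comboId = trace@comboId,
      nRemoved = k, kept = kept,
      accuracy = trace@accuracyByRemoved[k + 1], fisScore = scores[k + 1])
}

#' Dataset-size-adjusted decoding-significance threshold
#'
#' The theoretical chance level 1/nClasses holds only for infinitely many
#' predictions; for a finite trial count the threshold is raised by the
#' two-sided normal approximation of the binomial null at level \code{alpha},
#' then rounded up to an attainable integer number of correct trials:
#' \deqn{ceil(n (p_0 + z_{1-\alpha/2} \sqrt{p_0 (1-p_0)/n})) / n \times 100.}
#'
#' @param nTrials dataset size (total trials).
#' @param nClasses number of classes.
#' @param alpha significance level (default 0.05).
#' @return threshold accuracy in percent, rounded to 2 decimals.
#' @examples
#' significanceThreshold(350, 5)   # 24.29
#' significanceThreshold(360, 9)   # 14.44
#' significanceThreshold(400, 5)   # 24.00
#' @export
significanceThreshold <- function(nTrials, nClasses, alpha = 0.05) {
  stopifnot(nTrials >= 1, nClasses >= 2, alpha > 0, alpha < 1)
  p0 <- 1 / nClasses
  z <- stats::qnorm(1 - alpha / 2)
  bound <- p0 + z * sqrt(p0 * (1 - p0) / nTrials)
  round(ceiling(nTrials * bound) / nTrials * 100, 2)
}

#' Write top sets as a CSV table
#'
#' Long format: subject, comboId, accuracy, nRemoved, fisScore, kept
#' (semicolon-separated).
#' @param topSets list of [TopSet] objects.
#' @param path output file.
#' @export
writeTopSetCSV <- function(topSets, path) {
  df <- do.call(rbind, lapply(topSets, function(ts)
    data.frame(subject = ts@subject, comboId = ts@comboId,
               accuracy = ts@accuracy, nRemoved = ts@nRemoved,
               fisScore = ts@fisScore,
               kept = paste(ts@kept, collapse = ";"),
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTopSetCSV
#' @export
readTopSetCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    new("TopSet", subject = as.character(df$subject[i]),
        comboId = df$comboId[i], nRemoved = as.integer(df$nRemoved[i]),
        kept = strsplit(df$kept[i], ";")[[1]],
        accuracy = df$accuracy[i], fisScore = df$fisScore[i]))
}
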