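#' Build an experiment configuration
#'
#' Describes a full factorial electrode-reduction experiment: subjects x
#' features x classifiers x reducers. Completed combos are skipped on rerun
#' when their trace file already exists under the same resolved-config
#' fingerprint.
#'
#' @param data named list of [EpochedData] (one per subject), or a fixture
#'   preset name (single subject \code{"s1"}).
#' @param featureSpecs list of [FeatureSpec].
#' @param classifierSpecs list of [ClassifierSpec].
#' @param reducerSpecs list of [ReducerSpec].
#' @param splitPolicy list; either \code{list(kind = "random",
#'   testFraction = 0.2, seed = <int>)} or \code{list(kind = "predefined",
#'   trainIdx =, testIdx =)}.
#' @param fis a [fisConfig()].
#' @param montage a [Montage].
#' @param outDir output directory.
#' @param seed integer master seed.
#' @return a list of class \code{ExperimentConfig}.
#' @export
experimentConfig <- function(data, featureSpecs, classifierSpecs,
                             reducerSpecs,
                             splitPolicy = list(kind = "random",
                                                testFraction = 0.2,
                                                seed = 1L),
                             fis = fisConfig(), montage = standardMontage(),
                             outDir = tempfile("eegreduce-run"), seed = 1L) {
  if (is.character(data)) {
    data <- stats::setNames(list(makeFixture(data)$data), "s1")
  }
  stopifnot(length(data) >= 1, length(featureSpecs) >= 1,
            length(classifierSpecs) >= 1, length(reducerSpecs) >= 1)
  if (splitPolicy$kind == "random" && is.null(splitPolicy$seed))
    stop("random split policy requires a seed")
  cfg <- list(data = data, featureSpecs = featureSpecs,
              classifierSpecs = classifierSpecs, reducerSpecs = reducerSpecs,
              splitPolicy = splitPolicy, fis = fis, montage = montage,
              outDir = outDir, seed = as.integer(seed))
  class(cfg) <- "ExperimentConfig"
  cfg
}

configFingerprint <- function(cfg) {
  desc <- list(
    subjects = names(cfg$data),
    dims = lapply(cfg$data, function(d) dim(d@signal)),
    features = vapply(cfg$featureSpecs, function(x) x@kind, ""),
    classifiers = vapply(cfg$classifierSpecs,
                         function(x) paste0(x@kind, ":", x@seed), ""),
    reducers = vapply(cfg$reducerSpecs, function(x) x@kind, ""),
    split = cfg$splitPolicy, seed = cfg$seed)
  tmp <- tempfile()
  writeLines(jsonlite::toJSON(desc, auto_unbox = TRUE, digits = NA), tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

#' Run a full factorial reduction experiment
#'
#' For every subject x feature x classifier x reducer combination, runs
#' [runReduction()] under the subject's frozen split and [selectTopSet()] on
#' the resulting trace. Persists one JSON trace per combo, a long-format
#' results CSV (subject, combo, nRemoved, accuracy), a top-set CSV, the
#' electrode occurrence map, the removed-count cluster report, anatomical
#' benchmarks, a mean accuracy-vs-removed curve figure (if ggplot2 is
#' available) and a frozen copy of the resolved configuration. Reruns with an
#' unchanged config skip completed combos; per-combo failures are isolated
#' and reported in the returned \code{failures}.
#'
#' @param cfg an [experimentConfig()].
#' @return invisible list with \code{traces}, \code{topSets},
#'   \code{occurrence}, \code{clusters}, \code{benchmarks}, \code{failures},
#'   \code{outDir}.
#' @export
runExperiment <- function(cfg) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(cfg$outDir, "traces"), showWarnings = FALSE)
  fp <- configFingerprint(cfg)
  writeLines(fp, file.path(cfg$outDir, "config.fingerprint"))
  jsonlite::write_json(
    list(fingerprint = fp, seed = cfg$seed,
         subjects = names(cfg$data),
         features = vapply(cfg$featureSpecs, function(x) x@kind, ""),
         classifiers = vapply(cfg$classifierSpecs, function(x) x@kind, ""),
         reducers = vapply(cfg$reducerSpecs, function(x) x@kind, ""),
         splitPolicy = cfg$splitPolicy),
    file.path(cfg$outDir, "config.resolved.json"), auto_unbox = TRUE)

  traces <- list(); topSets <- list(); failures <- list()
  for (subj in names(cfg$data)) {
    epochs <- cfg$data[[subj]]
    split <- if (cfg$splitPolicy$kind == "predefined")
      predefinedSplit(cfg$splitPolicy$trainIdx, cfg$splitPolicy$testIdx)
    else makeSplit(trialLabels(epochs),
                   cfg$splitPolicy$testFraction %||% 0.2,
                   childSeed(cfg$splitPolicy$seed, subj))
    for (fs in cfg$featureSpecs) for (cs in cfg$classifierSpecs)
      for (rs in cfg$reducerSpecs) {
        comboId <- paste(fs@kind, cs@kind, rs@kind, sep = "+")
        key <- paste(subj, comboId, sep = "_")
        traceFile <- file.path(cfg$outDir, "traces",
                               paste0(key, "_", fp, ".json"))
        t0 <- Sys.time()
        res <- tryCatch({
          if (file.exists(traceFile)) readTraceJSON(traceFile)
          else {
            tr <- runReduction(epochs, split, fs, cs, rs,
                               seed = childSeed(cfg$seed, key))
            writeTraceJSON(tr, traceFile)
            tr
          }
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures[[key]] <- conditionMessage(res)
          message("combo ", key, " failed: ", conditionMessage(res))
          next
        }
        message(sprintf("combo %s done in %.1fs (seed %d)", key,
                        as.numeric(difftime(Sys.time(), t0, units = "secs")),
                        childSeed(cfg$seed, key)))
        traces[[key]] <- res
      }
    subjMax <- suppressWarnings(max(vapply(
      traces[startsWith(names(traces), paste0(subj, "_"))],
      function(t) max(t@accuracyByRemoved), numeric(1))))
    for (key in names(traces)[startsWith(names(traces), paste0(subj, "_"))])
      topSets[[key]] <- selectTopSet(traces[[key]], subjectMax = subjMax,
                                     config = cfg$fis, subject = subj)
  }

  occ <- NULL; clusters <- NULL; long <- NULL
  if (length(traces)) {
    long <- do.call(rbind, lapply(names(traces), function(key) {
      t <- traces[[key]]
      data.frame(subject = sub("_.*$", "", key), combo = t@comboId,
                 nRemoved = seq_along(t@accuracyByRemoved) - 1L,
                 accuracy = t@accuracyByRemoved, stringsAsFactors = FALSE)
    }))
    utils::write.csv(long, file.path(cfg$outDir, "results_long.csv"),
                     row.names = FALSE)
    writeTopSetCSV(topSets, file.path(cfg$outDir, "top_sets.csv"))
    if (all(unlist(lapply(topSets, function(ts)
      all(ts@kept %in% channelNames(cfg$montage)))))) {
      occ <- electrodeOccurrence(topSets, cfg$montage)
      writeOccurrenceCSV(occ, file.path(cfg$outDir, "occurrence.csv"))
    }
    nRem <- vapply(topSets, function(ts) as.numeric(ts@nRemoved), numeric(1))
    if (length(nRem) >= 2 && length(unique(nRem)) >= 2) {
      clusters <- clusterRemovedCounts(nRem, seed = cfg$seed)
      utils::write.csv(
        data.frame(value = nRem, cluster = clusters$assignments),
        file.path(cfg$outDir, "clusters.csv"), row.names = FALSE)
      utils::write.csv(
        data.frame(k = seq_along(clusters$sse), sse = clusters$sse),
        file.path(cfg$outDir, "sse_curve.csv"), row.names = FALSE)
    }
    plotMeanCurves(long, file.path(cfg$outDir, "accuracy_vs_removed.svg"))
  }

  benchmarks <- NULL
  availableSubsets <- names(cfg$montage@subsets)[
    vapply(cfg$montage@subsets, function(s)
      all(s %in% channelNames(cfg$data[[1]])), logical(1))]
  if (length(availableSubsets)) {
    benchmarks <- lapply(names(cfg$data), function(subj) {
      epochs <- cfg$data[[subj]]
      split <- makeSplit(trialLabels(epochs), 0.2,
                         childSeed(cfg$splitPolicy$seed %||% cfg$seed, subj))
      rows <- lapply(availableSubsets, function(sn) {
        b <- anatomicalBenchmark(epochs, split, cfg$montage, sn,
                                 cfg$featureSpecs, cfg$classifierSpecs[[1]])
        data.frame(subject = subj, subset = sn, best = b$best,
                   bestAccuracy = b$bestAccuracy, nChannels = b$nChannels)
      })
      do.call(rbind, rows)
    })
    benchmarks <- do.call(rbind, benchmarks)
    utils::write.csv(benchmarks, file.path(cfg$outDir, "benchmarks.csv"),
                     row.names = FALSE)
  }
  if (length(failures) && !length(traces))
    stop("all combos failed; first error: ", failures[[1]])
  invisible(list(traces = traces, topSets = topSets, occurrence = occ,
                 clusters = clusters, benchmarks = benchmarks,
                 failures = failures, long = long, outDir = cfg$outDir))
}

plotMeanCurves <- function(long, path) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) return(invisible(NULL))
  agg <- stats::aggregate(accuracy ~ combo + nRemoved, long, mean)
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = nRemoved, y = accuracy)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~combo) +
    ggplot2::labs(x = "electrodes removed", y = "mean test accuracy") +
    ggplot2::theme_minimal()
  grDevices::svg(path, width = 8, height = 6)
  print(p)
  grDevices::dev.off()
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' Keys: \code{data} (fixture preset name), \code{features} (list of kinds),
#' \code{classifiers} (list of \code{kind}/\code{seed} maps or kind strings),
#' \code{reducers} (list of kinds), \code{split}
#' (\code{kind}/\code{testFraction}/\code{seed}), \code{outDir}, \code{seed},
#' plus optional \code{filter} and \code{epoch} blocks consumed by the CLI.
#'
#' @param path YAML file.
#' @return an [experimentConfig()].
#' @export
readExperimentYAML <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  classifiers <- lapply(y$classifiers, function(c) {
    if (is.character(c)) classifierSpec(c, seed = seed)
    else classifierSpec(c$kind, seed = c$seed %||% seed)
  })
  experimentConfig(
    data = y$data,
    featureSpecs = lapply(y$features, featureSpec),
    classifierSpecs = classifiers,
    reducerSpecs = lapply(y$reducers, reducerSpec),
    splitPolicy = y$split %||% list(kind = "random", testFraction = 0.2,
                                    seed = seed),
    outDir = y$outDir %||% tempfile("eegreduce-run"),
    seed = seed)
}
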