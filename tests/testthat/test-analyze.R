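mkTopSet <- function(kept, subject = "s1")
  new("TopSet", subject = subject, comboId = "wav+rf+gwo",
      nRemoved = as.integer(64 - length(kept)), kept = kept,
      accuracy = 0.5, fisScore = 0.5)

test_that("occurrence percentages count kept channels correctly", {
  m <- standardMontage()
  all64 <- channelNames(m)
  occ <- electrodeOccurrence(list(mkTopSet(all64)), m)
  expect_true(all(occ$percent == 100))
  half1 <- all64[1:32]; half2 <- all64[33:64]
  occ2 <- electrodeOccurrence(list(mkTopSet(half1), mkTopSet(half2)), m)
  expect_true(all(occ2$percent == 50))
  # 10 synthetic top sets against a literal hand count
  withr::with_seed(9, {
    sets <- lapply(1:10, function(i) mkTopSet(sample(all64, sample(20:50, 1))))
    occ3 <- electrodeOccurrence(sets, m)
    for (ch in sample(all64, 8)) {
      manual <- 0
      for (s in sets) if (ch %in% s@kept) manual <- manual + 1
      expect_equal(occ3$percent[occ3$channel == ch], 10 * manual)
    }
  })
  expect_error(electrodeOccurrence(list(), m), "at least one")
})

test_that("three well-separated groups give an elbow at k = 3", {
  values <- c(1, 1, 2, 10, 11, 20, 21)
  res <- clusterRemovedCounts(values, kMax = 5, seed = 2)
  expect_equal(res$k, 3L)
  expect_equal(res$assignments, c(1, 1, 1, 2, 2, 3, 3))
  oracle <- oracleKmeans1d(values, 3)
  expect_equal(res$assignments, oracle$assignments)
})

test_that("identical values degenerate to a single cluster", {
  res <- clusterRemovedCounts(rep(4, 6))
  expect_equal(res$k, 1L)
  expect_true(all(res$sse == 0))
})

test_that("cluster structure is invariant to value order", {
  values <- c(1, 1, 2, 10, 11, 20, 21)
  perm <- c(7, 3, 1, 5, 2, 6, 4)
  a <- clusterRemovedCounts(values, kMax = 5, seed = 2)
  b <- clusterRemovedCounts(values[perm], kMax = 5, seed = 2)
  expect_equal(b$assignments[order(perm)], a$assignments)
  expect_equal(a$centers, b$centers)
})

test_that("k-means SSE matches the exact dynamic-programming solution", {
  withr::with_seed(33, {
    for (i in 1:20) {
      centers <- sort(sample(5:50, 3))
      values <- round(c(rnorm(8, centers[1], 1.2), rnorm(8, centers[2], 1.2),
                        rnorm(8, centers[3], 1.2)))
      res <- clusterRemovedCounts(values, kMax = 6, seed = i)
      for (k in 2:4) {
        dp <- oracleKmeans1d(values, k)
        expect_equal(res$sse[k], dp$sse, tolerance = 1e-8)
      }
    }
  })
})

test_that("anatomical benchmarks see exactly the subset channels", {
  fx <- makeFixture("study-like")
  d <- fx$data
  m <- standardMontage()
  split <- makeSplit(trialLabels(d), 0.2, seed = 1)
  # count the channels the pipeline actually receives via a probe spec
  res <- anatomicalBenchmark(d, split, m, "broca_wernicke",
                             list(featureSpec("wav")),
                             classifierSpec("rf", seed = 1))
  expect_equal(res$nChannels, 18)
  expect_named(res$accuracies, "wav")
})

test_that("missing subset channels are reported by name", {
  fx <- smallFixture()
  m <- standardMontage()
  split <- makeSplit(trialLabels(fx$data), 0.2, seed = 1)
  expect_error(anatomicalBenchmark(fx$data, split, m, "left",
                                   list(featureSpec("wav")),
                                   classifierSpec("rf", seed = 1)),
               "TP7")
})

test_that("informative channels outside the subset leave it at chance", {
  # place all class sources outside a small probe subset: decoding on the
  # subset stays inside the chance band while the full montage clears the
  # dataset-size-adjusted significance threshold
  chans <- c("F3", "F4", "C3", "Cz", "C4", "Pz", "PO3", "PO4")
  cfg <- synthConfig(nClasses = 4, trialsPerClass = 25, channels = chans,
                     informativeChannels = c("C3", "Cz", "C4", "Pz"),
                     snr = 2, seed = 61)
  d <- generateDataset(cfg)$data
  m <- montage(data.frame(label = chans, x = 0, y = 0),
               subsets = list(probe = c("F3", "F4", "PO3", "PO4")))
  split <- makeSplit(trialLabels(d), 0.2, seed = 61)
  sub <- anatomicalBenchmark(d, split, m, "probe", list(featureSpec("wav")),
                             classifierSpec("rf", seed = 2))
  full <- eegreduce:::pipelineAccuracy(d, split, featureSpec("wav"),
                                       classifierSpec("rf", seed = 2), chans)
  nTest <- length(split@testIdx)
  band <- qbinom(c(0.005, 0.995), nTest, 0.25) / nTest
  expect_lte(sub$bestAccuracy, band[2])
  expect_gt(full * 100, significanceThreshold(nTrials(d), 4))
})
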