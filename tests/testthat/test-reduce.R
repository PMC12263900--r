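test_that("the greedy step removes the channel whose exclusion scores highest", {
  kept <- c("F3", "Cz", "P4")
  res <- gwoStep(NULL, NULL, NULL, NULL, kept,
                 evaluator = function(chs) if (!"Cz" %in% chs) 0.9 else 0.5)
  expect_equal(res$removed, "Cz")
  expect_equal(res$table$accuracy[res$table$channel == "Cz"], 0.9)
})

test_that("greedy ties remove the earliest candidate in montage order", {
  kept <- c("F3", "Cz", "P4")
  res <- gwoStep(NULL, NULL, NULL, NULL, kept,
                 evaluator = function(chs) 0.7)
  expect_equal(res$removed, "F3")
})

test_that("the greedy removal always attains the maximum of its own table", {
  fx <- tinyFixture()
  split <- makeSplit(trialLabels(fx$data), 0.2, seed = 3)
  res <- gwoStep(fx$data, split, featureSpec("wav"),
                 classifierSpec("rf", seed = 3), channelNames(fx$data))
  expect_equal(res$table$accuracy[res$table$channel == res$removed],
               max(res$table$accuracy))
})

test_that("greedy stepping needs at least two channels", {
  expect_error(gwoStep(NULL, NULL, NULL, NULL, "Cz"), "fewer than 2")
})

test_that("csp-rank removes the channel absent from the extreme filters", {
  # channel 3's coefficients vanish in both extreme rows of the
  # importance-ordered matrix
  W <- rbind(c(5, 4, 0, 3),
             c(1, 1, 0.5, 1),
             c(0.2, 0.1, 0, 0.1))
  kept <- c("a", "b", "c", "d")
  expect_equal(cspRankStep(NULL, NULL, kept, filterMatrix = W), "c")
  # positive rescaling leaves the choice unchanged
  expect_equal(cspRankStep(NULL, NULL, kept, filterMatrix = 7.3 * W), "c")
})

test_that("csp-rank on a two-class toy rejects a noise channel", {
  # classes raise variance on channels 1 and 2 respectively; channels 3-4
  # carry class-independent unit noise. The class-extreme filters
  # concentrate on channels 1 and 2, so a noise channel is rejected.
  withr::with_seed(5, {
    nTr <- 10; nSamp <- 128
    sig <- array(rnorm(2 * nTr * 4 * nSamp), dim = c(2 * nTr, 4, nSamp))
    labs <- rep(c("A", "B"), each = nTr)
    for (tr in seq_len(2 * nTr)) {
      ch <- if (labs[tr] == "A") 1 else 2
      sig[tr, ch, ] <- sig[tr, ch, ] + 2 * rnorm(nSamp)
    }
    ep <- new("EpochedData", signal = sig, labels = labs, sfreq = 128,
              channelNames = c("c1", "c2", "c3", "c4"), epochLength = 1)
    split <- predefinedSplit(seq_len(2 * nTr - 4),
                             seq(2 * nTr - 3, 2 * nTr))
    removed <- cspRankStep(ep, split, channelNames(ep))
    expect_true(removed %in% c("c3", "c4"))
  })
})

test_that("one-vs-all selection removes the never-maximal channel", {
  pooled <- rbind(c(3, 0.1, 2, 1),
                  c(2.5, 0.2, 1.5, 2.2),
                  c(1, 0.05, 0.8, 0.9))
  kept <- c("a", "b", "c", "d")
  expect_equal(ocspRankSelect(NULL, NULL, kept, pooled = pooled), "b")
})

test_that("one-vs-all selection at two channels keeps the maximal one", {
  pooled <- rbind(c(0.2, 5), c(0.1, 1))
  expect_equal(ocspRankSelect(NULL, NULL, c("x", "y"), pooled = pooled), "x")
})

test_that("one-vs-all selection matches a straight-line reimplementation", {
  fx <- smallFixture(seed = 12)
  split <- makeSplit(trialLabels(fx$data), 0.2, seed = 12)
  kept <- channelNames(fx$data)
  # rebuild the pooled extreme eigenvectors independently
  tr <- eegreduce:::trainEpochs(fx$data, split, kept)
  cc <- eegreduce:::classCovariances(tr)
  K <- dim(cc$covs)[1]
  pooled <- NULL
  for (ci in seq_len(K)) {
    Crest <- apply(cc$covs[-ci, , , drop = FALSE], c(2, 3), mean)
    Wi <- eegreduce:::cspTwoClass(cc$covs[ci, , ], Crest)$W
    pooled <- rbind(pooled, Wi[c(1, nrow(Wi)), ])
  }
  # literal pooled-argmax loop: repeatedly take the unselected channel whose
  # column holds the globally largest remaining absolute coefficient
  A <- abs(pooled)
  selected <- rep(FALSE, length(kept))
  for (it in seq_len(length(kept) - 1)) {
    bestVal <- -Inf; bestCh <- NA
    for (ch in seq_along(kept)) {
      if (selected[ch]) next
      v <- max(A[, ch])
      if (v > bestVal) { bestVal <- v; bestCh <- ch }
    }
    selected[bestCh] <- TRUE
  }
  oracleRemoved <- kept[!selected]
  expect_equal(ocspRankSelect(fx$data, split, kept), oracleRemoved)
})

test_that("ica scores follow the voting rule on crafted matrices", {
  # identity components, |L| = 1: the L component's channel scores 2
  s <- icaChannelScores(diag(4), lFraction = 0.13)
  expect_equal(sum(s == 2), 1)
  expect_equal(sum(s == 1), 3)
  expect_equal(sum(s), 2 * 1 + (4 - 1))
})

test_that("ica score conservation holds under unique maxima", {
  withr::with_seed(7, {
    for (i in 1:20) {
      N <- sample(2:12, 1)
      M <- sample(2:12, 1)
      comp <- matrix(rnorm(N * M), N, M)
      s <- icaChannelScores(comp, lFraction = 0.13)
      nL <- max(1, round(0.13 * N))
      expect_equal(sum(s), 2 * nL + (N - nL))
      expect_identical(s, oracleIcaScores(comp, 0.13))
    }
  })
})

test_that("the ica step removes the lowest-scoring channel, ties latest", {
  kept <- c("F3", "Cz", "P4", "O1")
  expect_equal(icaStep(NULL, NULL, kept, scores = c(5, 3, 3, 1)), "O1")
  expect_equal(icaStep(NULL, NULL, kept, scores = c(2, 2, 2, 2)), "O1")
  expect_equal(icaStep(NULL, NULL, kept, scores = c(1, 3, 1, 3)), "P4")
})

test_that("ica reduction tends to drop non-informative channels first", {
  hits <- 0
  for (sd in 1:10) {
    fx <- smallFixture(snr = 2, seed = 400 + sd)
    split <- makeSplit(trialLabels(fx$data), 0.2, seed = sd)
    kept <- channelNames(fx$data)
    removed <- character(0)
    for (k in 1:4) {
      r <- suppressWarnings(icaStep(fx$data, split, kept, seed = sd * 31 + k))
      removed <- c(removed, r)
      kept <- setdiff(kept, r)
    }
    nNoise <- sum(!removed %in% fx$truth@informativeChannels)
    if (nNoise >= 3) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("full reduction traces satisfy their length and conservation contracts", {
  fx <- tinyFixture()
  split <- makeSplit(trialLabels(fx$data), 0.2, seed = 2)
  fs <- featureSpec("wav"); cs <- classifierSpec("rf", seed = 2)
  for (kind in c("gwo", "csp_rank", "ocsp_rank", "ica_score")) {
    tr <- runReduction(fx$data, split, fs, cs, reducerSpec(kind))
    expect_length(removalOrder(tr), 3)
    expect_length(accuracyByRemoved(tr), 4)
    expect_setequal(c(removalOrder(tr),
                      setdiff(channelNames(fx$data), removalOrder(tr))),
                    channelNames(fx$data))
    expect_true(all(accuracyByRemoved(tr) >= 0 &
                    accuracyByRemoved(tr) <= 1))
  }
})

test_that("greedy reduction is bit-for-bit reproducible", {
  fx <- tinyFixture()
  split <- makeSplit(trialLabels(fx$data), 0.2, seed = 2)
  fs <- featureSpec("wav"); cs <- classifierSpec("rf", seed = 2)
  t1 <- runReduction(fx$data, split, fs, cs, reducerSpec("gwo"))
  t2 <- runReduction(fx$data, split, fs, cs, reducerSpec("gwo"))
  expect_identical(removalOrder(t1), removalOrder(t2))
  expect_identical(accuracyByRemoved(t1), accuracyByRemoved(t2))
})

test_that("traces round-trip through JSON", {
  fx <- tinyFixture()
  split <- makeSplit(trialLabels(fx$data), 0.2, seed = 2)
  tr <- runReduction(fx$data, split, featureSpec("wav"),
                     classifierSpec("rf", seed = 2), reducerSpec("csp_rank"))
  path <- tempfile(fileext = ".json")
  writeTraceJSON(tr, path)
  back <- readTraceJSON(path)
  expect_identical(back@removalOrder, tr@removalOrder)
  expect_equal(back@accuracyByRemoved, tr@accuracyByRemoved)
  expect_identical(back@comboId, tr@comboId)
})
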