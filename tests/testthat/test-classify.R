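blobs <- function(n = 30, d = 6, sep = 6, seed = 2) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n * d), n, d),
               matrix(rnorm(n * d, mean = sep), n, d))
    colnames(X) <- paste0("f", seq_len(d))
    list(X = X, y = rep(c("a", "b"), each = n))
  })
}

test_that("every classifier family separates two well-separated Gaussian blobs", {
  tr <- blobs(seed = 2)
  te <- blobs(n = 10, seed = 3)
  for (kind in c("xgb", "rf", "svm", "nn")) {
    res <- trainEval(classifierSpec(kind, seed = 9), tr$X, tr$y, te$X, te$y)
    expect_equal(accuracy(res), 1)
    expect_equal(sum(confusion(res)), 20)
  }
})

test_that("reruns with identical spec and data give bit-identical accuracy", {
  fx <- smallFixture(seed = 55)
  split <- makeSplit(trialLabels(fx$data), 0.2, seed = 55)
  fit <- fitFeatures(featureSpec("wav"), fx$data)
  fm <- transformFeatures(fit, fx$data)
  X <- featureValues(fm)
  for (kind in c("xgb", "rf", "svm", "nn")) {
    spec <- classifierSpec(kind, seed = 13)
    a <- trainEval(spec, X[split@trainIdx, ], fx$data@labels[split@trainIdx],
                   X[split@testIdx, ], fx$data@labels[split@testIdx])
    b <- trainEval(spec, X[split@trainIdx, ], fx$data@labels[split@trainIdx],
                   X[split@testIdx, ], fx$data@labels[split@testIdx])
    expect_identical(accuracy(a), accuracy(b))
  }
})

test_that("permuted labels decode at chance", {
  # mean accuracy over 10 label permutations stays within the 95% binomial
  # interval around 1/5 for the pooled test-trial count
  fx <- smallFixture(seed = 8)
  fm <- featureValues(transformFeatures(fitFeatures(featureSpec("wav"),
                                                    fx$data), fx$data))
  split <- makeSplit(trialLabels(fx$data), 0.2, seed = 8)
  accs <- vapply(1:10, function(sd) {
    labs <- withr::with_seed(sd, sample(trialLabels(fx$data)))
    accuracy(trainEval(classifierSpec("rf", seed = sd),
                       fm[split@trainIdx, ], labs[split@trainIdx],
                       fm[split@testIdx, ], labs[split@testIdx]))
  }, numeric(1))
  nTest <- length(split@testIdx)
  upper <- qbinom(0.975, nTest, 0.2) / nTest
  # training on permuted labels is biased BELOW chance in small samples
  # (class proportions anti-correlate between train and test folds), so
  # only the upper tail is a leakage indicator
  expect_true(all(accs <= upper),
              info = paste("accuracies:", paste(accs, collapse = ", ")))
  expect_lte(mean(accs), 0.3)
})

test_that("tree ensembles are insensitive to feature column order", {
  fx <- smallFixture(seed = 4)
  fm <- featureValues(transformFeatures(fitFeatures(featureSpec("wav"),
                                                    fx$data), fx$data))
  split <- makeSplit(trialLabels(fx$data), 0.2, seed = 4)
  perm <- withr::with_seed(1, sample(ncol(fm)))
  for (kind in c("rf", "xgb")) {
    spec <- classifierSpec(kind, seed = 21)
    a <- accuracy(trainEval(spec, fm[split@trainIdx, ],
                            fx$data@labels[split@trainIdx],
                            fm[split@testIdx, ],
                            fx$data@labels[split@testIdx]))
    b <- accuracy(trainEval(spec, fm[split@trainIdx, perm],
                            fx$data@labels[split@trainIdx],
                            fm[split@testIdx, perm],
                            fx$data@labels[split@testIdx]))
    expect_lte(abs(a - b), 0.02)
  }
})

test_that("test classes unseen in training count as errors, not crashes", {
  tr <- blobs(seed = 2)
  te <- blobs(n = 4, seed = 3)
  te$y[1] <- "c"
  res <- trainEval(classifierSpec("rf", seed = 9), tr$X, tr$y, te$X, te$y)
  expect_equal(res@nTest, 8L)
  expect_lte(accuracy(res), 7 / 8)
  expect_true("c" %in% rownames(confusion(res)))
})

test_that("contract violations fail loudly", {
  tr <- blobs()
  expect_error(trainEval(classifierSpec("rf", seed = 1), tr$X, tr$y,
                         tr$X[, 1:3], tr$y),
               "columns differ")
  expect_error(trainEval(classifierSpec("rf", seed = 1), tr$X,
                         rep("a", nrow(tr$X)), tr$X, tr$y),
               "2 classes")
  expect_error(classifierSpec("boost", seed = 1), "kind")
  expect_error(classifierSpec("rf", seed = 1, maxDepth = 2), "unknown")
})

test_that("accuracy equals the confusion-matrix trace over the test count", {
  tr <- blobs(seed = 6)
  te <- blobs(n = 12, seed = 7)
  res <- trainEval(classifierSpec("svm", seed = 3), tr$X, tr$y, te$X, te$y)
  expect_equal(accuracy(res), sum(diag(confusion(res))) / res@nTest)
})
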