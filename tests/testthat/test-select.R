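test_that("fis scores stay in the unit interval across the input plane", {
  cfg <- fisConfig()
  for (a in seq(0, 0.6, by = 0.1))
    for (k in c(0, 15, 31, 45, 63)) {
      s <- fisScore(a, k, subjectMax = 0.6, C = 64, config = cfg)
      expect_gte(s, 0)
      expect_lte(s, 1)
    }
})

test_that("fis scores are non-decreasing in accuracy at fixed removal", {
  cfg <- fisConfig()
  for (k in c(0, 20, 40, 63)) {
    s <- vapply(seq(0, 0.6, length.out = 40), function(a)
      fisScore(a, k, subjectMax = 0.6, C = 64, config = cfg), numeric(1))
    expect_true(all(diff(s) >= -1e-9))
  }
})

test_that("the boundary point attains the configuration's maximal score", {
  cfg <- fisConfig()
  top <- fisScore(0.6, 63, subjectMax = 0.6, C = 64, config = cfg)
  grid <- expand.grid(a = seq(0, 0.6, length.out = 13),
                      k = round(seq(0, 63, length.out = 9)))
  all <- vapply(seq_len(nrow(grid)), function(i)
    fisScore(grid$a[i], grid$k[i], 0.6, 64, cfg), numeric(1))
  expect_equal(top, max(c(all, top)))
})

test_that("centroid defuzzification matches a dense-grid oracle", {
  cfg <- fisConfig()
  cases <- list(c(0.3, 31), c(0.55, 10), c(0.1, 60), c(0.48, 50))
  for (cs in cases) {
    mine <- fisScore(cs[1], cs[2], subjectMax = 0.6, C = 64, config = cfg)
    oracle <- oracleFisScore(cs[1], cs[2], subjectMax = 0.6, C = 64,
                             config = cfg)
    expect_equal(mine, oracle, tolerance = 1e-6)
  }
})

test_that("malformed fis configurations are rejected", {
  expect_error(fisConfig(rules = data.frame(accuracy = "low",
                                            removal = "few",
                                            output = "poor")),
               "total")
  badOut <- list(poor = c(0, 0, 0.1, 0.2), acceptable = c(0.5, 0.6, 0.7, 0.8),
                 good = c(0.7, 0.8, 0.85, 0.9), excellent = c(0.85, 0.95, 1, 1))
  expect_error(fisConfig(outputShapes = badOut), "cover")
})

test_that("top-set selection picks the fis argmax, ties to more removed", {
  trace <- new("ReductionTrace", comboId = "wav+rf+gwo",
               channels = paste0("c", 1:5),
               removalOrder = paste0("c", 1:4),
               accuracyByRemoved = c(0.5, 0.5, 0.5, 0.5, 0.5))
  ts <- selectTopSet(trace, subjectMax = 0.5)
  # constant accuracy: channel economy dominates, maximal removal wins
  expect_equal(ts@nRemoved, 4L)
  expect_equal(ts@accuracy, 0.5)
  expect_length(ts@kept, 1)
  scores <- vapply(0:4, function(k)
    fisScore(0.5, k, 0.5, 5), numeric(1))
  expect_equal(ts@fisScore, max(scores))
})

test_that("no other step of the trace beats the selected top set", {
  trace <- new("ReductionTrace", comboId = "wav+rf+gwo",
               channels = paste0("c", 1:8),
               removalOrder = paste0("c", 1:7),
               accuracyByRemoved = c(0.42, 0.5, 0.55, 0.52, 0.49, 0.4,
                                     0.3, 0.22))
  ts <- selectTopSet(trace, subjectMax = 0.55)
  scores <- vapply(0:7, function(k)
    fisScore(trace@accuracyByRemoved[k + 1], k, 0.55, 8), numeric(1))
  expect_equal(ts@fisScore, max(scores))
  expect_equal(ts@accuracy, trace@accuracyByRemoved[ts@nRemoved + 1])
  expect_setequal(c(ts@kept, trace@removalOrder[seq_len(ts@nRemoved)]),
                  trace@channels)
})

test_that("significance thresholds reproduce the dataset-size-adjusted values", {
  expect_equal(significanceThreshold(350, 5), 24.29)
  expect_equal(significanceThreshold(360, 9), 14.44)
  expect_equal(significanceThreshold(400, 5), 24.00)
  expect_equal(significanceThreshold(100, 4), 34.00)
})

test_that("the threshold approaches the theoretical chance level for huge n", {
  for (k in c(2, 5, 9)) {
    thr <- significanceThreshold(1e6, k)
    expect_gte(thr, 100 / k)
    expect_lte(thr - 100 / k, 0.1 + 1e-9)
  }
})

test_that("threshold preconditions are enforced", {
  expect_error(significanceThreshold(0, 5))
  expect_error(significanceThreshold(100, 1))
  expect_error(significanceThreshold(100, 5, alpha = 0))
})

test_that("top sets round-trip through CSV", {
  ts <- new("TopSet", subject = "s1", comboId = "wav+rf+gwo",
            nRemoved = 2L, kept = c("C3", "Cz"), accuracy = 0.8,
            fisScore = 0.71)
  path <- tempfile(fileext = ".csv")
  writeTopSetCSV(list(ts), path)
  back <- readTopSetCSV(path)[[1]]
  expect_identical(back@kept, ts@kept)
  expect_equal(back@accuracy, ts@accuracy)
  expect_equal(back@nRemoved, ts@nRemoved)
})
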