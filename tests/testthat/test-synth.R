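test_that("identical configs generate bit-identical datasets", {
  cfg <- synthConfig(nClasses = 3, trialsPerClass = 4,
                     channels = c("C3", "Cz", "C4", "Pz"),
                     informativeChannels = c("C3", "C4"), snr = 1, seed = 42)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(a$data@signal, b$data@signal)
  expect_identical(a$data@labels, b$data@labels)
  expect_identical(a$truth@channelGains, b$truth@channelGains)
})

test_that("labels are balanced and trial counts follow the config", {
  cfg <- synthConfig(nClasses = 5, trialsPerClass = 70,
                     channels = c("C3", "Cz", "C4", "Pz", "F3", "F4"),
                     informativeChannels = c("C3", "C4"), snr = 0.5, seed = 1)
  d <- generateDataset(cfg)$data
  expect_equal(nTrials(d), 350)
  expect_true(all(table(trialLabels(d)) == 70))
})

test_that("invalid generator configs are rejected", {
  expect_error(synthConfig(nClasses = 5, trialsPerClass = 10,
                           channels = c("C3", "C4"),
                           informativeChannels = c("C3", "C4"),
                           snr = -1, seed = 1),
               "snr")
  expect_error(synthConfig(nClasses = 5, trialsPerClass = 10,
                           channels = c("C3", "C4"),
                           informativeChannels = character(),
                           snr = 1, seed = 1),
               "informative")
  expect_error(synthConfig(nClasses = 1, trialsPerClass = 10,
                           channels = c("C3", "C4"),
                           informativeChannels = "C3", snr = 1, seed = 1),
               "nClasses")
})

test_that("class-frequency band power separates informative from noise channels", {
  # at high snr the between-class variance of band power at the class
  # frequencies must be strictly larger on every informative channel than on
  # every non-informative one, computed directly from the tensor
  fx <- smallFixture(snr = 2, seed = 9)
  d <- fx$data
  labs <- trialLabels(d)
  n <- dim(d@signal)[3]
  freqs <- pmin(0:(n - 1), n - (0:(n - 1))) * samplingRate(d) / n
  sel <- freqs >= 8 & freqs <= 30
  betweenVar <- vapply(seq_len(nChannels(d)), function(j) {
    pw <- vapply(seq_len(nTrials(d)), function(tr)
      sum(Mod(stats::fft(d@signal[tr, j, ]))[sel]^2), numeric(1))
    stats::var(tapply(pw, labs, mean))
  }, numeric(1))
  inf <- channelNames(d) %in% fx$truth@informativeChannels
  expect_gt(min(betweenVar[inf]), max(betweenVar[!inf]))
})

test_that("snr = 0 data decode at chance level", {
  fx <- smallFixture(snr = 0, seed = 31)
  split <- makeSplit(trialLabels(fx$data), 0.2, seed = 31)
  acc <- eegreduce:::pipelineAccuracy(fx$data, split, featureSpec("wav"),
                                      classifierSpec("rf", seed = 3),
                                      channelNames(fx$data))
  nTest <- length(split@testIdx)
  band <- qbinom(c(0.025, 0.975), nTest, 0.2) / nTest
  expect_gte(acc, band[1])
  expect_lte(acc, band[2])
})

test_that("decoding accuracy responds monotonically to snr", {
  # mean held-out accuracy over 5 seeds, non-decreasing across snr 0/0.5/2
  # within sampling error
  fs <- featureSpec("wav"); cs <- classifierSpec("rf", seed = 5)
  meanAcc <- vapply(c(0, 0.5, 2), function(s) {
    mean(vapply(1:5, function(sd) {
      fx <- smallFixture(snr = s, seed = 300 + sd)
      split <- makeSplit(trialLabels(fx$data), 0.2, seed = sd)
      eegreduce:::pipelineAccuracy(fx$data, split, fs, cs,
                                   channelNames(fx$data))
    }, numeric(1)))
  }, numeric(1))
  tol <- 0.05   # sampling error on 5 x 20 test trials
  expect_gte(meanAcc[2], meanAcc[1] - tol)
  expect_gte(meanAcc[3], meanAcc[2] - tol)
  expect_gt(meanAcc[3], meanAcc[1] + 0.2)
})

test_that("fixture presets have their documented shapes", {
  tiny <- tinyFixture()
  expect_equal(dim(tiny$data@signal)[1:2], c(20L, 4L))
  small <- smallFixture()
  expect_equal(nChannels(small$data), 16)
  expect_length(small$truth@informativeChannels, 4)
  study <- makeFixture("study-like")
  expect_equal(nTrials(study$data), 350)
  expect_equal(nChannels(study$data), 64)
  expect_equal(study$data@epochLength, 2)
  expect_error(makeFixture("huge"), "unknown preset")
})

test_that("fixtures round-trip through the plain-text serialization", {
  fx <- tinyFixture()
  dir <- tempfile("fix")
  writeFixture(fx, dir)
  back <- readFixture(dir)
  expect_equal(back$data@signal, fx$data@signal, tolerance = 1e-12)
  expect_identical(back$data@labels, fx$data@labels)
  expect_identical(back$truth@informativeChannels,
                   fx$truth@informativeChannels)
  expect_equal(back$truth@channelGains, fx$truth@channelGains,
               tolerance = 1e-12)
})

test_that("blink transients land on frontal channels only", {
  cfg <- synthConfig(nClasses = 2, trialsPerClass = 3,
                     channels = c("Fp1", "Fp2", "C3", "C4"),
                     informativeChannels = "C3", snr = 0.5,
                     blinkRate = 60, seed = 8)
  withBlinks <- generateDataset(cfg)$data
  cfg2 <- synthConfig(nClasses = 2, trialsPerClass = 3,
                      channels = c("Fp1", "Fp2", "C3", "C4"),
                      informativeChannels = "C3", snr = 0.5,
                      blinkRate = 0, seed = 8)
  without <- generateDataset(cfg2)$data
  dFront <- mean(abs(withBlinks@signal[, 1:2, ] - without@signal[, 1:2, ]))
  expect_gt(dFront, 0)
  # within the first trial the RNG streams coincide up to the blink draws,
  # so non-frontal channels must be bit-identical there
  expect_identical(withBlinks@signal[1, 3:4, ], without@signal[1, 3:4, ])
})
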