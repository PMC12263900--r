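makeRec <- function(sig, sfreq = 500, events = NULL) {
  if (is.null(events)) events <- data.frame(sample = integer(),
                                            label = character())
  new("ContinuousRecording", signal = sig, sfreq = sfreq,
      channelNames = paste0("ch", seq_len(nrow(sig))), events = events)
}

test_that("notch removes a 50 Hz tone by at least 20 dB", {
  sfreq <- 500
  t <- seq(0, 10, by = 1 / sfreq)[-1]
  rec <- makeRec(matrix(sin(2 * pi * 50 * t), nrow = 1), sfreq)
  out <- bandpassNotch(rec)
  core <- seq(sfreq, length(t) - sfreq)   # skip filter edge transients
  att <- 20 * log10(sqrt(mean(rec@signal[1, core]^2)) /
                    sqrt(mean(out@signal[1, core]^2)))
  expect_gt(att, 20)
})

test_that("a mid-passband tone passes within 1 dB", {
  sfreq <- 500
  t <- seq(0, 10, by = 1 / sfreq)[-1]
  rec <- makeRec(matrix(sin(2 * pi * 10 * t), nrow = 1), sfreq)
  out <- bandpassNotch(rec)
  core <- seq(sfreq, length(t) - sfreq)
  gain <- 20 * log10(sqrt(mean(out@signal[1, core]^2)) /
                     sqrt(mean(rec@signal[1, core]^2)))
  expect_lt(abs(gain), 1)
})

test_that("filtering an all-zero signal returns all zeros", {
  rec <- makeRec(matrix(0, nrow = 2, ncol = 2000))
  out <- bandpassNotch(rec)
  expect_equal(out@signal, rec@signal)
})

test_that("invalid band edges are rejected", {
  rec <- makeRec(matrix(0, nrow = 1, ncol = 2000), sfreq = 250)
  expect_error(bandpassNotch(rec, low = 0), "band edges")
  expect_error(bandpassNotch(rec, low = 60, high = 50), "band edges")
  expect_error(bandpassNotch(rec, high = 200), "band edges")
  expect_error(bandpassNotch(rec, notch = 70, high = 60), "notch")
})

test_that("epoching slices one window per event with correct labels", {
  sfreq <- 500
  nEv <- 6
  sig <- matrix(rnorm(3 * 20000), nrow = 3)
  events <- data.frame(sample = seq(100, by = 1200, length.out = nEv),
                       label = rep(c("a", "b"), nEv / 2))
  rec <- makeRec(sig, sfreq, events)
  ep <- epochRecording(rec, length = 2)
  expect_equal(dim(ep@signal), c(nEv, 3, 1000))
  expect_identical(trialLabels(ep), rep(c("a", "b"), nEv / 2))
  # pure-slice property: each epoch equals the corresponding raw window
  for (i in seq_len(nEv)) {
    w <- events$sample[i]:(events$sample[i] + 999)
    expect_identical(ep@signal[i, , ], sig[, w])
  }
})

test_that("epoch offset shifts the window start", {
  sfreq <- 500
  sig <- matrix(rnorm(2 * 5000), nrow = 2)
  events <- data.frame(sample = c(1000, 2500), label = c("a", "a"))
  rec <- makeRec(sig, sfreq, events)
  ep <- epochRecording(rec, length = 1, offset = 0.5)
  expect_identical(ep@signal[1, , ], sig[, 1250:1749])
})

test_that("zero events yield an empty epoch set, not an error", {
  rec <- makeRec(matrix(rnorm(2000), nrow = 1))
  ep <- epochRecording(rec, length = 2)
  expect_equal(nTrials(ep), 0)
})

test_that("out-of-bounds windows fail naming the offending events", {
  rec <- makeRec(matrix(rnorm(3000), nrow = 1), sfreq = 500,
                 events = data.frame(sample = c(100, 2999),
                                     label = c("ok", "late")))
  expect_error(epochRecording(rec, length = 2), "late")
})

test_that("filter-then-epoch equals epoching the filtered recording", {
  sfreq <- 500
  sig <- matrix(rnorm(2 * 8000), nrow = 2)
  events <- data.frame(sample = c(1500, 4000), label = c("a", "a"))
  rec <- makeRec(sig, sfreq, events)
  filtered <- bandpassNotch(rec)
  ep <- epochRecording(filtered, length = 2)
  for (i in 1:2) {
    w <- events$sample[i]:(events$sample[i] + 999)
    expect_identical(ep@signal[i, , ], filtered@signal[, w])
  }
})
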