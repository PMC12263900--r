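#' SynthConfig: parameters of the synthetic-EEG generator
#'
#' @slot nClasses number of imagined-word classes (>= 2).
#' @slot trialsPerClass trials generated per class.
#' @slot channels channel labels of the simulated cap.
#' @slot informativeChannels subset of \code{channels} carrying the
#'   class-discriminative sources.
#' @slot sfreq sampling rate (Hz).
#' @slot epochLength epoch duration (s).
#' @slot snr linear source-to-noise amplitude (RMS) ratio on informative
#'   channels; 0 generates pure noise.
#' @slot lineFreq power-line frequency (Hz).
#' @slot blinkRate blink transients per minute on the frontal channels.
#' @slot seed integer seed; all generator randomness flows from it.
#' @export
setClass("SynthConfig",
  representation(nClasses = "integer", trialsPerClass = "integer",
                 channels = "character", informativeChannels = "character",
                 sfreq = "numeric", epochLength = "numeric", snr = "numeric",
                 lineFreq = "numeric", blinkRate = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@nClasses < 2) msg <- c(msg, "nClasses must be >= 2")
  if (object@snr < 0) msg <- c(msg, "snr must be >= 0")
  if (object@snr > 0 && length(object@informativeChannels) == 0)
    msg <- c(msg, "informative channel set must be non-empty when snr > 0")
  if (!all(object@informativeChannels %in% object@channels))
    msg <- c(msg, "informativeChannels must be a subset of channels")
  if (object@blinkRate < 0) msg <- c(msg, "blinkRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Build a SynthConfig
#'
#' @param nClasses number of classes.
#' @param trialsPerClass trials per class.
#' @param channels channel labels (default: the full 64-channel montage).
#' @param informativeChannels channels that receive the class sources.
#' @param sfreq sampling rate in Hz.
#' @param epochLength epoch length in seconds.
#' @param snr linear source-to-noise RMS ratio (>= 0).
#' @param lineFreq line-interference frequency in Hz.
#' @param blinkRate blink transients per minute (0 disables blinks).
#' @param seed integer seed.
#' @return a [SynthConfig].
#' @export
synthConfig <- function(nClasses, trialsPerClass,
                        channels = channelNames(standardMontage()),
                        informativeChannels, sfreq = 128, epochLength = 2,
                        snr = 1, lineFreq = 50, blinkRate = 0, seed) {
  new("SynthConfig", nClasses = as.integer(nClasses),
      trialsPerClass = as.integer(trialsPerClass), channels = channels,
      informativeChannels = informativeChannels, sfreq = sfreq,
      epochLength = epochLength, snr = snr, lineFreq = lineFreq,
      blinkRate = blinkRate, seed = as.integer(seed))
}

# 1/f background: spectrally shape white Gaussian noise so amplitude falls
# as f^(-1/2) (power ~ 1/f), then rescale to the requested RMS.
pinkNoise <- function(n, rms) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1e-3, seq_len(n - 1))          # pseudo-DC kept near zero
  f <- pmin(f, n - f)                   # two-sided frequency index
  shape <- 1 / sqrt(pmax(f, 1))
  shape[1] <- 0
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

blinkWave <- function(nSamples, sfreq, centers) {
  x <- numeric(nSamples)
  width <- round(0.4 * sfreq)           # ~0.4 s positive half-wave
  for (c0 in centers) {
    idx <- seq(c0 - width %/% 2, c0 + width %/% 2)
    keep <- idx >= 1 & idx <= nSamples
    phase <- seq(0, pi, length.out = length(idx))
    x[idx[keep]] <- x[idx[keep]] + sin(phase[keep])
  }
  x
}

#' Generate a synthetic epoched EEG dataset
#'
#' Each trial contains a class-specific band-limited source: a sinusoid at
#' the class's center frequency (distinct per class, spread over 8-30 Hz)
#' with a Hann amplitude envelope and per-trial random phase, mixed only into
#' the informative channels with fixed per-channel gains. All channels carry
#' independent 1/f background noise, a common line-frequency sinusoid, and
#' optionally low-frequency positive blink transients on the most frontal
#' channels. The source amplitude is set so that the ratio of source RMS to
#' noise RMS on informative channels equals \code{snr}. Identical configs
#' give bit-identical output.
#'
#' @param config a [SynthConfig].
#' @return list with elements \code{data} ([EpochedData]) and \code{truth}
#'   ([SynthGroundTruth]).
#' @examples
#' cfg <- synthConfig(nClasses = 2, trialsPerClass = 5,
#'                    channels = c("C3", "Cz", "C4"),
#'                    informativeChannels = "C3", snr = 2, seed = 7)
#' d <- generateDataset(cfg)
#' dim(d$data@signal)
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  nCh <- length(config@channels)
  nSamp <- round(config@epochLength * config@sfreq)
  nTrials <- config@nClasses * config@trialsPerClass
  classes <- paste0("class", seq_len(config@nClasses))
  classFreqs <- stats::setNames(
    seq(9, 27, length.out = config@nClasses), classes)
  noiseRMS <- 10                         # microvolts
  lineRMS <- 5
  infIdx <- match(config@informativeChannels, config@channels)
  t <- seq(0, config@epochLength, length.out = nSamp + 1)[seq_len(nSamp)]
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = nSamp))
  frontal <- grep("^(Fp|AF|F)[0-9z]", config@channels)
  if (!length(frontal)) frontal <- seq_len(min(4, nCh))
  frontal <- utils::head(frontal, 4)

  out <- withSeed(config@seed, {
    # class-specific spatial pattern: each class projects onto its own
    # informative channel, as distinct cortical patches do for distinct
    # imagined words. Classes beyond the channel capacity stay unmodulated
    # (rest-like), which keeps every informative channel's contribution
    # unique: without the rest class, a removed channel's class would remain
    # identifiable by the mere absence of any source pattern. With more
    # informative channels than classes, channels are dealt round-robin.
    nInf <- length(infIdx)
    gains <- matrix(0, config@nClasses, nInf,
                    dimnames = list(classes, config@informativeChannels))
    if (nInf > 0 && nInf <= config@nClasses) {
      for (j in seq_len(nInf)) gains[j, j] <- stats::runif(1, 0.9, 1.1)
    } else if (nInf > 0) {
      for (j in seq_len(nInf))
        gains[(j - 1) %% config@nClasses + 1, j] <- stats::runif(1, 0.9, 1.1)
    }
    labels <- rep(classes, each = config@trialsPerClass)
    ord <- sample(nTrials)
    labels <- labels[ord]
    sig <- array(0, dim = c(nTrials, nCh, nSamp))
    for (tr in seq_len(nTrials)) {
      # class source with trial-to-trial variability: random phase, center
      # frequency jitter, and Rayleigh-distributed amplitude (unit mean), so
      # some trials carry weak imagery just as real recordings do
      if (config@snr > 0) {
        f <- classFreqs[labels[tr]] + stats::rnorm(1, 0, 1.2)
        phase <- stats::runif(1, 0, 2 * pi)
        amp <- sqrt(2 / pi) * sqrt(-2 * log(stats::runif(1)))
        src <- sin(2 * pi * f * t + phase) * hann
        src <- src / sqrt(mean(src^2))   # unit RMS
        for (j in seq_along(infIdx))
          sig[tr, infIdx[j], ] <- src * amp * config@snr * noiseRMS *
            gains[labels[tr], j]
      }
      # 1/f noise, per channel independent
      for (ch in seq_len(nCh))
        sig[tr, ch, ] <- sig[tr, ch, ] + pinkNoise(nSamp, noiseRMS)
      # common line interference
      linePhase <- stats::runif(1, 0, 2 * pi)
      line <- sqrt(2) * lineRMS * sin(2 * pi * config@lineFreq * t + linePhase)
      sig[tr, , ] <- sweep(sig[tr, , ], 2, line, "+")
      # blink transients on frontal channels
      if (config@blinkRate > 0) {
        nBlinks <- stats::rpois(1, config@blinkRate * config@epochLength / 60)
        if (nBlinks > 0) {
          centers <- round(stats::runif(nBlinks, 1, nSamp))
          wave <- 60 * blinkWave(nSamp, config@sfreq, centers)
          for (ch in frontal) sig[tr, ch, ] <- sig[tr, ch, ] + wave
        }
      }
    }
    list(sig = sig, labels = labels, gains = gains)
  })

  data <- new("EpochedData", signal = out$sig, labels = out$labels,
              sfreq = config@sfreq, channelNames = config@channels,
              epochLength = config@epochLength)
  truth <- new("SynthGroundTruth",
               informativeChannels = config@informativeChannels,
               classFreqs = classFreqs, channelGains = out$gains,
               snr = config@snr, seed = config@seed)
  list(data = data, truth = truth)
}

fixturePresets <- list(
  tiny = list(nClasses = 2L, trialsPerClass = 10L,
              channels = c("C3", "Cz", "C4", "Pz"),
              informativeChannels = c("C3", "C4"),
              sfreq = 128, snr = 2, seed = 101L),
  small = list(nClasses = 5L, trialsPerClass = 20L,
               channels = c("F3", "Fz", "F4", "FC5", "FC6", "C3", "Cz", "C4",
                            "CP5", "CP6", "P3", "Pz", "P4", "PO3", "PO4", "Oz"),
               informativeChannels = c("C3", "Cz", "C4", "Pz"),
               sfreq = 128, snr = 2, seed = 202L),
  `study-like` = list(nClasses = 5L, trialsPerClass = 70L,
                      channels = NULL,   # full montage
                      informativeChannels = c("F7", "FT7", "FC5", "T7", "C5",
                                              "C3", "Cz", "TP7", "CP5", "CP3",
                                              "P5", "P3"),
                      sfreq = 250, snr = 1, seed = 303L)
)

#' Deterministic synthetic fixtures
#'
#' Three presets used throughout the test suite: \code{"tiny"} (4 channels,
#' 2 classes, 20 trials), \code{"small"} (16 channels of which 4 informative,
#' 5 classes, 100 trials) and \code{"study-like"} (the full 64-channel
#' montage, 5 classes, 70 trials per class = 350 trials, 2-s epochs).
#'
#' @param name one of \code{"tiny"}, \code{"small"}, \code{"study-like"}.
#' @param snr optional override of the preset's source-to-noise ratio.
#' @param seed optional override of the preset's seed.
#' @return list with \code{data} and \code{truth}, as [generateDataset()].
#' @export
makeFixture <- function(name, snr = NULL, seed = NULL) {
  if (!name %in% names(fixturePresets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(fixturePresets), collapse = ", "))
  p <- fixturePresets[[name]]
  if (is.null(p$channels)) p$channels <- channelNames(standardMontage())
  cfg <- synthConfig(nClasses = p$nClasses, trialsPerClass = p$trialsPerClass,
                     channels = p$channels,
                     informativeChannels = p$informativeChannels,
                     sfreq = p$sfreq, snr = if (is.null(snr)) p$snr else snr,
                     seed = if (is.null(seed)) p$seed else seed)
  generateDataset(cfg)
}

#' Write / read a fixture as plain text
#'
#' Serializes an epoched dataset with its ground truth as a CSV signal table
#' (one row per trial x channel) plus a JSON sidecar carrying labels, channel
#' names, sampling rate and generator parameters.
#'
#' @param fixture list with \code{data} and \code{truth}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- fixture$data
  dims <- dim(d@signal)
  flat <- matrix(aperm(d@signal, c(3, 2, 1)), nrow = dims[1] * dims[2],
                 byrow = TRUE)
  utils::write.csv(flat, file.path(dir, "signal.csv"), row.names = FALSE)
  gt <- fixture$truth
  side <- list(trials = dims[1], channels = d@channelNames,
               samples = dims[3], labels = d@labels, sfreq = d@sfreq,
               epochLength = d@epochLength,
               truth = list(informativeChannels = gt@informativeChannels,
                            classFreqs = as.list(gt@classFreqs),
                            channelGains = gt@channelGains,
                            snr = gt@snr, seed = gt@seed))
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeFixture
#' @param dir directory previously written by [writeFixture()].
#' @export
readFixture <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.csv(file.path(dir, "signal.csv")))
  nCh <- length(side$channels)
  sig <- aperm(array(t(flat), dim = c(side$samples, nCh, side$trials)),
               c(3, 2, 1))
  data <- new("EpochedData", signal = sig, labels = side$labels,
              sfreq = side$sfreq, channelNames = side$channels,
              epochLength = side$epochLength)
  gains <- side$truth$channelGains
  if (!is.matrix(gains)) gains <- matrix(unlist(gains), nrow = 1)
  dimnames(gains) <- list(names(side$truth$classFreqs),
                          side$truth$informativeChannels)
  truth <- new("SynthGroundTruth",
               informativeChannels = side$truth$informativeChannels,
               classFreqs = unlist(side$truth$classFreqs),
               channelGains = gains,
               snr = side$truth$snr, seed = as.integer(side$truth$seed))
  list(data = data, truth = truth)
}
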