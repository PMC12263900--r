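# Minimal readers for the two interchange formats the study datasets use.
# Only the subset needed for epoched decoding is implemented: multiplexed
# binary BrainVision (IEEE float32 / int16) with stimulus markers, and
# EDF int16 signals with events taken from a marker channel.

parseVhdrIni <- function(lines) {
  section <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln) && section != "") {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

readBrainVision <- function(vhdrPath) {
  if (!file.exists(vhdrPath)) stop("header file not found: ", vhdrPath)
  ini <- parseVhdrIni(readLines(vhdrPath, warn = FALSE))
  ci <- ini[["Common Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: ", vhdrPath)
  dir <- dirname(vhdrPath)
  dataFile <- file.path(dir, ci$DataFile)
  markerFile <- if (!is.null(ci$MarkerFile)) file.path(dir, ci$MarkerFile)
  if (!file.exists(dataFile)) stop("data file missing: ", dataFile)
  if (toupper(ci$DataOrientation %||% "MULTIPLEXED") != "MULTIPLEXED")
    stop("only multiplexed orientation is supported")
  nCh <- as.integer(ci$NumberOfChannels)
  sfreq <- 1e6 / as.numeric(ci$SamplingInterval)
  chans <- ini[["Channel Infos"]]
  labels <- character(nCh); res <- rep(1, nCh)
  for (i in seq_len(nCh)) {
    parts <- strsplit(chans[[paste0("Ch", i)]], ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) res[i] <- as.numeric(parts[3])
  }
  fmt <- toupper(ini[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
  nBytes <- file.size(dataFile)
  raw <- if (fmt == "IEEE_FLOAT_32")
    readBin(dataFile, "numeric", n = nBytes / 4, size = 4, endian = "little")
  else if (fmt == "INT_16")
    readBin(dataFile, "integer", n = nBytes / 2, size = 2, signed = TRUE,
            endian = "little")
  else stop("unsupported binary format: ", fmt)
  sig <- matrix(raw, nrow = nCh) * res
  events <- data.frame(sample = integer(), label = character())
  if (!is.null(markerFile) && file.exists(markerFile)) {
    mk <- parseVhdrIni(readLines(markerFile, warn = FALSE))[["Marker Infos"]]
    for (nm in names(mk)) {
      parts <- strsplit(mk[[nm]], ",", fixed = TRUE)[[1]]
      if (toupper(parts[1]) == "STIMULUS")
        events <- rbind(events,
                        data.frame(sample = as.integer(parts[3]),
                                   label = parts[2]))
    }
  }
  new("ContinuousRecording", signal = sig, sfreq = sfreq,
      channelNames = labels, events = events)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

padAscii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readAscii <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  readAscii(8 + 80 + 80 + 8 + 8)
  nHeader <- as.integer(readAscii(8))
  readAscii(44)
  nRecords <- as.integer(readAscii(8))
  recDur <- as.numeric(readAscii(8))
  nSig <- as.integer(readAscii(4))
  field <- function(w) vapply(seq_len(nSig), function(i) readAscii(w), "")
  labels <- field(16); field(80); field(8)
  physMin <- as.numeric(field(8)); physMax <- as.numeric(field(8))
  digMin <- as.numeric(field(8)); digMax <- as.numeric(field(8))
  field(80)
  sampPerRec <- as.integer(field(8)); field(32)
  if (length(unique(sampPerRec)) != 1)
    stop("per-signal sampling rates differ; not supported")
  spr <- sampPerRec[1]
  sfreq <- spr / recDur
  sig <- matrix(0, nSig, nRecords * spr)
  for (r in seq_len(nRecords)) {
    for (s in seq_len(nSig)) {
      v <- readBin(con, "integer", n = spr, size = 2, signed = TRUE,
                   endian = "little")
      scale <- (physMax[s] - physMin[s]) / (digMax[s] - digMin[s])
      sig[s, ((r - 1) * spr + 1):(r * spr)] <-
        (v - digMin[s]) * scale + physMin[s]
    }
  }
  isMarker <- grepl("marker|status|^sti", labels, ignore.case = TRUE)
  events <- data.frame(sample = integer(), label = character())
  if (any(isMarker)) {
    mk <- round(sig[which(isMarker)[1], ])
    onsets <- which(mk != 0 & c(0, utils::head(mk, -1)) == 0)
    events <- data.frame(sample = onsets,
                         label = paste0("S", mk[onsets]))
  }
  list(rec = new("ContinuousRecording",
                 signal = sig[!isMarker, , drop = FALSE], sfreq = sfreq,
                 channelNames = labels[!isMarker], events = events),
       allLabels = labels, droppedChannels = labels[isMarker])
}

#' Write a ContinuousRecording as EDF
#'
#' 16-bit EDF with one extra \code{Marker} channel encoding the events
#' (value = numeric suffix of the label at the event sample). Intended for
#' interoperability round-trips; one data record per second.
#'
#' @param rec a [ContinuousRecording].
#' @param path output path.
#' @export
writeEDF <- function(rec, path) {
  spr <- as.integer(round(rec@sfreq))
  nRecords <- ncol(rec@signal) %/% spr
  nKeep <- nRecords * spr
  mk <- numeric(nKeep)
  if (nrow(rec@events)) {
    num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", rec@events$label)))
    num[is.na(num)] <- 1
    ok <- rec@events$sample <= nKeep
    mk[rec@events$sample[ok]] <- num[ok]
  }
  sig <- rbind(rec@signal[, seq_len(nKeep), drop = FALSE], mk)
  labels <- c(rec@channelNames, "Marker")
  nSig <- nrow(sig)
  physMin <- floor(apply(sig, 1, min)); physMax <- ceiling(apply(sig, 1, max))
  physMax[physMax <= physMin] <- physMin[physMax <= physMin] + 1
  digMin <- rep(-32768, nSig); digMax <- rep(32767, nSig)
  con <- file(path, "wb")
  on.exit(close(con))
  wA <- function(x, w) writeBin(charToRaw(padAscii(x, w)), con)
  wA("0", 8); wA("synthetic", 80); wA("synthetic", 80)
  wA("01.01.26", 8); wA("00.00.00", 8)
  wA(256 + nSig * 256, 8); wA("", 44); wA(nRecords, 8); wA("1", 8)
  wA(nSig, 4)
  for (s in labels) wA(s, 16)
  for (s in labels) wA("", 80)
  for (s in labels) wA("uV", 8)
  for (v in physMin) wA(v, 8)
  for (v in physMax) wA(v, 8)
  for (v in digMin) wA(v, 8)
  for (v in digMax) wA(v, 8)
  for (s in labels) wA("", 80)
  for (s in labels) wA(spr, 8)
  for (s in labels) wA("", 32)
  for (r in seq_len(nRecords)) {
    for (s in seq_len(nSig)) {
      x <- sig[s, ((r - 1) * spr + 1):(r * spr)]
      d <- round((x - physMin[s]) / (physMax[s] - physMin[s]) *
                   (digMax[s] - digMin[s]) + digMin[s])
      writeBin(as.integer(d), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Load a continuous recording from disk
#'
#' Reads a BrainVision triplet (pass the .vhdr path) or an EDF file, matches
#' channels against the montage, and drops unmatched channels with a warning
#' naming them. Errors if the sampling rate is at or below 120 Hz (the 60 Hz
#' band edge must stay below Nyquist).
#'
#' @param path .vhdr or .edf file path.
#' @param format \code{"brainvision"} or \code{"edf"}; guessed from the
#'   extension by default.
#' @param montage a [Montage] to match channels against (default: the
#'   standard 64-channel layout).
#' @return a [ContinuousRecording] with montage channels only.
#' @export
loadRecording <- function(path, format = c("auto", "brainvision", "edf"),
                          montage = standardMontage()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vhdr$", path, ignore.case = TRUE)) "brainvision"
              else "edf"
  rec <- if (format == "brainvision") readBrainVision(path) else readEDF(path)$rec
  if (rec@sfreq <= 120)
    stop("sampling rate must exceed 120 Hz, got ", rec@sfreq)
  known <- rec@channelNames %in% channelNames(montage)
  if (!all(known)) {
    warning("dropping channels not in the montage: ",
            paste(rec@channelNames[!known], collapse = ", "))
    rec <- selectChannels(rec, rec@channelNames[known])
  }
  rec
}
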