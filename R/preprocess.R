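#' Band-pass and notch filter a continuous recording
#'
#' Applies a 4th-order Butterworth band-pass followed by a biquad notch
#' (quality factor 30), both run forward-backward (zero phase) so that event
#' alignment is preserved. The normative contract is attenuation, not the
#' realization: a pure tone at the notch frequency loses at least 20 dB RMS,
#' a mid-passband tone stays within 1 dB.
#'
#' @param rec a [ContinuousRecording].
#' @param low,high band-pass edges in Hz (defaults 0.5 and 60).
#' @param notch notch center frequency in Hz (default 50).
#' @return the filtered [ContinuousRecording]; same shape and events.
#' @export
bandpassNotch <- function(rec, low = 0.5, high = 60, notch = 50) {
  stopifnot(is(rec, "ContinuousRecording"))
  nyq <- rec@sfreq / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < sfreq/2")
  if (!(notch > low && notch < high))
    stop("notch frequency must lie inside the pass band")
  bp <- signal::butter(2, c(low, high) / nyq, type = "pass")
  # RBJ biquad notch, Q = 30
  w0 <- pi * notch / nyq
  alpha <- sin(w0) / (2 * 30)
  bN <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  aN <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  out <- rec@signal
  for (ch in seq_len(nrow(out))) {
    x <- signal::filtfilt(bp, out[ch, ])
    out[ch, ] <- signal::filtfilt(signal::Arma(b = bN, a = aN), x)
  }
  new("ContinuousRecording", signal = out, sfreq = rec@sfreq,
      channelNames = rec@channelNames, events = rec@events)
}

#' Cut a continuous recording into fixed-length epochs
#'
#' Slices one window per event: the event's sample (plus \code{offset}) is
#' the first sample of the epoch, and windows are half-open of
#' \code{round(length * sfreq)} samples. Epoch extraction is a pure slice.
#'
#' @param rec a [ContinuousRecording] with events.
#' @param length epoch length in seconds (default 2).
#' @param offset onset shift relative to the event marker, in seconds.
#' @return an [EpochedData] with one trial per event (0 events give an empty
#'   object, not an error).
#' @export
epochRecording <- function(rec, length = 2.0, offset = 0.0) {
  stopifnot(is(rec, "ContinuousRecording"))
  nSamp <- round(length * rec@sfreq)
  ev <- rec@events
  if (nrow(ev) == 0) {
    return(new("EpochedData",
               signal = array(0, dim = c(0, nrow(rec@signal), nSamp)),
               labels = character(), sfreq = rec@sfreq,
               channelNames = rec@channelNames, epochLength = length))
  }
  start <- ev$sample + round(offset * rec@sfreq)
  end <- start + nSamp - 1
  bad <- which(start < 1 | end > ncol(rec@signal))
  if (base::length(bad))
    stop("epoch window out of bounds for event(s) ",
         paste0("#", bad, " (sample ", ev$sample[bad], ", label '",
                ev$label[bad], "')", collapse = ", "))
  sig <- array(0, dim = c(nrow(ev), nrow(rec@signal), nSamp))
  for (i in seq_len(nrow(ev)))
    sig[i, , ] <- rec@signal[, start[i]:end[i]]
  new("EpochedData", signal = sig, labels = as.character(ev$label),
      sfreq = rec@sfreq, channelNames = rec@channelNames,
      epochLength = length)
}
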