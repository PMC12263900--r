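# Discrete wavelet transform with the biorthogonal 2.2 analysis bank.
# Decimated pyramid with symmetric (half-sample) boundary extension; the
# high-pass taps sum to zero exactly in double precision, so constants are
# annihilated bit-exactly.

bior22DecLo <- c(0, -0.1767766952966369, 0.3535533905932738,
                 1.0606601717798212, 0.3535533905932738, -0.1767766952966369)
bior22DecHi <- c(0, 0.3535533905932738, -0.7071067811865476,
                 0.3535533905932738, 0, 0)

# One analysis step: symmetric-pad, filter, downsample by 2.
dwtStep <- function(x, filt) {
  fl <- length(filt)
  n <- length(x)
  pad <- c(rev(x[seq_len(fl - 1)]), x, rev(x[n - seq_len(fl - 1) + 1]))
  full <- stats::filter(pad, rev(filt), method = "convolution", sides = 1)
  full <- full[fl:(fl + n + fl - 2)]
  full[seq(2, length(full), by = 2)]
}

#' Multi-level DWT subband decomposition (bior2.2)
#'
#' @param x numeric signal.
#' @param levels decomposition depth.
#' @return list with \code{approximation} (coarsest) and \code{details}
#'   (list, finest level last).
#' @export
dwtDecompose <- function(x, levels = 4) {
  stopifnot(levels >= 1)
  if (length(x) < 2^levels)
    stop("signal too short for a ", levels, "-level decomposition")
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    details[[lev]] <- dwtStep(a, bior22DecHi)
    a <- dwtStep(a, bior22DecLo)
  }
  list(approximation = a, details = rev(details))
}

#' Relative wavelet energy of a signal
#'
#' Fraction of total wavelet energy carried by each subband of a
#' \code{levels}-deep decomposition (approximation first, then details from
#' coarsest to finest). Sums to 1 for any non-zero signal.
#'
#' @inheritParams dwtDecompose
#' @return numeric vector of length \code{levels + 1}.
#' @export
relativeWaveletEnergy <- function(x, levels = 4) {
  dec <- dwtDecompose(x, levels)
  en <- c(sum(dec$approximation^2),
          vapply(dec$details, function(d) sum(d^2), numeric(1)))
  tot <- sum(en)
  if (tot == 0) c(1, rep(0, levels)) else en / tot
}

#' Wavelet feature vector of a single-channel epoch
#'
#' The per-channel building block of the \code{wav} feature configuration:
#' maximum, minimum, mean and standard deviation of the raw series, followed
#' by the relative wavelet energy of the \code{levels + 1} subbands of a
#' bior2.2 decomposition.
#'
#' @param x single-channel epoch (numeric vector).
#' @param levels decomposition depth (default 4).
#' @return named numeric vector of length \code{4 + levels + 1}.
#' @export
dwtChannelFeatures <- function(x, levels = 4) {
  rwe <- relativeWaveletEnergy(x, levels)
  out <- c(max(x), min(x), mean(x), stats::sd(x), rwe)
  names(out) <- c("max", "min", "mean", "std",
                  "rwe_A", paste0("rwe_D", seq(levels, 1)))
  out
}
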