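# Per-channel time/frequency feature vector: band power spectral intensity
# and relative intensity ratio over the five classical EEG bands, plus
# fractal, complexity and long-range-dependence measures. Degenerate
# (zero-variance) inputs return defined sentinel values, never NaN, so that
# downstream classifiers stay total.

#' Default EEG band edges
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-60 Hz; chosen to
#' tile the 0.5-60 Hz filtered range.
#' @return named list of two-element numeric vectors.
#' @export
defaultBandEdges <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 60))
}

bandPSI <- function(x, sfreq, bandEdges) {
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n %/% 2)
  freqs <- k * sfreq / n
  mag2 <- Mod(X[k + 1])^2
  vapply(bandEdges, function(b) sum(mag2[freqs >= b[1] & freqs < b[2]]),
         numeric(1))
}

petrosianFD <- function(x) {
  n <- length(x)
  d <- diff(x)
  nd <- sum(d[-length(d)] * d[-1] < 0)
  denom <- log10(n) + log10(n / (n + 0.4 * nd))
  if (denom == 0) 1 else log10(n) / denom
}

higuchiFD <- function(x, kmax = 8) {
  n <- length(x)
  L <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) { lm[m] <- 0; next }
      lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (k * (length(idx) - 1) * k)
    }
    L[k] <- mean(lm)
  }
  ok <- L > 0
  if (sum(ok) < 2) return(0)
  lx <- log(1 / seq_len(kmax))[ok]
  ly <- log(L[ok])
  stats::coef(stats::lm(ly ~ lx))[[2]]
}

hjorthParams <- function(x) {
  v0 <- stats::var(x)
  if (v0 == 0) return(c(mobility = 0, complexity = 0))
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- stats::var(d1)
  mob <- sqrt(v1 / v0)
  comp <- if (v1 == 0) 0 else sqrt(stats::var(d2) / v1) / mob
  c(mobility = mob, complexity = comp)
}

skewnessVal <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^3) / (mean((x - mean(x))^2))^1.5
}

fisherInfo <- function(x, dim = 20, lag = 2) {
  n <- length(x) - (dim - 1) * lag
  if (n < 2) return(0)
  emb <- sapply(seq_len(dim), function(j) x[(j - 1) * lag + seq_len(n)])
  sv <- svd(emb, nu = 0, nv = 0)$d
  tot <- sum(sv)
  if (tot == 0) return(0)
  p <- sv / tot
  keep <- p[-length(p)] > 0
  sum((diff(p)^2 / p[-length(p)])[keep])
}

approxEntropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  phi <- function(mm) {
    nv <- n - mm + 1
    emb <- sapply(seq_len(mm), function(j) x[j:(j + nv - 1)])
    if (is.null(dim(emb))) emb <- matrix(emb, ncol = 1)
    # Chebyshev distances between all embedding vectors
    d <- matrix(0, nv, nv)
    for (j in seq_len(mm))
      d <- pmax(d, abs(outer(emb[, j], emb[, j], "-")))
    mean(log(rowMeans(d <= r)))
  }
  phi(m) - phi(m + 1)
}

dfaExponent <- function(x) {
  n <- length(x)
  y <- cumsum(x - mean(x))
  sizes <- unique(pmin(4 * 2^(0:30), n %/% 4))
  sizes <- sizes[sizes >= 4]
  if (length(sizes) < 2) return(0)
  F <- vapply(sizes, function(s) {
    nSeg <- n %/% s
    res <- vapply(seq_len(nSeg), function(i) {
      seg <- y[((i - 1) * s + 1):(i * s)]
      tt <- seq_len(s)
      fit <- stats::lm.fit(cbind(1, tt), seg)
      sqrt(mean(fit$residuals^2))
    }, numeric(1))
    sqrt(mean(res^2))
  }, numeric(1))
  ok <- F > 0
  if (sum(ok) < 2) return(0)
  stats::coef(stats::lm(log(F[ok]) ~ log(sizes[ok])))[[2]]
}

hurstExponent <- function(x) {
  n <- length(x)
  sizes <- unique(pmin(8 * 2^(0:30), n))
  sizes <- sizes[sizes >= 8]
  if (length(sizes) < 2) return(0)
  rs <- vapply(sizes, function(s) {
    nSeg <- n %/% s
    vals <- vapply(seq_len(nSeg), function(i) {
      seg <- x[((i - 1) * s + 1):(i * s)]
      z <- cumsum(seg - mean(seg))
      r <- max(z) - min(z)
      sdev <- stats::sd(seg)
      if (sdev == 0) NA_real_ else r / sdev
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2) return(0)
  stats::coef(stats::lm(log(rs[ok]) ~ log(sizes[ok])))[[2]]
}

#' Time/frequency feature vector of a single-channel epoch
#'
#' Computes, per channel: power spectral intensity (PSI) over the five EEG
#' bands, relative intensity ratio (RIR) over the same bands, Petrosian and
#' Higuchi fractal dimensions, Hjorth mobility and complexity, band spectral
#' entropy, skewness, Fisher information of a delay embedding, approximate
#' entropy, the detrended-fluctuation exponent and the Hurst exponent -
#' 20 values spanning the classical time/frequency feature families.
#'
#' @param x single-channel epoch (numeric vector, >= 64 samples).
#' @param sfreq sampling rate in Hz.
#' @param bandEdges named list of band edges (default [defaultBandEdges()]).
#' @param higuchiKmax maximum delay for the Higuchi curve-length fit.
#' @param apenM,apenRfactor approximate-entropy embedding dimension and
#'   tolerance factor (r = apenRfactor * sd).
#' @param fisherDim,fisherLag delay-embedding dimension and lag for the
#'   Fisher-information feature.
#' @return named numeric vector of 20 finite values.
#' @export
featvecChannelFeatures <- function(x, sfreq, bandEdges = defaultBandEdges(),
                                   higuchiKmax = 8, apenM = 2,
                                   apenRfactor = 0.2, fisherDim = 20,
                                   fisherLag = 2) {
  if (length(x) < 64) stop("need at least 64 samples")
  psi <- bandPSI(x, sfreq, bandEdges)
  tot <- sum(psi)
  rir <- if (tot > 0) psi / tot else psi * 0
  specEnt <- if (tot > 0) {
    p <- rir[rir > 0]
    -sum(p * log(p)) / log(length(bandEdges))
  } else 0
  hj <- hjorthParams(x)
  apen <- if (stats::sd(x) == 0) 0
          else approxEntropy(x, apenM, apenRfactor * stats::sd(x))
  out <- c(stats::setNames(psi, paste0("psi_", names(bandEdges))),
           stats::setNames(rir, paste0("rir_", names(bandEdges))),
           petrosian = petrosianFD(x),
           higuchi = higuchiFD(x, higuchiKmax),
           hjorth_mobility = unname(hj["mobility"]),
           hjorth_complexity = unname(hj["complexity"]),
           spectral_entropy = specEnt,
           skewness = skewnessVal(x),
           fisher_info = fisherInfo(x, fisherDim, fisherLag),
           apen = apen,
           dfa = dfaExponent(x),
           hurst = hurstExponent(x))
  stopifnot(all(is.finite(out)))
  out
}
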