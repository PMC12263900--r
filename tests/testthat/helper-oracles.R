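# Independent oracles used across the suite. These deliberately re-derive
# quantities by the most literal route available (double loops, dense grids,
# exhaustive dynamic programming) and stay independent of the package's own
# implementation paths.

# Literal double-loop evaluation of the per-electrode ICA voting score:
# component n gives 2 points to the channel holding its maximum if the
# component is in L, 1 point otherwise.
oracleIcaScores <- function(components, lFraction = 0.13) {
  N <- nrow(components)
  M <- ncol(components)
  norms <- apply(components, 1, function(r) sqrt(sum(r^2)))
  nL <- max(1, round(lFraction * N))
  inL <- rank(-norms, ties.method = "first") <= nL
  scores <- integer(M)
  for (n in seq_len(N)) {
    mx <- max(components[n, ])
    hit <- which(components[n, ] == mx)[1]
    for (i in seq_len(M)) {
      if (i == hit)
        scores[i] <- scores[i] + (if (inL[n]) 2L else 1L)
    }
  }
  scores
}

# Dense-grid Mamdani centroid: recomputes fuzzification, rule firing and
# aggregation from the config description and integrates on its own much
# finer grid with trapezoid weights.
oracleFisScore <- function(accuracy, nRemoved, subjectMax, C, config,
                           gridN = 200001) {
  trap <- function(x, p) {
    if (x <= p[1]) return(if (p[1] == p[2] && x == p[1]) 1 else 0)
    if (x >= p[4]) return(if (p[3] == p[4] && x == p[4]) 1 else 0)
    if (x < p[2]) return((x - p[1]) / (p[2] - p[1]))
    if (x <= p[3]) return(1)
    (p[4] - x) / (p[4] - p[3])
  }
  trapVec <- function(xs, p) vapply(xs, trap, numeric(1), p = p)
  a <- min(max(accuracy / subjectMax, 0), 1)
  r <- min(max(nRemoved / (C - 1), 0), 1)
  grid <- seq(0, 1, length.out = gridN)
  agg <- numeric(gridN)
  for (i in seq_len(nrow(config$rules))) {
    s <- min(trap(a, config$accuracyShapes[[config$rules$accuracy[i]]]),
             trap(r, config$removalShapes[[config$rules$removal[i]]]))
    if (s > 0)
      agg <- pmax(agg, pmin(s, trapVec(grid,
               config$outputShapes[[config$rules$output[i]]])))
  }
  if (all(agg == 0)) return(0)
  w <- c(0.5, rep(1, gridN - 2), 0.5)
  sum(w * grid * agg) / sum(w * agg)
}

# Exact 1-D k-means by dynamic programming over sorted values (optimal
# clusters of 1-D data are contiguous runs).
oracleKmeans1d <- function(x, k) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  segCost <- function(i, j) {  # cost of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in seq_len(n)) D[1, j] <- segCost(1, j)
  if (k > 1) for (m in 2:k) {
    for (j in m:n) {
      for (i in m:j) {
        c <- D[m - 1, i - 1] + segCost(i, j)
        if (c < D[m, j]) { D[m, j] <- c; B[m, j] <- i }
      }
    }
  }
  # recover assignment over sorted order, then undo the sort
  bounds <- integer(k + 1)
  bounds[k + 1] <- n
  j <- n
  for (m in k:2) {
    bounds[m] <- B[m, j] - 1L
    j <- B[m, j] - 1L
  }
  bounds[1] <- 0L
  assignSorted <- integer(n)
  for (m in seq_len(k))
    if (bounds[m + 1] > bounds[m])
      assignSorted[(bounds[m] + 1):bounds[m + 1]] <- m
  assign <- integer(n)
  assign[ord] <- assignSorted
  list(sse = D[k, n], assignments = assign)
}

# Subband energies of a 1-D signal by direct FFT band splitting: energy in
# the dyadic bands a levels-deep wavelet pyramid targets.
oracleDyadicBandEnergy <- function(x, sfreq, levels) {
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (0:(n - 1)) * sfreq / n
  freqs <- pmin(freqs, sfreq - freqs)
  # approximation [0, sfreq/2^(L+1)), then details coarse to fine up to
  # the finest band [sfreq/4, sfreq/2)
  bands <- c(0, sfreq / 2^((levels + 1):2))
  en <- numeric(levels + 1)
  for (b in seq_len(levels + 1)) {
    lo <- bands[b]
    hi <- if (b == levels + 1) sfreq / 2 else bands[b + 1]
    sel <- freqs >= lo & freqs < hi
    en[b] <- sum(Mod(X[sel])^2) / n
  }
  en   # approximation band first, then details coarse -> fine
}

# Shared tiny fixtures under fixed seeds.
tinyFixture <- function(seed = NULL) makeFixture("tiny", seed = seed)
smallFixture <- function(snr = NULL, seed = NULL)
  makeFixture("small", snr = snr, seed = seed)
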