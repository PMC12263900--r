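# FastICA (symmetric orthogonalization, logcosh contrast), hand-written so
# the ICA electrode-reduction path is fully deterministic under a seed.

#' FastICA decomposition
#'
#' @param X data matrix, channels x samples.
#' @param nComponents number of components (default: all channels).
#' @param seed integer seed for the random initial rotation.
#' @param maxIter maximum fixed-point iterations.
#' @param tol convergence tolerance on the rotation update.
#' @return list with \code{unmixing} (components x channels, applies to raw
#'   X), \code{mixing} (channels x components back-projection),
#'   \code{converged} flag.
#' @export
fastICA <- function(X, nComponents = nrow(X), seed = 1, maxIter = 200,
                    tol = 1e-4) {
  stopifnot(is.matrix(X), nComponents >= 1, nComponents <= nrow(X))
  Xc <- X - rowMeans(X)
  C <- tcrossprod(Xc) / ncol(Xc)
  e <- eigen(C, symmetric = TRUE)
  keep <- which(e$values > max(e$values) * 1e-12)[seq_len(nComponents)]
  if (anyNA(keep)) stop("rank of the data is below nComponents")
  K <- diag(1 / sqrt(e$values[keep]), length(keep)) %*% t(e$vectors[, keep])
  Z <- K %*% Xc                              # whitened
  W <- withSeed(seed, {
    matrix(stats::rnorm(nComponents^2), nComponents, nComponents)
  })
  W <- symmetricOrth(W)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    WX <- W %*% Z
    G <- tanh(WX)
    gPrime <- 1 - G^2
    W1 <- (G %*% t(Z)) / ncol(Z) - diag(rowMeans(gPrime)) %*% W
    W1 <- symmetricOrth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  unmixing <- W %*% K
  mixing <- pseudoInverse(unmixing)
  # fix signs: largest-|loading| channel of each back-projection positive
  for (j in seq_len(ncol(mixing))) {
    i <- which.max(abs(mixing[, j]))
    if (mixing[i, j] < 0) {
      mixing[, j] <- -mixing[, j]
      unmixing[j, ] <- -unmixing[j, ]
    }
  }
  list(unmixing = unmixing, mixing = mixing, converged = converged)
}

symmetricOrth <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

# Moore-Penrose pseudoinverse via SVD (square W is simply inverted).
pseudoInverse <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > max(s$d) * tol
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
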