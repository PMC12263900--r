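# Common spatial patterns. Two classes: generalized eigenproblem of the
# class covariances solved by whitening. More classes: approximate joint
# diagonalization (Pham's algorithm) of the per-class mean covariances,
# with components ordered by an information criterion on the projected
# class variances; a one-vs-rest eigen fallback covers AJD non-convergence.

classCovariances <- function(epochs) {
  labs <- unique(trialLabels(epochs))
  nCh <- nChannels(epochs)
  covs <- array(0, dim = c(length(labs), nCh, nCh))
  for (ci in seq_along(labs)) {
    idx <- which(trialLabels(epochs) == labs[ci])
    acc <- matrix(0, nCh, nCh)
    for (tr in idx) {
      x <- epochs@signal[tr, , , drop = TRUE]
      if (is.null(dim(x))) x <- matrix(x, nrow = 1)
      x <- x - rowMeans(x)
      S <- tcrossprod(x) / ncol(x)
      acc <- acc + S / sum(diag(S))      # trace-normalized per trial
    }
    covs[ci, , ] <- acc / length(idx)
  }
  # ridge keeps low-rank toys non-singular
  for (ci in seq_along(labs)) {
    eps <- 1e-10 * sum(diag(covs[ci, , ])) / nCh
    covs[ci, , ] <- covs[ci, , ] + diag(eps, nCh)
  }
  list(covs = covs, classes = labs,
       weights = as.vector(table(factor(trialLabels(epochs), levels = labs))))
}

# Pham (2000) approximate joint diagonalization of SPD matrices.
# Returns V such that V %*% C_k %*% t(V) is approximately diagonal for all k.
ajdPham <- function(covs, eps = 1e-8, maxIter = 30) {
  K <- dim(covs)[1]
  n <- dim(covs)[2]
  A <- matrix(0, n, n * K)
  for (k in seq_len(K)) A[, ((k - 1) * n + 1):(k * n)] <- covs[k, , ]
  V <- diag(n)
  epsilon <- n * (n - 1) * eps
  for (it in seq_len(maxIter)) {
    decr <- 0
    for (ii in 2:n) {
      for (jj in seq_len(ii - 1)) {
        Ii <- seq(ii, n * K, by = n)
        Ij <- seq(jj, n * K, by = n)
        c1 <- A[ii, Ii]
        c2 <- A[jj, Ij]
        g12 <- mean(A[ii, Ij] / c1)
        g21 <- mean(A[ii, Ij] / c2)
        omega21 <- mean(c1 / c2)
        omega12 <- mean(c2 / c1)
        omega <- sqrt(omega12 * omega21)
        tmp <- sqrt(omega21 / omega12)
        tmp1 <- (tmp * g12 + g21) / (omega + 1)
        tmp2 <- (tmp * g12 - g21) / max(omega - 1, 1e-9)
        h12 <- tmp1 + tmp2
        h21 <- (tmp1 - tmp2) / tmp
        decr <- decr + K * (g12 * h12 + g21 * h21) / 2
        disc <- 1 - h12 * h21
        tmp <- 1 + sqrt(max(disc, 1e-12))
        tau <- matrix(c(1, -h21 / tmp, -h12 / tmp, 1), 2, 2)
        A[c(ii, jj), ] <- tau %*% A[c(ii, jj), ]
        cols <- cbind(A[, Ii], A[, Ij])
        cols <- matrix(as.vector(cols), n * K, 2)
        cols <- cols %*% t(tau)
        A[, Ii] <- matrix(cols[, 1], n, K)
        A[, Ij] <- matrix(cols[, 2], n, K)
        V[c(ii, jj), ] <- tau %*% V[c(ii, jj), ]
      }
    }
    if (abs(decr) < epsilon) return(list(V = V, converged = TRUE))
  }
  list(V = V, converged = FALSE)
}

# Two-class CSP filters: rows ordered by eigenvalue of the whitened
# first-class covariance (descending). Row signs fixed so the largest
# absolute coefficient is positive.
cspTwoClass <- function(C1, C2) {
  Cc <- C1 + C2
  e <- eigen(Cc, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  P <- diag(1 / sqrt(e$values[keep]), sum(keep)) %*% t(e$vectors[, keep])
  S1 <- P %*% C1 %*% t(P)
  e1 <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)
  W <- t(e1$vectors) %*% P
  fixSigns(W, list(eigenvalues = e1$values))
}

fixSigns <- function(W, extra = list()) {
  for (i in seq_len(nrow(W))) {
    j <- which.max(abs(W[i, ]))
    if (W[i, j] < 0) W[i, ] <- -W[i, ]
  }
  c(list(W = W), extra)
}

#' Fit CSP spatial filters
#'
#' For two classes, solves the generalized eigenproblem of the class
#' covariances and retains the \code{nComponents/2} most extreme filters from
#' each end of the eigenvalue spectrum. For more classes, approximately
#' jointly diagonalizes the per-class mean covariances (Pham's algorithm) and
#' ranks the resulting filters by an information criterion on the projected
#' per-class variances, falling back to pooled one-vs-rest eigen filters if
#' the AJD does not converge. Per-trial covariances are trace-normalized and
#' ridge-regularized. Filters are deterministic for fixed input and
#' sign-fixed (largest coefficient positive).
#'
#' @param train an [EpochedData] with >= 2 classes, >= 2 trials per class.
#' @param nComponents number of spatial filters to retain (even).
#' @return list with \code{filters} (nComponents x channels),
#'   \code{allFilters} (channels x channels, importance-ordered:
#'   eigenvalue-descending for two classes, separation-ranked otherwise),
#'   \code{extremePair} (the two most class-informative filters),
#'   \code{channels}, \code{classes}.
#' @export
fitCSP <- function(train, nComponents = 4) {
  stopifnot(is(train, "EpochedData"))
  if (nComponents %% 2 != 0 && nComponents < nChannels(train))
    stop("nComponents must be even")
  if (nComponents > nChannels(train))
    stop("nComponents must not exceed the channel count")
  if (!all(is.finite(train@signal))) stop("non-finite input")
  cc <- classCovariances(train)
  nCh <- nChannels(train)
  K <- length(cc$classes)
  if (K < 2) stop("need at least 2 classes")
  if (K == 2) {
    fit <- cspTwoClass(cc$covs[1, , ], cc$covs[2, , ])
    W <- fit$W   # rows ordered by eigenvalue, descending
    pick <- utils::head(unique(c(seq_len(ceiling(nComponents / 2)),
                                 nCh - seq_len(max(1, floor(nComponents / 2))) + 1)),
                        nComponents)
    all <- W
    filters <- W[pick, , drop = FALSE]
    extremePair <- W[c(1, nCh), , drop = FALSE]
  } else {
    ajd <- ajdPham(cc$covs)
    if (ajd$converged) {
      W <- ajd$V
    } else {
      # one-vs-rest fallback: pool extreme eigenfilters of each class-vs-rest
      rows <- matrix(0, 0, nCh)
      for (ci in seq_len(K)) {
        Crest <- apply(cc$covs[-ci, , , drop = FALSE], c(2, 3), mean)
        Wi <- cspTwoClass(cc$covs[ci, , ], Crest)$W
        rows <- rbind(rows, Wi[c(1, nCh), , drop = FALSE])
      }
      W <- rows[seq_len(min(nCh, nrow(rows))), , drop = FALSE]
    }
    # normalize: unit projected variance under the weighted mean covariance
    meanCov <- apply(cc$covs, c(2, 3), function(v) sum(v * cc$weights)) /
      sum(cc$weights)
    for (i in seq_len(nrow(W))) {
      s <- sqrt(drop(W[i, ] %*% meanCov %*% W[i, ]))
      if (s > 0) W[i, ] <- W[i, ] / s
    }
    W <- fixSigns(W)$W
    # rank by class-separation information of projected variances
    probs <- cc$weights / sum(cc$weights)
    info <- vapply(seq_len(nrow(W)), function(i) {
      aa <- 0; bb <- 0
      for (ci in seq_len(K)) {
        v <- drop(W[i, ] %*% cc$covs[ci, , ] %*% W[i, ])
        aa <- aa + probs[ci] * log(sqrt(v))
        bb <- bb + probs[ci] * (v^2 - 1)
      }
      -(aa + (3 / 16) * bb^2)
    }, numeric(1))
    ord <- order(info, decreasing = TRUE)
    all <- W[ord, , drop = FALSE]
    filters <- all[seq_len(nComponents), , drop = FALSE]
    extremePair <- all[seq_len(min(2, nrow(all))), , drop = FALSE]
  }
  colnames(filters) <- channelNames(train)
  colnames(all) <- channelNames(train)
  colnames(extremePair) <- channelNames(train)
  list(filters = filters, allFilters = all, extremePair = extremePair,
       channels = channelNames(train), classes = cc$classes)
}
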