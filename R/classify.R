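#' ClassifierSpec: one of the four classifier families
#'
#' All stochastic components (validation carving, tree bootstraps, weight
#' initialization) draw from the spec seed, so identical (spec, data) reruns
#' give bit-identical accuracy. Features are standardized inside
#' [trainEval()] using training-set statistics only.
#'
#' @slot kind one of \code{xgb}, \code{nn}, \code{rf}, \code{svm}.
#' @slot seed mandatory integer seed.
#' @slot params named list of per-kind hyperparameters; unset entries take
#'   the defaults below.
#'
#' @section Defaults:
#' \describe{
#'   \item{xgb}{softmax objective, mean-error metric, early stopping after 10
#'     stagnant rounds on a 20\% validation split of the training set, at most
#'     200 rounds, depth 6, learning rate 0.3.}
#'   \item{nn}{multilayer perceptron 256-128-64-32-16, alternating ReLU/tanh,
#'     dropout 0.3, softmax output, categorical cross-entropy, Adam,
#'     patience-5 early stopping on a 20\% validation split.}
#'   \item{rf}{random forest, 100 trees, unlimited depth.}
#'   \item{svm}{RBF kernel, C = 1, gamma = 1 / (n_features * var(features)).}
#' }
#' @export
setClass("ClassifierSpec",
  representation(kind = "character", seed = "integer", params = "list"))

setValidity("ClassifierSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("xgb", "nn", "rf", "svm"))
    msg <- c(msg, "kind must be one of xgb/nn/rf/svm")
  if (is.na(object@seed)) msg <- c(msg, "seed is mandatory")
  known <- switch(object@kind,
    xgb = c("nrounds", "maxDepth", "eta", "earlyStoppingRounds", "valFraction"),
    nn = c("hidden", "dropout", "lr", "maxEpochs", "patience", "batchSize",
           "valFraction"),
    rf = c("nTrees"),
    svm = c("cost", "gamma"))
  bad <- setdiff(names(object@params), known)
  if (length(bad))
    msg <- c(msg, paste0("unknown ", object@kind, " hyperparameters: ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Build a ClassifierSpec
#' @param kind classifier family (\code{xgb}, \code{nn}, \code{rf}, \code{svm}).
#' @param seed integer seed (mandatory).
#' @param ... per-kind hyperparameter overrides (see [ClassifierSpec-class]).
#' @return a [ClassifierSpec].
#' @export
classifierSpec <- function(kind, seed, ...) {
  new("ClassifierSpec", kind = kind, seed = as.integer(seed),
      params = list(...))
}

param <- function(spec, name, default) {
  if (!is.null(spec@params[[name]])) spec@params[[name]] else default
}

# Stratified validation carve-out from training rows only.
carveValidation <- function(y, fraction, seed) {
  withSeed(seed, {
    val <- integer()
    for (cl in unique(y)) {
      pool <- which(y == cl)
      if (length(pool) >= 2)
        val <- c(val, sample(pool, max(1L, round(length(pool) * fraction))))
    }
    sort(val)
  })
}

#' Train on one feature matrix and evaluate on another
#'
#' Standardizes both matrices with training-set mean/sd (constant columns get
#' unit scale), trains the classifier described by \code{spec}, and scores
#' held-out accuracy. Test classes unseen in training are evaluated normally
#' and count as errors unless hit by chance.
#'
#' @param spec a [ClassifierSpec].
#' @param train a [FeatureMatrix] (or plain matrix) of training trials.
#' @param trainLabels,testLabels class labels.
#' @param test feature matrix of test trials; identical columns as train.
#' @return an [EvalResult].
#' @export
trainEval <- function(spec, train, trainLabels, test, testLabels) {
  stopifnot(is(spec, "ClassifierSpec"))
  validObject(spec)
  Xtr <- if (is(train, "FeatureMatrix")) train@values else train
  Xte <- if (is(test, "FeatureMatrix")) test@values else test
  if (ncol(Xtr) != ncol(Xte) ||
      !identical(colnames(Xtr), colnames(Xte)))
    stop("train and test feature columns differ")
  if (length(unique(trainLabels)) < 2)
    stop("need at least 2 classes in training labels")
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xtr <- scale(Xtr, center = mu, scale = sdv)
  Xte <- scale(Xte, center = mu, scale = sdv)
  classes <- sort(unique(trainLabels))
  yTr <- factor(trainLabels, levels = classes)
  pred <- switch(spec@kind,
    xgb = predictXGB(spec, Xtr, yTr, Xte),
    rf = predictRF(spec, Xtr, yTr, Xte),
    svm = predictSVM(spec, Xtr, yTr, Xte),
    nn = predictMLP(spec, Xtr, yTr, Xte))
  allClasses <- sort(unique(c(classes, testLabels)))
  conf <- table(factor(testLabels, levels = allClasses),
                factor(pred, levels = allClasses))
  conf <- matrix(as.integer(conf), nrow(conf), ncol(conf),
                 dimnames = dimnames(conf))
  nTest <- length(testLabels)
  new("EvalResult", accuracy = sum(diag(conf)) / nTest, confusion = conf,
      nTest = as.integer(nTest))
}

predictXGB <- function(spec, Xtr, yTr, Xte) {
  valFrac <- param(spec, "valFraction", 0.2)
  val <- carveValidation(as.character(yTr), valFrac,
                         childSeed(spec@seed, "xgb-val"))
  yNum <- as.integer(yTr) - 1L
  dtrain <- xgboost::xgb.DMatrix(Xtr[-val, , drop = FALSE],
                                 label = yNum[-val])
  dval <- xgboost::xgb.DMatrix(Xtr[val, , drop = FALSE], label = yNum[val])
  params <- list(objective = "multi:softmax",
                 num_class = nlevels(yTr),
                 eval_metric = "merror",
                 max_depth = param(spec, "maxDepth", 6),
                 eta = param(spec, "eta", 0.3),
                 # exact greedy splits: thresholds at midpoints between
                 # observations, not histogram bin edges
                 tree_method = "exact",
                 nthread = 1,
                 seed = spec@seed)
  fit <- xgboost::xgb.train(
    params = params, data = dtrain,
    nrounds = param(spec, "nrounds", 200),
    evals = list(val = dval),
    early_stopping_rounds = param(spec, "earlyStoppingRounds", 10),
    verbose = 0)
  # prediction uses the best early-stopped iteration automatically
  idx <- stats::predict(fit, xgboost::xgb.DMatrix(Xte)) + 1
  levels(yTr)[idx]
}

predictRF <- function(spec, Xtr, yTr, Xte) {
  fit <- withSeed(childSeed(spec@seed, "rf"), {
    randomForest::randomForest(x = Xtr, y = yTr,
                               ntree = param(spec, "nTrees", 100))
  })
  as.character(stats::predict(fit, Xte))
}

predictSVM <- function(spec, Xtr, yTr, Xte) {
  v <- stats::var(as.vector(Xtr))
  gamma <- param(spec, "gamma",
                 if (v > 0) 1 / (ncol(Xtr) * v) else 1 / ncol(Xtr))
  fit <- e1071::svm(x = Xtr, y = yTr, kernel = "radial",
                    cost = param(spec, "cost", 1), gamma = gamma,
                    scale = FALSE)
  as.character(stats::predict(fit, Xte))
}

# Hand-written multilayer perceptron: alternating ReLU/tanh hidden stack,
# inverted dropout, softmax + cross-entropy, Adam, early stopping on a
# carved validation split.
predictMLP <- function(spec, Xtr, yTr, Xte) {
  hidden <- param(spec, "hidden", c(256, 128, 64, 32, 16))
  dropout <- param(spec, "dropout", 0.3)
  lr <- param(spec, "lr", 1e-3)
  maxEpochs <- param(spec, "maxEpochs", 100)
  patience <- param(spec, "patience", 5)
  batchSize <- param(spec, "batchSize", 16)
  valFrac <- param(spec, "valFraction", 0.2)

  K <- nlevels(yTr)
  val <- carveValidation(as.character(yTr), valFrac,
                         childSeed(spec@seed, "nn-val"))
  Xv <- Xtr[val, , drop = FALSE]
  yv <- as.integer(yTr)[val]
  Xt <- Xtr[-val, , drop = FALSE]
  yt <- as.integer(yTr)[-val]
  sizes <- c(ncol(Xtr), hidden, K)
  acts <- c(rep(c("relu", "tanh"), length.out = length(hidden)), "softmax")

  forward <- function(W, b, X, train = FALSE, dropMasks = NULL) {
    A <- list(t(X))
    for (l in seq_along(W)) {
      Z <- W[[l]] %*% A[[l]] + as.vector(b[[l]])
      H <- switch(acts[l],
                  relu = pmax(Z, 0),
                  tanh = tanh(Z),
                  softmax = {
                    E <- exp(sweep(Z, 2, apply(Z, 2, max)))
                    sweep(E, 2, colSums(E), "/")
                  })
      if (train && acts[l] != "softmax" && dropout > 0)
        H <- H * dropMasks[[l]] / (1 - dropout)
      A[[l + 1]] <- H
    }
    A
  }

  run <- withSeed(childSeed(spec@seed, "nn"), {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      # He scaling into ReLU layers, Xavier into tanh/softmax layers
      sc <- if (acts[l] == "relu") sqrt(2 / sizes[l]) else sqrt(1 / sizes[l])
      W[[l]] <- matrix(stats::rnorm(sizes[l + 1] * sizes[l], sd = sc),
                       sizes[l + 1], sizes[l])
      b[[l]] <- numeric(sizes[l + 1])
    }
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mB <- lapply(b, function(x) x * 0); vB <- mB
    beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8; step <- 0
    best <- list(loss = Inf, W = W, b = b); wait <- 0
    oneHot <- function(y) {
      M <- matrix(0, K, length(y)); M[cbind(y, seq_along(y))] <- 1; M
    }
    Yt <- oneHot(yt)
    for (epoch in seq_len(maxEpochs)) {
      ord <- sample(nrow(Xt))
      for (start in seq(1, length(ord), by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1, length(ord))]
        masks <- lapply(seq_along(hidden), function(l)
          matrix(stats::runif(sizes[l + 1] * length(idx)) > dropout,
                 sizes[l + 1], length(idx)))
        A <- forward(W, b, Xt[idx, , drop = FALSE], train = TRUE,
                     dropMasks = masks)
        delta <- A[[length(A)]] - Yt[, idx, drop = FALSE]
        for (l in rev(seq_along(W))) {
          gW <- delta %*% t(A[[l]]) / length(idx)
          gB <- rowMeans(delta)
          if (l > 1) {
            back <- t(W[[l]]) %*% delta
            H <- A[[l]]
            dAct <- if (acts[l - 1] == "relu") (H > 0) * 1 else 1 - H^2
            delta <- back * dAct
            if (dropout > 0)
              delta <- delta * masks[[l - 1]] / (1 - dropout)
          }
          step <- step + 1
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB
          vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB^2
          corr <- sqrt(1 - beta2^step) / (1 - beta1^step)
          W[[l]] <- W[[l]] - lr * corr * mW[[l]] / (sqrt(vW[[l]]) + epsA)
          b[[l]] <- b[[l]] - lr * corr * mB[[l]] / (sqrt(vB[[l]]) + epsA)
        }
      }
      Pv <- forward(W, b, Xv)[[length(sizes)]]
      loss <- -mean(log(pmax(Pv[cbind(yv, seq_along(yv))], 1e-12)))
      if (loss < best$loss - 1e-6) {
        best <- list(loss = loss, W = W, b = b); wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= patience) break
      }
    }
    best
  })
  P <- forward(run$W, run$b, Xte)[[length(sizes)]]
  levels(yTr)[apply(P, 2, which.max)]
}
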