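# Internal helpers shared across modules.

# Run code with a local RNG state seeded from `seed`; the caller's global
# RNG stream is untouched. All package randomness flows through this.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream tag, staying inside
# the 32-bit signed range.
childSeed <- function(seed, tag) {
  stopifnot(length(tag) == 1)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.double(seed) * 48271 + h * 9973) %% 2147483563) + 1L
}

# Hemisphere from a 10-20 label: trailing z -> midline, odd digit -> left,
# even digit -> right.
hemisphereFromLabel <- function(labels) {
  side <- rep(NA_character_, length(labels))
  side[grepl("z$", labels)] <- "midline"
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", labels)))
  side[is.na(side) & !is.na(num) & num %% 2 == 1] <- "left"
  side[is.na(side) & !is.na(num) & num %% 2 == 0] <- "right"
  if (anyNA(side))
    stop("labels not parseable as 10-20 names: ",
         paste(labels[is.na(side)], collapse = ", "))
  side
}

# Stratified train/test split, frozen by seed.
#' Create a frozen stratified train/test split
#'
#' Draws a stratified split of trials and freezes it in a [SplitSpec] so the
#' same partition is reused at every electrode-elimination step.
#'
#' @param labels per-trial class labels.
#' @param testFraction fraction of trials per class assigned to the test set.
#' @param seed integer seed.
#' @return a [SplitSpec].
#' @export
makeSplit <- function(labels, testFraction = 0.2, seed) {
  stopifnot(testFraction > 0, testFraction < 1)
  idx <- withSeed(seed, {
    test <- integer()
    for (cl in unique(labels)) {
      pool <- which(labels == cl)
      nTest <- max(1L, round(length(pool) * testFraction))
      test <- c(test, sample(pool, nTest))
    }
    sort(test)
  })
  new("SplitSpec", trainIdx = setdiff(seq_along(labels), idx),
      testIdx = idx, seed = as.integer(seed))
}

#' Predefined train/test split
#'
#' Wraps externally fixed index lists (e.g. a competition's 300/50 split)
#' into a [SplitSpec].
#'
#' @param trainIdx,testIdx 1-based trial indices.
#' @return a [SplitSpec].
#' @export
predefinedSplit <- function(trainIdx, testIdx) {
  new("SplitSpec", trainIdx = as.integer(trainIdx),
      testIdx = as.integer(testIdx), seed = NA_integer_)
}
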