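#' Construct a Montage
#'
#' Builds a [Montage] from a label/side/coordinate table and registers the
#' standard anatomical comparison subsets: \code{"broca_wernicke"} (the F7/P3
#' neighbourhood covering Broca's and Wernicke's areas), \code{"left"} and
#' \code{"right"}. Midline electrodes belong to both hemispheric subsets,
#' which is the only assignment giving 35 + 35 labels on a 64-channel layout
#' with 6 midline sites.
#'
#' @param table data.frame with columns \code{label}, \code{side}, \code{x},
#'   \code{y}. \code{side} may be omitted; it is then derived from the label.
#' @param subsets optional named list of extra label subsets to register.
#' @return a [Montage].
#' @export
montage <- function(table, subsets = list()) {
  stopifnot(is.data.frame(table), all(c("label", "x", "y") %in% names(table)))
  labels <- as.character(table$label)
  side <- if ("side" %in% names(table)) as.character(table$side)
          else hemisphereFromLabel(labels)
  coords <- cbind(x = as.numeric(table$x), y = as.numeric(table$y))
  rownames(coords) <- labels
  base <- list(
    left = labels[side != "right"],
    right = labels[side != "left"]
  )
  bw <- c("F7", "AF7", "AF3", "F5", "F9", "F3", "FT9", "FT7", "FC5",
          "CP5", "CP3", "CPz", "P5", "P1", "P3", "PO3", "PO8", "POz")
  if (all(bw %in% labels)) base$broca_wernicke <- bw
  new("Montage", labels = labels, side = side, coords = coords,
      subsets = utils::modifyList(base, subsets))
}

#' The 64-channel 10-20 reference montage
#'
#' The extended 10-20 layout of the 64-channel caps used throughout the
#' pipeline: 29 left, 29 right and 6 midline electrodes (Fz, Cz, CPz, Pz,
#' POz, Oz), including the inferior F9/F10 and FT9/FT10 rows. Shipped as a
#' plain-text table under \code{inst/extdata}; pass a different table to
#' [montage()] to override.
#'
#' @return a [Montage] with 64 channels and the subsets
#'   \code{broca_wernicke} (18 labels), \code{left} (35) and \code{right} (35).
#' @examples
#' m <- standardMontage()
#' length(anatomicalSubset(m, "broca_wernicke"))
#' @export
standardMontage <- function() {
  path <- system.file("extdata", "montage64.csv", package = "eegreduce")
  montage(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Look up a registered anatomical subset
#'
#' @param montage a [Montage].
#' @param name registered subset name, e.g. \code{"broca_wernicke"},
#'   \code{"left"}, \code{"right"}.
#' @return character vector of channel labels, in registry order.
#' @export
anatomicalSubset <- function(montage, name) {
  stopifnot(is(montage, "Montage"))
  if (!name %in% names(montage@subsets))
    stop("unknown subset '", name, "'; registered: ",
         paste(names(montage@subsets), collapse = ", "))
  montage@subsets[[name]]
}

#' Read a montage override from JSON
#'
#' Accepts a JSON object with fields \code{label}, \code{side} (optional),
#' \code{x}, \code{y} as parallel arrays, plus an optional \code{subsets}
#' object mapping names to label arrays.
#'
#' @param path JSON file path.
#' @return a [Montage].
#' @export
readMontageJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- data.frame(label = obj$label, x = obj$x, y = obj$y,
                    stringsAsFactors = FALSE)
  if (!is.null(obj$side)) tab$side <- obj$side
  subsets <- if (is.null(obj$subsets)) list() else as.list(obj$subsets)
  montage(tab, subsets = subsets)
}
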