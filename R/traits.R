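#' Canonical perceptual trait set
#'
#' The six image-derived phenotypic traits used throughout the package:
#' Leaf Colour (LC), Leaf Area (LA), Texture Uniformity (TU), Vein
#' Prominence (VP), Edge Sharpness (ES) and Wilting Index (WI), in the
#' fixed canonical order that anchors every embedding coordinate and
#' serialisation.
#'
#' @return A data frame with columns `code`, `name` and `index` (0-based
#'   position in canonical order).
#' @examples
#' pgk_traits()
#' @export
pgk_traits <- function() {
  data.frame(
    code = c("LC", "LA", "TU", "VP", "ES", "WI"),
    name = c("Leaf Colour", "Leaf Area", "Texture Uniformity",
             "Vein Prominence", "Edge Sharpness", "Wilting Index"),
    index = 0:5,
    stringsAsFactors = FALSE
  )
}

#' Trait codes of a trait registry
#'
#' @param traits a trait registry data frame as returned by [pgk_traits()].
#' @return Character vector of trait codes in canonical order.
#' @export
trait_codes <- function(traits = pgk_traits()) {
  validate_traits(traits)
  traits$code
}

validate_traits <- function(traits) {
  if (!is.data.frame(traits) || !all(c("code", "name") %in% names(traits)))
    stop("trait registry must be a data frame with columns 'code' and 'name'")
  if (anyDuplicated(traits$code))
    stop("trait codes must be unique")
  if (nrow(traits) < 2L)
    stop("a trait registry needs at least two traits")
  invisible(traits)
}

#' Canonical trait-pair enumeration
#'
#' Enumerates all unordered trait pairs in canonical order (first trait
#' varying slowest): for the default six-trait set this yields the 15 pairs
#' LC-LA, LC-TU, LC-VP, LC-ES, LC-WI, LA-TU, ..., ES-WI.  This order fixes
#' the coordinates of the interaction embedding.
#'
#' @param codes character vector of trait codes in canonical order.
#' @return Data frame with columns `a`, `b` (trait codes) and `label`
#'   (`"a-b"`).
#' @examples
#' trait_pairs()
#' @export
trait_pairs <- function(codes = trait_codes()) {
  m <- length(codes)
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  data.frame(
    a = codes[idx[, "row"]],
    b = codes[idx[, "col"]],
    label = paste(codes[idx[, "row"]], codes[idx[, "col"]], sep = "-"),
    stringsAsFactors = FALSE
  )
}

#' Condition classes used for stress labelling
#' @return Character vector `c("Healthy", "Mild", "Severe")`.
#' @export
condition_levels <- function() c("Healthy", "Mild", "Severe")
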