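#' Synaptic strength thresholds
#'
#' Connections between neuron pairs are stratified by their total synaptic
#' weight (the number of postsynaptic densities) into three classes: weak
#' (weight below `medium_min`), medium (at least `medium_min` but below
#' `strong_min`) and strong (at least `strong_min`). The defaults, 3 and 10,
#' are the conventional hemibrain criteria: one or two synapses are
#' considered weak and error-prone, three to nine medium, ten or more strong.
#'
#' @param medium_min Smallest total weight classified as medium. Default 3.
#' @param strong_min Smallest total weight classified as strong. Default 10.
#'
#' @return An object of class `strength_thresholds`: a named list with
#'   elements `medium_min` and `strong_min`.
#' @examples
#' strength_thresholds()
#' strength_thresholds(medium_min = 3, strong_min = 11)
#' @export
strength_thresholds <- function(medium_min = 3L, strong_min = 10L) {
  medium_min <- as.integer(medium_min)
  strong_min <- as.integer(strong_min)
  if (is.na(medium_min) || is.na(strong_min)) {
    abort("thresholds must be integers")
  }
  if (!(1L < medium_min && medium_min <= strong_min)) {
    abort("thresholds must satisfy 1 < medium_min <= strong_min")
  }
  structure(
    list(medium_min = medium_min, strong_min = strong_min),
    class = "strength_thresholds"
  )
}

#' @export
print.strength_thresholds <- function(x, ...) {
  cat(sprintf(
    "<strength_thresholds> weak < %d <= medium < %d <= strong\n",
    x$medium_min, x$strong_min
  ))
  invisible(x)
}

#' Strength class levels, ordered weak < medium < strong
#' @keywords internal
strength_levels <- c("weak", "medium", "strong")

#' Classify synaptic weights into strength classes
#'
#' Applies the weak/medium/strong stratification to total connection weights.
#' Classification always operates on the total weight between a neuron pair,
#' never on per-ROI synapse counts.
#'
#' @param weight Vector of positive integer synaptic weights.
#' @param thresholds A [strength_thresholds()] object.
#'
#' @return An ordered factor with levels `weak < medium < strong`.
#' @examples
#' classify_strength(c(1, 2, 3, 9, 10, 200))
#' @export
classify_strength <- function(weight, thresholds = strength_thresholds()) {
  stopifnot(inherits(thresholds, "strength_thresholds"))
  if (length(weight) && (any(is.na(weight)) || any(weight < 1))) {
    abort("synaptic weights must be >= 1")
  }
  cls <- ifelse(
    weight >= thresholds$strong_min, "strong",
    ifelse(weight >= thresholds$medium_min, "medium", "weak")
  )
  factor(cls, levels = strength_levels, ordered = TRUE)
}

#' Coerce a strength class specification to an ordered factor level
#' @noRd
as_strength_class <- function(min_class) {
  min_class <- match.arg(as.character(min_class), strength_levels)
  factor(min_class, levels = strength_levels, ordered = TRUE)
}

#' Logical mask: which weights reach at least `min_class`?
#' @noRd
weight_reaches <- function(weight, min_class, thresholds) {
  classify_strength(weight, thresholds) >= as_strength_class(min_class)
}
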