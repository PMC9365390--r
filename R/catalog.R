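#' The identified clock-neuron catalog
#'
#' Returns the catalog of the 28 circadian clock neurons identified in the
#' hemibrain v1.2.1 volume: the four PDF-expressing s-LNvs, six LNds, the
#' 5th LNv, four LPNs, two DN1as, five DN1pAs, two DN1pBs and four l-LNvs.
#' The `functional_group` column carries the morning/evening oscillator
#' subphase assignments: M (the four s-LNvs), E1 (LNd4, LNd5), E2 (LNd6 and
#' the 5th LNv) and E3 (LNd1-LNd3); all other cells, which are clock neurons
#' but not part of a lateral-neuron functional subgroup, carry `"none"`.
#'
#' @return A tibble with columns `body_id` (integer-valued numeric, unique),
#'   `type_label`, `sequential_label`, `clock_class`, `functional_group`
#'   and `is_fragment` (all `FALSE` here).
#' @examples
#' default_catalog()
#' dplyr::count(default_catalog(), functional_group)
#' @export
default_catalog <- function() {
  path <- system.file("extdata", "clock_catalog.csv", package = "clocknet")
  read_catalog(path)
}

#' Read a clock-cell catalog file
#'
#' Parses a catalog CSV with columns `bodyId,type,label,subphase`. An empty
#' subphase maps to functional group `"none"`. The clock class is derived
#' from the type column; unrecognised types are kept verbatim with class
#' `"non-clock"`.
#'
#' @param path Path to a CSV file.
#' @return A catalog tibble (see [default_catalog()]).
#' @export
read_catalog <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      bodyId = readr::col_double(),
      type = readr::col_character(),
      label = readr::col_character(),
      subphase = readr::col_character()
    )
  )
  req <- c("bodyId", "type", "label", "subphase")
  if (!all(req %in% names(raw))) {
    abort(paste0(
      "catalog file must have columns ", paste(req, collapse = ",")
    ))
  }
  if (anyDuplicated(raw$bodyId)) abort("duplicate bodyId in catalog")
  if (any(is.na(raw$bodyId)) || any(raw$bodyId < 1)) {
    abort("bodyId must be a positive integer")
  }
  tibble(
    body_id = raw$bodyId,
    type_label = dplyr::coalesce(raw$type, ""),
    sequential_label = dplyr::coalesce(raw$label, ""),
    clock_class = clock_class_from_type(raw$type),
    functional_group = factor(
      dplyr::coalesce(raw$subphase, "none"),
      levels = functional_group_levels
    ),
    is_fragment = FALSE
  ) |>
    validate_catalog()
}

clock_class_levels <- c(
  "s-LNv", "5th-LNv", "LNd", "l-LNv", "LPN", "DN1a", "DN1pA", "DN1pB",
  "non-clock"
)

functional_group_levels <- c("M", "E1", "E2", "E3", "none")

clock_class_from_type <- function(type) {
  type <- dplyr::coalesce(type, "")
  cls <- dplyr::case_when(
    type == "s-LNv" ~ "s-LNv",
    type %in% c("5th LNv", "5th-LNv", "5th s-LNv") ~ "5th-LNv",
    type == "LNd" ~ "LNd",
    type == "l-LNv" ~ "l-LNv",
    type == "LPN" ~ "LPN",
    type == "DN1a" ~ "DN1a",
    type == "DN1pA" ~ "DN1pA",
    type == "DN1pB" ~ "DN1pB",
    .default = "non-clock"
  )
  factor(cls, levels = clock_class_levels)
}

validate_catalog <- function(catalog) {
  bad <- catalog$functional_group != "none" &
    !catalog$clock_class %in% c("s-LNv", "5th-LNv", "LNd")
  if (any(bad)) {
    abort("functional groups M/E1/E2/E3 are restricted to lateral neurons")
  }
  catalog
}

#' Members of a functional group or clock class
#'
#' Convenience selectors over a catalog tibble.
#'
#' @param catalog A catalog tibble, e.g. [default_catalog()].
#' @param group A functional group name (`"M"`, `"E1"`, `"E2"`, `"E3"`).
#' @return A numeric vector of body ids, ordered by sequential label then
#'   body id.
#' @examples
#' group_members(default_catalog(), "E1")
#' @export
group_members <- function(catalog, group) {
  group <- match.arg(group, setdiff(functional_group_levels, "none"))
  out <- catalog |>
    dplyr::filter(.data$functional_group == .env$group) |>
    dplyr::arrange(.data$sequential_label, .data$body_id)
  out$body_id
}

#' @rdname group_members
#' @param class A clock class name, e.g. `"LNd"`.
#' @export
class_members <- function(catalog, class) {
  class <- match.arg(class, clock_class_levels)
  out <- catalog |>
    dplyr::filter(.data$clock_class == .env$class) |>
    dplyr::arrange(.data$sequential_label, .data$body_id)
  out$body_id
}

#' Build an internal catalog row for uncatalogued neurons
#' @noRd
fragment_records <- function(body_ids) {
  tibble(
    body_id = as.numeric(body_ids),
    type_label = "",
    sequential_label = "",
    clock_class = factor("non-clock", levels = clock_class_levels),
    functional_group = factor("none", levels = functional_group_levels),
    is_fragment = TRUE
  )
}
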