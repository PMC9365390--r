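#' Build a connectome table from a directed synaptic edge list
#'
#' The central container of the package: a collection of directed synaptic
#' connections (one per ordered pre/post neuron pair, weighted by the total
#' number of postsynaptic densities) together with a cell catalog and the
#' strength thresholds in force. All analysis functions take one of these as
#' their first argument.
#'
#' Edge rows are given in long form with columns `pre`, `post`, `weight` and
#' optionally `roi`. When several rows share a (pre, post) pair and carry
#' distinct ROI labels, the total connection weight is their sum; a row whose
#' `roi` is `NA` or `"TOTAL"` instead states the total explicitly, in which
#' case per-ROI weights may sum to less than the total (the remainder is
#' unassigned). Exact duplicate keys are summed with a warning, since the
#' synaptic weight between a pair is the total PSD count.
#'
#' @param edges A data frame with columns `pre`, `post`, `weight` and
#'   optionally `roi`.
#' @param catalog A catalog tibble ([default_catalog()] or [read_catalog()]).
#'   Neurons appearing in `edges` but missing from the catalog are appended
#'   as unnamed non-clock fragments.
#' @param thresholds A [strength_thresholds()] object.
#' @param allow_autapses Admit self-connections (`pre == post`)? Default
#'   `FALSE`: autapses are rejected at ingest.
#' @param roi_level Free-text name recording which flat ROI vocabulary the
#'   `roi` labels come from (e.g. `"primary"`). Metadata only.
#'
#' @return An object of class `connectome`: a list with tibbles
#'   `connections` (pre, post, weight) and `rois` (pre, post, roi, weight),
#'   the `catalog`, the `thresholds` and ingest metadata.
#' @examples
#' edges <- tibble::tibble(
#'   pre = c(1, 1), post = c(2, 2), roi = c("SLP", "SMP"), weight = c(7, 5)
#' )
#' connectome(edges)
#' @export
connectome <- function(edges, catalog = default_catalog(),
                       thresholds = strength_thresholds(),
                       allow_autapses = FALSE, roi_level = "primary") {
  stopifnot(is.data.frame(edges))
  req <- c("pre", "post", "weight")
  if (!all(req %in% names(edges))) {
    abort("edge table must have columns pre, post, weight")
  }
  edges <- as_tibble(edges)
  if (!"roi" %in% names(edges)) edges$roi <- NA_character_
  check_weights(edges$weight)
  if (any(is.na(edges$pre)) || any(is.na(edges$post)) ||
      any(edges$pre < 1) || any(edges$post < 1)) {
    abort("body ids must be positive integers")
  }
  if (!allow_autapses && any(edges$pre == edges$post)) {
    abort("autapses (pre == post) present; set allow_autapses = TRUE to admit them")
  }

  edges <- edges |>
    dplyr::mutate(roi = ifelse(.data$roi %in% "TOTAL", NA_character_, .data$roi))

  dup <- edges |> dplyr::count(.data$pre, .data$post, .data$roi) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    warn(sprintf(
      "%d duplicate (pre, post, roi) edge keys were summed", nrow(dup)
    ))
    edges <- edges |>
      dplyr::summarise(
        weight = sum(.data$weight),
        .by = c("pre", "post", "roi")
      )
  }

  rois <- edges |>
    dplyr::filter(!is.na(.data$roi)) |>
    dplyr::select("pre", "post", "roi", "weight") |>
    dplyr::arrange(.data$pre, .data$post, .data$roi)

  totals <- edges |>
    dplyr::filter(is.na(.data$roi)) |>
    dplyr::select("pre", "post", total = "weight")
  roi_sums <- rois |>
    dplyr::summarise(roi_sum = sum(.data$weight), .by = c("pre", "post"))

  connections <- dplyr::full_join(totals, roi_sums, by = c("pre", "post")) |>
    dplyr::mutate(
      weight = dplyr::coalesce(.data$total, .data$roi_sum)
    )
  bad <- !is.na(connections$total) & !is.na(connections$roi_sum) &
    connections$roi_sum > connections$total
  if (any(bad)) {
    abort(sprintf(
      "per-ROI weights exceed the stated total for %d connection(s)",
      sum(bad)
    ))
  }
  connections <- connections |>
    dplyr::select("pre", "post", "weight") |>
    dplyr::arrange(.data$pre, .data$post)

  seen <- unique(c(connections$pre, connections$post))
  missing <- setdiff(seen, catalog$body_id)
  if (length(missing)) {
    catalog <- dplyr::bind_rows(catalog, fragment_records(sort(missing)))
  }

  structure(
    list(
      connections = connections,
      rois = rois,
      catalog = catalog,
      thresholds = thresholds,
      allow_autapses = allow_autapses,
      roi_level = roi_level
    ),
    class = "connectome"
  )
}

check_weights <- function(weight) {
  if (any(is.na(weight)) || any(weight < 1) || any(weight != round(weight))) {
    bad <- which(is.na(weight) | weight < 1 | weight != round(weight))
    abort(sprintf(
      "synaptic weights must be positive integers (first bad row: %d)",
      bad[1]
    ))
  }
  invisible(weight)
}

#' @export
print.connectome <- function(x, ...) {
  cls <- classify_strength(x$connections$weight, x$thresholds)
  cat(sprintf(
    "<connectome> %d connections among %d neurons (%d catalogued, %d fragments)\n",
    nrow(x$connections),
    length(unique(c(x$connections$pre, x$connections$post))),
    sum(!x$catalog$is_fragment), sum(x$catalog$is_fragment)
  ))
  cat(sprintf(
    "  strength: %d weak / %d medium / %d strong (thresholds %d/%d)\n",
    sum(cls == "weak"), sum(cls == "medium"), sum(cls == "strong"),
    x$thresholds$medium_min, x$thresholds$strong_min
  ))
  invisible(x)
}

#' Extract the connection table of a connectome
#'
#' @param x A [connectome()] object.
#' @param min_class Keep only connections whose strength class is at least
#'   this (`"weak"` keeps everything).
#' @return A tibble with columns `pre`, `post`, `weight` and `class`.
#' @examples
#' connections(toy_connectome())
#' @export
connections <- function(x, min_class = "weak") {
  stopifnot(inherits(x, "connectome"))
  out <- x$connections |>
    dplyr::mutate(class = classify_strength(.data$weight, x$thresholds))
  out[weight_reaches(out$weight, min_class, x$thresholds), , drop = FALSE]
}

#' Look up a neuron's catalog entry, erroring on unknown ids
#' @noRd
require_known <- function(x, body_ids) {
  unknown <- setdiff(body_ids, x$catalog$body_id)
  if (length(unknown)) {
    abort(paste0(
      "unknown body id(s): ", paste(head(unknown, 5), collapse = ", ")
    ))
  }
  invisible(body_ids)
}

#' A small worked-example connectome
#'
#' Six neurons: a two-cell clock group (`m1`, `m2`, body ids 1 and 2), three
#' downstream targets (`t1`-`t3`, ids 11-13) and one further clock cell
#' (`c1`, id 21). Used throughout the documentation and tests as a fixture
#' whose every statistic can be checked by hand.
#'
#' @return A [connectome()] object.
#' @examples
#' toy_connectome()
#' @export
toy_connectome <- function() {
  catalog <- tibble(
    body_id = c(1, 2, 11, 12, 13, 21),
    type_label = c("clock", "clock", "", "", "", "clock"),
    sequential_label = c("m1", "m2", "t1", "t2", "t3", "c1"),
    clock_class = factor(
      c("non-clock", "non-clock", "non-clock", "non-clock", "non-clock",
        "non-clock"),
      levels = clock_class_levels
    ),
    functional_group = factor("none", levels = functional_group_levels),
    is_fragment = FALSE
  )
  edges <- tibble(
    pre    = c(1, 2, 1, 2, 11, 1),
    post   = c(11, 11, 12, 13, 21, 2),
    roi    = c("SLP", "SLP", "SMP", "SMP", "SLP", "AME"),
    weight = c(12, 10, 11, 4, 5, 3)
  )
  connectome(edges, catalog = catalog)
}
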