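#' Neuropil distribution of a cell's connections
#'
#' Where, anatomically, does a neuron make its (medium-plus-strong, by
#' default) connections? With the default `basis = "synapse_weight"` the
#' percentage for each ROI is the summed per-ROI synapse count of the
#' qualifying connections divided by their summed total weight; synapses
#' not assigned to any ROI fall into an explicit `"unassigned"` bucket so
#' the profile always sums to 100. With `basis = "partner_count"` each
#' qualifying connection contributes once, to its majority ROI (ties break
#' to the alphabetically first ROI; connections with no ROI data count as
#' unassigned).
#'
#' Strength classification always applies to a connection's total weight,
#' never to its per-ROI counts.
#'
#' @param x A [connectome()] object.
#' @param cell A body id.
#' @param direction `"inputs"` or `"outputs"`.
#' @param min_class Minimum strength class of included connections.
#' @param basis `"synapse_weight"` or `"partner_count"`.
#' @return A `neuropil_profile`: a tibble with columns `roi`, `amount`
#'   (synapse count or connection count) and `percentage`, sorted by
#'   descending percentage with `"unassigned"` last. Attribute `empty` is
#'   `TRUE` when the cell has no qualifying connections (the tibble is
#'   then empty).
#' @examples
#' roi_percentages(toy_connectome(), 1, "outputs")
#' @export
roi_percentages <- function(x, cell, direction = c("outputs", "inputs"),
                            min_class = "medium",
                            basis = c("synapse_weight", "partner_count")) {
  stopifnot(inherits(x, "connectome"), length(cell) == 1)
  direction <- match.arg(direction)
  basis <- match.arg(basis)
  require_known(x, cell)

  con <- connections(x, min_class)
  con <- if (direction == "outputs") {
    con |> dplyr::filter(.data$pre == .env$cell)
  } else {
    con |> dplyr::filter(.data$post == .env$cell)
  }
  rois <- x$rois |>
    dplyr::semi_join(con, by = c("pre", "post"))

  if (nrow(con) == 0) {
    out <- tibble(roi = character(), amount = numeric(),
                  percentage = numeric())
    return(new_neuropil_profile(out, cell, direction, min_class, basis,
                                empty = TRUE, thresholds = x$thresholds))
  }

  if (basis == "synapse_weight") {
    denom <- sum(con$weight)
    per_roi <- rois |>
      dplyr::summarise(amount = sum(.data$weight), .by = "roi")
    unassigned <- denom - sum(per_roi$amount)
    if (unassigned > 0) {
      per_roi <- dplyr::bind_rows(
        per_roi, tibble(roi = "unassigned", amount = unassigned)
      )
    }
  } else {
    majority <- rois |>
      dplyr::arrange(.data$roi) |>
      dplyr::slice_max(.data$weight, n = 1, with_ties = FALSE,
                       by = c("pre", "post")) |>
      dplyr::select("pre", "post", "roi")
    assigned <- con |>
      dplyr::left_join(majority, by = c("pre", "post")) |>
      dplyr::mutate(roi = dplyr::coalesce(.data$roi, "unassigned"))
    denom <- nrow(assigned)
    per_roi <- assigned |> dplyr::summarise(amount = dplyr::n(), .by = "roi")
  }
  out <- per_roi |>
    dplyr::mutate(percentage = 100 * .data$amount / denom) |>
    dplyr::arrange(.data$roi == "unassigned",
                   dplyr::desc(.data$percentage), .data$roi)
  new_neuropil_profile(out, cell, direction, min_class, basis,
                       empty = FALSE, thresholds = x$thresholds)
}

new_neuropil_profile <- function(out, cell, direction, min_class, basis,
                                 empty, thresholds) {
  structure(out,
            class = c("neuropil_profile", class(out)),
            cell = as.numeric(cell), direction = direction,
            min_class = as.character(min_class), basis = basis,
            empty = empty, thresholds = thresholds)
}

#' @export
print.neuropil_profile <- function(x, ...) {
  cat(sprintf("<neuropil_profile> cell %s, %s, min class %s, basis %s%s\n",
              format(attr(x, "cell")), attr(x, "direction"),
              attr(x, "min_class"), attr(x, "basis"),
              if (attr(x, "empty")) " (no qualifying connections)" else ""))
  NextMethod()
}

#' Neuropil profiles for several cells, stacked-bar ready
#'
#' @param x A [connectome()] object.
#' @param cells Body ids.
#' @inheritParams roi_percentages
#' @return A tibble with columns `body_id`, `label`, `roi`, `amount` and
#'   `percentage` (one row per cell and ROI).
#' @export
neuropil_profiles <- function(x, cells, direction = c("outputs", "inputs"),
                              min_class = "medium",
                              basis = c("synapse_weight", "partner_count")) {
  direction <- match.arg(direction)
  basis <- match.arg(basis)
  purrr::map2_dfr(cells, cell_labels(x, cells), function(cell, lab) {
    p <- roi_percentages(x, cell, direction, min_class, basis)
    if (nrow(p) == 0) return(tibble())
    tibble(body_id = as.numeric(cell), label = lab, roi = p$roi,
           amount = p$amount, percentage = p$percentage)
  })
}

#' Stacked bar chart of neuropil profiles
#'
#' @param object A tibble from [neuropil_profiles()] or a single
#'   `neuropil_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_neuropil_profiles <- function(object, ...) {
  if (inherits(object, "neuropil_profile")) {
    object <- tibble(label = format(attr(object, "cell")), roi = object$roi,
                     percentage = object$percentage)
  }
  ggplot2::ggplot(object, ggplot2::aes(.data$label, .data$percentage,
                                       fill = .data$roi)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of connections", fill = "neuropil") +
    ggplot2::theme_minimal()
}
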