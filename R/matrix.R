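#' Pairwise connectivity matrix over a set of neurons
#'
#' Entry (i, j) is the total synaptic weight of the directed connection from
#' `cells[i]` onto `cells[j]` if that connection's strength class reaches
#' `min_class`, and 0 otherwise. Rows are presynaptic. With the default
#' `min_class = "weak"` this reproduces all-connection heatmaps, weak
#' connections included.
#'
#' @param x A [connectome()] object.
#' @param cells Ordered vector of body ids (must all be in the catalog).
#'   Rows and columns follow this order; labels use the catalog's sequential
#'   labels where available.
#' @param min_class Minimum strength class to include.
#' @return A `weight_matrix`: an integer matrix with dimnames.
#' @examples
#' pairwise_matrix(toy_connectome(), cells = c(1, 2))
#' @export
pairwise_matrix <- function(x, cells, min_class = "weak") {
  stopifnot(inherits(x, "connectome"))
  require_known(x, cells)
  n <- length(cells)
  m <- matrix(0, n, n, dimnames = list(cell_labels(x, cells),
                                       cell_labels(x, cells)))
  if (n > 0) {
    keep <- connections(x, min_class) |>
      dplyr::filter(.data$pre %in% .env$cells, .data$post %in% .env$cells)
    if (nrow(keep)) {
      i <- match(keep$pre, cells)
      j <- match(keep$post, cells)
      m[cbind(i, j)] <- keep$weight
    }
  }
  new_weight_matrix(m, x, min_class, kind = "pairwise")
}

#' Class-aggregated connectivity matrix
#'
#' Sums connection weights between named, disjoint groups of neurons: entry
#' (A, B) is the summed total weight of all connections from members of
#' group A onto members of group B whose strength class reaches `min_class`.
#' Within-group entries include member-to-member connections. The default
#' `min_class = "medium"` reproduces combined medium-plus-strong
#' class-to-class summaries.
#'
#' @param x A [connectome()] object.
#' @param groups Named list of body-id vectors; groups must be disjoint.
#' @param min_class Minimum strength class to include.
#' @return A `weight_matrix` over the group names.
#' @examples
#' class_aggregate(toy_connectome(), list(G = c(1, 2), C = 21))
#' @export
class_aggregate <- function(x, groups, min_class = "medium") {
  stopifnot(inherits(x, "connectome"), is.list(groups))
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("groups must be named")
  }
  all_ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_ids)) abort("groups must be disjoint")
  require_known(x, all_ids)
  labels <- names(groups)
  n <- length(groups)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  membership <- setNames(rep(labels, lengths(groups)), NULL)
  lookup <- setNames(membership, all_ids)
  keep <- connections(x, min_class) |>
    dplyr::filter(.data$pre %in% .env$all_ids, .data$post %in% .env$all_ids)
  if (nrow(keep)) {
    agg <- keep |>
      dplyr::mutate(
        from = lookup[as.character(.data$pre)],
        to = lookup[as.character(.data$post)]
      ) |>
      dplyr::summarise(weight = sum(.data$weight), .by = c("from", "to"))
    m[cbind(agg$from, agg$to)] <- agg$weight
  }
  new_weight_matrix(m, x, min_class, kind = "class_aggregate")
}

#' Per-neuron input and output synapse totals
#'
#' Raw postsynaptic-density counts summed over every connection touching
#' each cell, weak connections and fragment partners included: the input
#' total of a cell is the summed weight of all connections onto it, the
#' output total the summed weight of all connections it makes.
#'
#' @param x A [connectome()] object.
#' @param cells Body ids to tabulate; defaults to every catalogued
#'   (non-fragment) neuron.
#' @return A tibble with columns `body_id`, `label`, `input_total`,
#'   `output_total` and `total` (their sum), one row per cell in the order
#'   given.
#' @examples
#' synapse_totals(toy_connectome())
#' @export
synapse_totals <- function(x, cells = NULL) {
  stopifnot(inherits(x, "connectome"))
  if (is.null(cells)) {
    cells <- x$catalog$body_id[!x$catalog$is_fragment]
  }
  require_known(x, cells)
  con <- x$connections
  ins <- con |> dplyr::summarise(input_total = sum(.data$weight),
                                 .by = "post")
  outs <- con |> dplyr::summarise(output_total = sum(.data$weight),
                                  .by = "pre")
  tibble(body_id = as.numeric(cells), label = cell_labels(x, cells)) |>
    dplyr::left_join(ins, by = c(body_id = "post")) |>
    dplyr::left_join(outs, by = c(body_id = "pre")) |>
    dplyr::mutate(
      input_total = dplyr::coalesce(.data$input_total, 0),
      output_total = dplyr::coalesce(.data$output_total, 0),
      total = .data$input_total + .data$output_total
    )
}

cell_labels <- function(x, cells) {
  idx <- match(cells, x$catalog$body_id)
  lab <- x$catalog$sequential_label[idx]
  ifelse(is.na(lab) | lab == "", as.character(cells), lab)
}

new_weight_matrix <- function(m, x, min_class, kind) {
  structure(
    m,
    class = c("weight_matrix", "matrix", "array"),
    min_class = as.character(min_class),
    thresholds = x$thresholds,
    kind = kind
  )
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf(
    "<weight_matrix: %s, min class %s> %d x %d\n",
    attr(x, "kind"), attr(x, "min_class"), nrow(x), ncol(x)
  ))
  print(unclass_matrix(x))
  invisible(x)
}

unclass_matrix <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

#' Tidy a weight matrix into a long tibble
#'
#' @param x A `weight_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `pre`, `post` and `weight`.
#' @method tidy weight_matrix
#' @export
tidy.weight_matrix <- function(x, ...) {
  m <- unclass_matrix(x)
  tibble(
    pre = rep(rownames(m), times = ncol(m)),
    post = rep(colnames(m), each = nrow(m)),
    weight = as.vector(m)
  )
}

#' Heatmap of a weight matrix
#'
#' @param object A `weight_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot weight_matrix
#' @export
autoplot.weight_matrix <- function(object, ...) {
  df <- tidy(object)
  df$pre <- factor(df$pre, levels = rev(rownames(object)))
  df$post <- factor(df$post, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$post, .data$pre,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "postsynaptic", y = "presynaptic",
                  fill = "weight") +
    ggplot2::theme_minimal()
}
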