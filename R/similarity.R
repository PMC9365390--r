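#' Jaccard similarity of two sets
#'
#' The ratio of the size of the intersection to the size of the union of
#' two sets: 0 means no overlap, 1 identical sets. When both sets are empty
#' the index is defined as 0 here (flagged in report metadata), so cells
#' with no qualifying partners do not appear spuriously similar.
#'
#' @param a,b Vectors interpreted as sets (duplicates ignored).
#' @return A number in \[0, 1\].
#' @examples
#' jaccard(c(1, 2, 3), c(2, 3, 4)) # 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Jaccard similarity matrix over neurons' partner sets
#'
#' Pairwise Jaccard indices of the cells' partner sets in one direction.
#' The default `min_class = "medium"` compares medium-plus-strong partner
#' sets, the criterion used for connectomic typing of clock neurons; pass
#' `"strong"` to restrict to strong partners.
#'
#' @param x A [connectome()] object.
#' @param cells Ordered vector of body ids.
#' @param direction `"inputs"` or `"outputs"`.
#' @param min_class Minimum strength class defining the partner sets.
#' @return A `jaccard_matrix`: a symmetric numeric matrix with values in
#'   \[0, 1\]; the diagonal is 1 for cells with a non-empty partner set and
#'   0 otherwise (the both-empty convention, recorded in the
#'   `empty_sets_zero` attribute).
#' @examples
#' jaccard_matrix(toy_connectome(), c(1, 2), "outputs")
#' @export
jaccard_matrix <- function(x, cells, direction = c("outputs", "inputs"),
                           min_class = "medium") {
  stopifnot(inherits(x, "connectome"))
  direction <- match.arg(direction)
  require_known(x, cells)
  sets <- purrr::map(cells, partner_ids, x = x, direction = direction,
                     min_class = min_class)
  n <- length(cells)
  m <- matrix(0, n, n,
              dimnames = list(cell_labels(x, cells), cell_labels(x, cells)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i) {
        m[i, j] <- m[j, i]
      } else {
        m[i, j] <- jaccard(sets[[i]], sets[[j]])
      }
    }
  }
  structure(m, class = c("jaccard_matrix", "matrix", "array"),
            cells = as.numeric(cells), direction = direction,
            min_class = as.character(min_class),
            empty_sets_zero = TRUE, thresholds = x$thresholds)
}

#' @export
print.jaccard_matrix <- function(x, ...) {
  cat(sprintf("<jaccard_matrix: %s partner sets, min class %s> %d cells\n",
              attr(x, "direction"), attr(x, "min_class"), nrow(x)))
  print(round(unclass_matrix(x), 3))
  invisible(x)
}

#' @rdname tidy.weight_matrix
#' @method tidy jaccard_matrix
#' @export
tidy.jaccard_matrix <- function(x, ...) {
  m <- unclass_matrix(x)
  tibble(
    cell_a = rep(rownames(m), times = ncol(m)),
    cell_b = rep(colnames(m), each = nrow(m)),
    jaccard = as.vector(m)
  )
}

#' Heatmap of a Jaccard matrix
#'
#' Indices below `display_min` are blanked, mirroring the usual display
#' threshold for these heatmaps; the computation itself is never
#' thresholded.
#'
#' @param object A `jaccard_matrix`.
#' @param display_min Smallest index displayed (default 0.01).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot jaccard_matrix
#' @export
autoplot.jaccard_matrix <- function(object, display_min = 0.01, ...) {
  df <- tidy(object)
  df$jaccard[df$jaccard < display_min] <- NA_real_
  df$cell_a <- factor(df$cell_a, levels = rev(rownames(object)))
  df$cell_b <- factor(df$cell_b, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$cell_b, .data$cell_a,
                                   fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard") +
    ggplot2::theme_minimal()
}

#' Export a Jaccard matrix with the display threshold applied
#'
#' Writes two CSVs: the raw matrix and a display copy in which indices
#' below `display_min` are zeroed.
#'
#' @param m A `jaccard_matrix`.
#' @param path Base output path; the display copy gets suffix
#'   `"_display"`.
#' @param display_min Display threshold (default 0.01).
#' @return Paths written, invisibly.
#' @export
write_jaccard_csv <- function(m, path, display_min = 0.01) {
  stopifnot(inherits(m, "jaccard_matrix"))
  raw <- unclass_matrix(m)
  write_matrix_csv(raw, path)
  disp <- raw
  disp[disp < display_min] <- 0
  display_path <- sub("(\\.[^.]+)?$", "_display\\1", path)
  write_matrix_csv(disp, display_path)
  invisible(c(path, display_path))
}

#' Group cells by similarity of their partner sets
#'
#' Average-linkage (by default) agglomerative clustering on the distance
#' 1 - J, cut at a fixed height, partitioning the cells into connectomic
#' groups. Deterministic for a given matrix: cells are processed in the
#' matrix's order and distance ties resolve by that order.
#'
#' @param m A `jaccard_matrix`.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @param cut Distance threshold in \[0, 1\] at which the dendrogram is
#'   cut. Default 0.85: cells whose partner sets overlap by (roughly) 15%
#'   or more end up together.
#' @return A tibble with columns `body_id`, `label` and `group` (integer
#'   group codes, numbered by first appearance in the input order).
#' @examples
#' m <- jaccard_matrix(toy_connectome(), c(1, 2), "outputs")
#' cluster_by_similarity(m, cut = 0.9)
#' @export
cluster_by_similarity <- function(m, linkage = c("average", "complete",
                                                 "single"),
                                  cut = 0.85) {
  stopifnot(inherits(m, "jaccard_matrix"))
  linkage <- match.arg(linkage)
  if (cut < 0 || cut > 1) abort("cut must lie in [0, 1]")
  d <- as.dist(1 - unclass_matrix(m))
  if (nrow(m) < 2) {
    grp <- rep(1L, nrow(m))
  } else {
    hc <- hclust(d, method = linkage)
    grp <- cutree(hc, h = cut)
  }
  grp <- as.integer(factor(grp, levels = unique(grp)))
  tibble(
    body_id = attr(m, "cells"),
    label = rownames(m),
    group = grp
  )
}
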