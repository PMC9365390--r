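#' Define a named cell group
#'
#' A cell group is a named, ordered set of body ids, e.g. the four
#' PDF-positive s-LNvs (the M group) or an evening oscillator subgroup.
#'
#' @param name Group name.
#' @param members Vector of body ids; non-empty, no duplicates.
#' @return A `cell_group` object.
#' @examples
#' cell_group("E1", group_members(default_catalog(), "E1"))
#' @export
cell_group <- function(name, members) {
  members <- as.numeric(members)
  if (length(members) == 0) abort("a cell group must have members")
  if (anyDuplicated(members)) abort("duplicate members in cell group")
  structure(list(name = as.character(name), members = members),
            class = "cell_group")
}

#' @export
print.cell_group <- function(x, ...) {
  cat(sprintf("<cell_group %s> %d members: %s\n", x$name,
              length(x$members),
              paste(x$members, collapse = ", ")))
  invisible(x)
}

as_group <- function(group, name = "group") {
  if (inherits(group, "cell_group")) return(group)
  cell_group(name, group)
}

#' Synaptic partners of a single neuron
#'
#' The presynaptic (`direction = "inputs"`) or postsynaptic
#' (`direction = "outputs"`) partners of a cell whose connection with it
#' reaches `min_class`. The default, medium, yields the medium-plus-strong
#' partner sets used for Jaccard similarity.
#'
#' @param x A [connectome()] object.
#' @param cell A body id present in the catalog.
#' @param direction `"inputs"` or `"outputs"`.
#' @param min_class Minimum strength class.
#' @return A tibble with columns `partner` and `weight`, sorted by
#'   descending weight then partner id; attributes record the focal cell,
#'   direction and class filter.
#' @examples
#' partner_set(toy_connectome(), 1, "outputs", min_class = "strong")
#' @export
partner_set <- function(x, cell, direction = c("outputs", "inputs"),
                        min_class = "medium") {
  stopifnot(inherits(x, "connectome"), length(cell) == 1)
  direction <- match.arg(direction)
  require_known(x, cell)
  con <- connections(x, min_class)
  out <- if (direction == "outputs") {
    con |> dplyr::filter(.data$pre == .env$cell) |>
      dplyr::transmute(partner = .data$post, weight = .data$weight)
  } else {
    con |> dplyr::filter(.data$post == .env$cell) |>
      dplyr::transmute(partner = .data$pre, weight = .data$weight)
  }
  out <- out |> dplyr::arrange(dplyr::desc(.data$weight), .data$partner)
  structure(out, focal = as.numeric(cell), direction = direction,
            min_class = as.character(min_class))
}

partner_ids <- function(x, cell, direction, min_class) {
  partner_set(x, cell, direction, min_class)$partner
}

#' Distinct strong partners of a cell group
#'
#' Counts the neurons that make (or receive) a strong connection with at
#' least one member of the group: the size of the union of the members'
#' strong partner sets. Partners that are themselves group members count.
#'
#' @param x A [connectome()] object.
#' @param group A [cell_group()] or vector of body ids.
#' @param direction `"inputs"` or `"outputs"`.
#' @param min_class Minimum strength class; default strong.
#' @return A single integer.
#' @examples
#' distinct_strong_partner_count(toy_connectome(), c(1, 2), "outputs")
#' @export
distinct_strong_partner_count <- function(x, group,
                                          direction = c("outputs", "inputs"),
                                          min_class = "strong") {
  direction <- match.arg(direction)
  group <- as_group(group)
  sets <- purrr::map(group$members, partner_ids, x = x,
                     direction = direction, min_class = min_class)
  length(unique(unlist(sets)))
}

#' Shared strong partners of a cell group
#'
#' Finds the neurons that share a strong connection with at least
#' `min_members` distinct members of a group — the shared strong inputs or
#' outputs that define a group's common connectivity. Each qualifying
#' partner is reported with its per-member strong connection weights.
#'
#' Group members reachable by strong connections from other members are
#' themselves eligible partners; set `exclude_members = TRUE` to drop them.
#'
#' @inheritParams distinct_strong_partner_count
#' @param min_members Minimum number of distinct group members a partner
#'   must connect strongly with (default 2, the usual "shared" criterion).
#' @param exclude_members Drop partners that are group members?
#' @return A `shared_partner_report`: a tibble with columns `partner`,
#'   `label`, `n_members` (contributing members) and `total` (summed strong
#'   weight), followed by one weight column per group member (0 when the
#'   connection is absent or below strong). Rows are sorted by descending
#'   `total`, then partner id.
#' @examples
#' shared_strong_partners(toy_connectome(), c(1, 2), "outputs")
#' @export
shared_strong_partners <- function(x, group,
                                   direction = c("outputs", "inputs"),
                                   min_members = 2, min_class = "strong",
                                   exclude_members = FALSE) {
  direction <- match.arg(direction)
  group <- as_group(group)
  if (min_members < 2) abort("min_members must be at least 2")
  if (min_members > length(group$members)) {
    abort("min_members exceeds the group size")
  }
  member_labels <- cell_labels(x, group$members)
  per_member <- purrr::map2_dfr(
    group$members, member_labels,
    function(m, lab) {
      ps <- partner_set(x, m, direction, min_class)
      if (nrow(ps) == 0) return(tibble(partner = numeric(),
                                       member = character(),
                                       weight = numeric()))
      tibble(partner = ps$partner, member = lab, weight = ps$weight)
    }
  )
  if (exclude_members && nrow(per_member)) {
    per_member <- per_member |>
      dplyr::filter(!.data$partner %in% group$members)
  }
  wide <- per_member |>
    tidyr::pivot_wider(names_from = "member", values_from = "weight",
                       values_fill = 0)
  for (lab in setdiff(member_labels, names(wide))) wide[[lab]] <- numeric(nrow(wide))
  if (nrow(wide) == 0) {
    wide <- tibble(partner = numeric())
    for (lab in member_labels) wide[[lab]] <- numeric()
  }
  wmat <- as.matrix(wide[, member_labels, drop = FALSE])
  report <- wide |>
    dplyr::mutate(
      n_members = rowSums(wmat > 0),
      total = rowSums(wmat),
      label = cell_labels(x, .data$partner),
      .after = "partner"
    ) |>
    dplyr::filter(.data$n_members >= .env$min_members) |>
    dplyr::arrange(dplyr::desc(.data$total), .data$partner) |>
    dplyr::select("partner", "label", "n_members", "total",
                  dplyr::all_of(member_labels))
  structure(report,
            class = c("shared_partner_report", class(report)),
            group = group, direction = direction,
            min_members = min_members, min_class = as.character(min_class),
            member_labels = member_labels,
            thresholds = x$thresholds)
}

#' Extract the partner-by-member weight matrix of a shared-partner report
#'
#' @param report A `shared_partner_report`.
#' @return A numeric matrix, partners in rows, group members in columns.
#' @export
partner_matrix <- function(report) {
  stopifnot(inherits(report, "shared_partner_report"))
  labs <- attr(report, "member_labels")
  m <- as.matrix(report[, labs, drop = FALSE])
  rownames(m) <- report$label
  m
}

#' Count the strong partners two cells share
#'
#' The size of the intersection of the two cells' partner sets at
#' `min_class` (default strong), in the given direction.
#'
#' @inheritParams partner_set
#' @param cell_a,cell_b Body ids.
#' @return A single integer; symmetric in the two cells.
#' @examples
#' pairwise_shared_count(toy_connectome(), 1, 2, "outputs")
#' @export
pairwise_shared_count <- function(x, cell_a, cell_b,
                                  direction = c("outputs", "inputs"),
                                  min_class = "strong") {
  direction <- match.arg(direction)
  length(intersect(
    partner_ids(x, cell_a, direction, min_class),
    partner_ids(x, cell_b, direction, min_class)
  ))
}

#' Export a shared-partner report as Sankey flow records
#'
#' One flow record per nonzero partner/member weight. For output reports
#' flows run member -> partner; for input reports partner -> member. The
#' summed flow equals the report's matrix sum.
#'
#' @param report A `shared_partner_report`.
#' @return A tibble with columns `source`, `target` and `weight`.
#' @export
sankey_export <- function(report) {
  stopifnot(inherits(report, "shared_partner_report"))
  labs <- attr(report, "member_labels")
  long <- report |>
    dplyr::select("label", dplyr::all_of(labs)) |>
    tidyr::pivot_longer(dplyr::all_of(labs), names_to = "member",
                        values_to = "weight") |>
    dplyr::filter(.data$weight > 0)
  if (attr(report, "direction") == "outputs") {
    tibble(source = long$member, target = long$label, weight = long$weight)
  } else {
    tibble(source = long$label, target = long$member, weight = long$weight)
  }
}

#' Per-member partner sets in SuperVenn-style list form
#'
#' @param x A [connectome()] object.
#' @param group A [cell_group()] or vector of body ids.
#' @param direction `"inputs"` or `"outputs"`.
#' @param min_class Minimum strength class.
#' @return A named list, one body-id vector per group member.
#' @export
partner_set_list <- function(x, group, direction = c("outputs", "inputs"),
                             min_class = "strong") {
  direction <- match.arg(direction)
  group <- as_group(group)
  sets <- purrr::map(group$members, partner_ids, x = x,
                     direction = direction, min_class = min_class)
  names(sets) <- cell_labels(x, group$members)
  sets
}

#' @export
print.shared_partner_report <- function(x, ...) {
  cat(sprintf(
    "<shared_partner_report> group %s, %s, >= %d members at %s: %d partner(s)\n",
    attr(x, "group")$name, attr(x, "direction"), attr(x, "min_members"),
    attr(x, "min_class"), nrow(x)
  ))
  NextMethod()
}

#' Stacked-bar view of a shared-partner report
#'
#' @param object A `shared_partner_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shared_partner_report
#' @export
autoplot.shared_partner_report <- function(object, ...) {
  labs <- attr(object, "member_labels")
  long <- object |>
    dplyr::select("label", dplyr::all_of(labs)) |>
    tidyr::pivot_longer(dplyr::all_of(labs), names_to = "member",
                        values_to = "weight") |>
    dplyr::filter(.data$weight > 0)
  long$label <- factor(long$label, levels = rev(object$label))
  ggplot2::ggplot(long, ggplot2::aes(.data$weight, .data$label,
                                     fill = .data$member)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "strong connection weight", y = NULL,
                  fill = "group member") +
    ggplot2::theme_minimal()
}
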