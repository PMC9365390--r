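#' Strong shared outputs that contact clock neurons in turn
#'
#' Takes the strong shared output targets of a cell group (per
#' [shared_strong_partners()]) and asks which of them form synapses back
#' onto clock neurons — length-2 paths group -> target -> clock. A target
#' is flagged recurrent when it makes at least one connection of class
#' `back_min_class` or stronger (default medium, i.e. medium-plus-strong)
#' onto any member of `clock_set`. Weak back-contacts are listed but never
#' set the flag. Targets that are themselves clock cells are flagged
#' `target_is_clock` and are eligible to be recurrent like any other
#' target; direct group -> clock connections do not count as recurrence.
#'
#' @param x A [connectome()] object.
#' @param group A [cell_group()] or vector of body ids.
#' @param clock_set Body ids regarded as clock neurons; defaults to the
#'   full identified-clock catalog ([default_catalog()] entries present in
#'   `x`).
#' @param min_members Shared criterion for the output targets (default 2).
#' @param back_min_class Minimum class of a back-contact that makes a
#'   target recurrent.
#' @return A `recurrence_report`: a tibble with one row per shared strong
#'   target — columns `target`, `label`, `target_is_clock`, `n_members`,
#'   `total` (summed strong weight from the group), `contacts` (list-column
#'   of tibbles `clock`, `clock_label`, `clock_class`, `weight`, `class`),
#'   `n_back` (qualifying back-contacts) and `is_recurrent` — ordered as in
#'   the shared-partner report. Attribute `percent_recurrent` holds
#'   100 * recurrent / targets (`NA` with attribute
#'   `percent_undefined = TRUE` when there are no targets). Use [glance()]
#'   for a one-row summary.
#' @examples
#' recurrent_targets(toy_connectome(), c(1, 2), clock_set = c(21, 1, 2))
#' @export
recurrent_targets <- function(x, group, clock_set = NULL, min_members = 2,
                              back_min_class = "medium") {
  stopifnot(inherits(x, "connectome"))
  group <- as_group(group)
  if (is.null(clock_set)) {
    clock_set <- intersect(default_catalog()$body_id, x$catalog$body_id)
  }
  clock_set <- unique(as.numeric(clock_set))
  if (length(clock_set) == 0) abort("clock_set must be non-empty")

  shared <- shared_strong_partners(x, group, "outputs",
                                   min_members = min_members)
  con_all <- connections(x, "weak")
  back <- con_all |>
    dplyr::filter(.data$pre %in% shared$partner,
                  .data$post %in% .env$clock_set)
  cat_idx <- match(back$post, x$catalog$body_id)
  back <- back |>
    dplyr::mutate(
      clock_label = cell_labels(x, .data$post),
      clock_class = as.character(x$catalog$clock_class[cat_idx]),
      qualifies = weight_reaches(.data$weight, back_min_class, x$thresholds)
    )

  contacts <- purrr::map(shared$partner, function(tgt) {
    b <- back |> dplyr::filter(.data$pre == tgt)
    tibble(
      clock = b$post, clock_label = b$clock_label,
      clock_class = b$clock_class, weight = b$weight,
      class = as.character(b$class), qualifies = b$qualifies
    ) |> dplyr::arrange(dplyr::desc(.data$weight), .data$clock)
  })

  base <- shared
  class(base) <- setdiff(class(base), "shared_partner_report")
  report <- base |>
    dplyr::select("partner", "label", "n_members", "total") |>
    dplyr::rename(target = "partner") |>
    dplyr::mutate(
      target_is_clock = .data$target %in% .env$clock_set,
      contacts = contacts,
      n_back = purrr::map_int(contacts, ~ sum(.x$qualifies)),
      is_recurrent = .data$n_back > 0
    )
  n_targets <- nrow(report)
  pct <- if (n_targets == 0) NA_real_ else {
    100 * sum(report$is_recurrent) / n_targets
  }
  structure(report,
            class = c("recurrence_report", class(report)),
            group = group, clock_set = clock_set,
            min_members = min_members,
            back_min_class = as.character(back_min_class),
            percent_recurrent = pct,
            percent_undefined = n_targets == 0,
            thresholds = x$thresholds)
}

#' Percent of a group's shared strong outputs that are recurrent
#'
#' @param report A `recurrence_report`.
#' @return A number in \[0, 100\], or `NA` when the group has no shared
#'   strong targets.
#' @export
percent_recurrent <- function(report) {
  stopifnot(inherits(report, "recurrence_report"))
  attr(report, "percent_recurrent")
}

#' @export
print.recurrence_report <- function(x, ...) {
  cat(sprintf(
    "<recurrence_report> group %s: %d shared strong target(s), %d recurrent (%s%%)\n",
    attr(x, "group")$name, nrow(x), sum(x$is_recurrent),
    format(round(attr(x, "percent_recurrent"), 1))
  ))
  NextMethod()
}

#' One-row summary of a recurrence report
#'
#' @param x A `recurrence_report`.
#' @param ... Unused.
#' @return A tibble with columns `group`, `n_targets`, `n_recurrent` and
#'   `percent_recurrent`.
#' @method glance recurrence_report
#' @export
glance.recurrence_report <- function(x, ...) {
  tibble(
    group = attr(x, "group")$name,
    n_targets = nrow(x),
    n_recurrent = sum(x$is_recurrent),
    percent_recurrent = attr(x, "percent_recurrent")
  )
}

#' Flatten a recurrence report's back-contacts
#'
#' @param x A `recurrence_report`.
#' @param ... Unused.
#' @return A tibble with one row per target/clock contact, including weak
#'   contacts (`qualifies` marks those reaching the back-contact
#'   criterion).
#' @method tidy recurrence_report
#' @export
tidy.recurrence_report <- function(x, ...) {
  x |>
    dplyr::select("target", "label", "contacts") |>
    tidyr::unnest("contacts")
}

#' Summarise recurrence across groups: the inter-clock neurons
#'
#' Combines per-group recurrence reports (which must share one clock set)
#' into the percent-recurrent table and the deduplicated roster of
#' "inter-clock" neurons — targets receiving strong shared output from at
#' least one group and contacting clock neurons in turn — annotated with
#' the groups feeding each and the clock classes it contacts.
#'
#' @param reports A list of `recurrence_report` objects.
#' @return A list with components `percent` (per-group tibble, as
#'   [glance()]) and `interclock` (tibble with columns `target`, `label`,
#'   `fed_by`, `contacts_classes`).
#' @export
interclock_summary <- function(reports) {
  stopifnot(length(reports) >= 1,
            all(purrr::map_lgl(reports, inherits, "recurrence_report")))
  clock_sets <- purrr::map(reports, attr, "clock_set")
  same <- purrr::map_lgl(clock_sets, ~ setequal(.x, clock_sets[[1]]))
  if (!all(same)) abort("all reports must share one clock_set")

  percent <- purrr::map_dfr(reports, glance)

  rec <- purrr::map_dfr(reports, function(r) {
    r |>
      dplyr::filter(.data$is_recurrent) |>
      dplyr::mutate(group = attr(r, "group")$name) |>
      dplyr::select("target", "label", "group", "contacts")
  })
  interclock <- if (nrow(rec) == 0) {
    tibble(target = numeric(), label = character(),
           fed_by = character(), contacts_classes = character())
  } else {
    rec |>
      tidyr::unnest("contacts") |>
      dplyr::filter(.data$qualifies) |>
      dplyr::summarise(
        fed_by = paste(sort(unique(.data$group)), collapse = ","),
        contacts_classes = paste(sort(unique(.data$clock_class)),
                                 collapse = ","),
        .by = c("target", "label")
      ) |>
      dplyr::arrange(.data$target)
  }
  list(percent = percent, interclock = interclock)
}

#' Edge list of the group -> target -> clock subgraph
#'
#' @param x A [connectome()] object the report was computed from.
#' @param report A `recurrence_report`.
#' @return A tibble of edges `pre`, `post`, `weight`, `role` (either
#'   `"group_to_target"` or `"target_to_clock"`).
#' @export
recurrence_subgraph <- function(x, report) {
  stopifnot(inherits(report, "recurrence_report"))
  group <- attr(report, "group")
  labs <- attr(shared_for_report(x, report), "member_labels")
  fwd <- sankey_export(shared_for_report(x, report)) |>
    dplyr::mutate(role = "group_to_target") |>
    dplyr::rename(pre = "source", post = "target")
  bwd <- tidy(report) |>
    dplyr::filter(.data$qualifies) |>
    dplyr::transmute(pre = .data$label, post = .data$clock_label,
                     weight = .data$weight, role = "target_to_clock")
  dplyr::bind_rows(fwd, bwd)
}

shared_for_report <- function(x, report) {
  shared_strong_partners(x, attr(report, "group"), "outputs",
                         min_members = attr(report, "min_members"))
}
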