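#' Read a synaptic edge-list CSV
#'
#' Parses connectivity exports in either of two dialects mirroring
#' neuPrint-style adjacency downloads:
#'
#' * **long**: columns `pre_bodyId,post_bodyId,roi,weight`, one row per
#'   connection per ROI. A row with `roi` empty or `"TOTAL"` states the
#'   pair's total weight explicitly; otherwise the total is the sum of the
#'   pair's ROI rows.
#' * **wide**: columns `pre_bodyId,post_bodyId,weight`, plus optional
#'   per-ROI columns named `roi:NAME` (zero cells mean no synapses in that
#'   ROI).
#'
#' @param path Path to a CSV file (UTF-8, header row required).
#' @param format `"long"` or `"wide"`.
#' @inheritParams connectome
#' @return A [connectome()] object.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "pre_bodyId,post_bodyId,roi,weight",
#'   "1,11,SLP,7", "1,11,SMP,5"
#' ), f)
#' read_connections(f, format = "long")
#' @export
read_connections <- function(path, format = c("long", "wide"),
                             catalog = default_catalog(),
                             thresholds = strength_thresholds(),
                             allow_autapses = FALSE, roi_level = "primary") {
  format <- match.arg(format)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (format == "long") {
    req <- c("pre_bodyId", "post_bodyId", "roi", "weight")
    if (!all(req %in% names(raw))) {
      abort(paste0(
        "long edge CSV must have columns ", paste(req, collapse = ",")
      ))
    }
    edges <- tibble(
      pre = parse_body_id(raw$pre_bodyId, path),
      post = parse_body_id(raw$post_bodyId, path),
      roi = ifelse(raw$roi %in% c("", "TOTAL") | is.na(raw$roi),
                   NA_character_, raw$roi),
      weight = parse_weight(raw$weight)
    )
  } else {
    req <- c("pre_bodyId", "post_bodyId", "weight")
    if (!all(req %in% names(raw))) {
      abort(paste0(
        "wide edge CSV must have columns ", paste(req, collapse = ",")
      ))
    }
    roi_cols <- grep("^roi:", names(raw), value = TRUE)
    base <- tibble(
      pre = parse_body_id(raw$pre_bodyId, path),
      post = parse_body_id(raw$post_bodyId, path),
      roi = NA_character_,
      weight = parse_weight(raw$weight)
    )
    roi_edges <- purrr::map_dfr(roi_cols, function(col) {
      w <- suppressWarnings(as.numeric(raw[[col]]))
      w[is.na(w)] <- 0
      keep <- w > 0
      tibble(
        pre = base$pre[keep], post = base$post[keep],
        roi = sub("^roi:", "", col), weight = w[keep]
      )
    })
    edges <- dplyr::bind_rows(base, roi_edges)
  }
  connectome(edges, catalog = catalog, thresholds = thresholds,
             allow_autapses = allow_autapses, roi_level = roi_level)
}

#' Write a connectome's edge list as a long-format CSV
#'
#' Emits one row per (pre, post, roi) weight plus a `TOTAL` row whenever a
#' connection's total exceeds its assigned per-ROI weights, so that
#' `read_connections()` recovers the table exactly.
#'
#' @param x A [connectome()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connections <- function(x, path) {
  stopifnot(inherits(x, "connectome"))
  roi_sums <- x$rois |>
    dplyr::summarise(roi_sum = sum(.data$weight), .by = c("pre", "post"))
  totals <- x$connections |>
    dplyr::left_join(roi_sums, by = c("pre", "post")) |>
    dplyr::filter(is.na(.data$roi_sum) | .data$weight > .data$roi_sum) |>
    dplyr::transmute(.data$pre, .data$post, roi = "TOTAL", .data$weight)
  out <- dplyr::bind_rows(x$rois, totals) |>
    dplyr::arrange(.data$pre, .data$post, .data$roi) |>
    dplyr::rename(pre_bodyId = "pre", post_bodyId = "post")
  readr::write_csv(out, path)
  invisible(path)
}

parse_body_id <- function(x, path) {
  out <- suppressWarnings(as.numeric(x))
  if (any(is.na(out)) || any(out < 1) || any(out != round(out))) {
    bad <- which(is.na(out) | out < 1 | out != round(out))[1]
    abort(sprintf("invalid body id at data row %d of %s", bad, path))
  }
  out
}

parse_weight <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  if (any(is.na(out)) || any(out < 1) || any(out != round(out))) {
    bad <- which(is.na(out) | out < 1 | out != round(out))[1]
    abort(sprintf(
      "weights must be positive integers (first bad data row: %d)", bad
    ))
  }
  out
}

#' Write and read labelled integer matrices as CSV
#'
#' Matrices are written with row labels in the first column (header cell
#' empty-named `label`) and column labels in the header, so that
#' `read_matrix_csv(write_matrix_csv(m, f))` round-trips exactly.
#'
#' @param m A matrix with `dimnames`.
#' @param path Output path.
#' @return `write_matrix_csv` returns `path` invisibly; `read_matrix_csv`
#'   returns the matrix.
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(is.matrix(m))
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
  df <- tibble(label = rownames(m))
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- m[, j]
  if (nrow(m) == 0) {
    df <- tibble(label = character())
    for (cn in colnames(m)) df[[cn]] <- numeric()
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    label = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$label
  m
}

#' Write an analysis report as self-describing JSON
#'
#' Serialises any of the package's report objects (shared-partner,
#' recurrence, neuropil, Jaccard reports) to JSON, embedding the strength
#' thresholds and other metadata stored on the object so the file is
#' interpretable on its own.
#'
#' @param report A report object or plain list.
#' @param path Output path.
#' @param thresholds Thresholds to record; defaults to the `thresholds`
#'   attribute of `report` when present.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path,
                              thresholds = attr(report, "thresholds")) {
  meta <- list(package = "clocknet", version = pkg_version())
  if (!is.null(thresholds)) {
    meta$thresholds <- list(
      medium_min = thresholds$medium_min,
      strong_min = thresholds$strong_min
    )
  }
  for (a in c("direction", "min_class", "min_members", "roi_level", "basis",
              "empty_sets_zero")) {
    if (!is.null(attr(report, a))) meta[[a]] <- attr(report, a)
  }
  payload <- list(metadata = meta, report = strip_attrs(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

strip_attrs <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.matrix(x)) {
    return(list(rows = rownames(x), cols = colnames(x),
                values = unclass(unname(x))))
  }
  if (is.list(x)) return(lapply(x, strip_attrs))
  x
}

pkg_version <- function() {
  as.character(utils::packageVersion("clocknet"))
}
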