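#' Assemble a pipeline run configuration
#'
#' Collects everything one end-to-end analysis needs: input paths, strength
#' thresholds, group definitions and analysis options. Configurations
#' round-trip losslessly through YAML via [write_run_config()] /
#' [read_run_config()].
#'
#' @param edges Path to the edge-list CSV.
#' @param format Edge-list dialect, `"long"` or `"wide"`.
#' @param catalog Optional path to a catalog CSV; `NULL` uses
#'   [default_catalog()].
#' @param medium_min,strong_min Strength thresholds.
#' @param groups Named list of body-id vectors; `NULL` derives the
#'   functional groups (M, E1, E2, E3) from the catalog.
#' @param min_members Shared-partner criterion.
#' @param back_min_class Recurrence back-contact criterion.
#' @param roi_basis Neuropil percentage basis.
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed recorded with the run.
#' @return A `run_config` list.
#' @export
run_config <- function(edges, format = "long", catalog = NULL,
                       medium_min = 3, strong_min = 10, groups = NULL,
                       min_members = 2, back_min_class = "medium",
                       roi_basis = "synapse_weight", out_dir = "results",
                       seed = 1) {
  structure(
    list(
      edges = edges, format = format, catalog = catalog,
      medium_min = as.integer(medium_min),
      strong_min = as.integer(strong_min),
      groups = groups, min_members = as.integer(min_members),
      back_min_class = back_min_class, roi_basis = roi_basis,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw[setdiff(names(raw), "groups")])
  if (!is.null(raw$groups)) {
    cfg$groups <- purrr::map(raw$groups, as.numeric)
  }
  cfg
}

#' Run the full connectomic analysis pipeline
#'
#' Executes every stage on one edge list and writes a report bundle with
#' fixed filenames into `config$out_dir`: the pairwise clock connectivity
#' matrix (weak included), per-cell synapse totals, input and output
#' Jaccard matrices over the grouped cells, shared strong partner reports
#' per group and direction, recurrence reports with the percent-recurrent
#' table and inter-clock roster, neuropil profiles, and the
#' class-aggregated medium-plus-strong matrix. A manifest records the
#' package version, configuration and its hash; identical inputs and
#' configuration give byte-identical bundles.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the computed objects and `files`, the
#'   written paths.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  thresholds <- strength_thresholds(config$medium_min, config$strong_min)
  catalog <- if (is.null(config$catalog)) {
    default_catalog()
  } else {
    read_catalog(config$catalog)
  }
  x <- read_connections(config$edges, format = config$format,
                        catalog = catalog, thresholds = thresholds)
  if (nrow(x$connections) == 0) {
    warn("edge list is empty; emitting empty reports")
  }

  groups <- config$groups
  if (is.null(groups)) {
    present <- setdiff(as.character(unique(catalog$functional_group)),
                       "none")
    groups <- stats::setNames(
      purrr::map(present, group_members, catalog = catalog), present
    )
  }
  groups <- purrr::keep(groups, ~ length(.x) >= 2)
  grouped_cells <- unlist(groups, use.names = FALSE)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  files <- character()

  clock_cells <- catalog$body_id[!catalog$is_fragment]
  pw <- pairwise_matrix(x, clock_cells, min_class = "weak")
  files <- c(files, write_matrix_csv(unclass_matrix(pw),
                                     path("pairwise_clock_matrix.csv")))

  totals <- synapse_totals(x, grouped_cells)
  readr::write_csv(totals, path("synapse_totals.csv"))
  files <- c(files, path("synapse_totals.csv"))

  jac <- list()
  for (dir in c("inputs", "outputs")) {
    jm <- jaccard_matrix(x, grouped_cells, direction = dir)
    jac[[dir]] <- jm
    files <- c(files, write_jaccard_csv(jm, path(sprintf("jaccard_%s.csv",
                                                         dir))))
  }

  shared <- list()
  for (gname in names(groups)) {
    for (dir in c("inputs", "outputs")) {
      rep <- shared_strong_partners(
        x, cell_group(gname, groups[[gname]]), dir,
        min_members = config$min_members
      )
      shared[[paste(gname, dir, sep = "_")]] <- rep
      f <- path(sprintf("shared_%s_%s.csv", gname, dir))
      readr::write_csv(as_tibble(rep), f)
      files <- c(files, f)
    }
  }

  clock_set <- intersect(catalog$body_id[!catalog$is_fragment],
                         unique(c(x$connections$pre, x$connections$post,
                                  catalog$body_id)))
  recurrence <- purrr::imap(groups, function(ids, gname) {
    recurrent_targets(x, cell_group(gname, ids), clock_set = clock_set,
                      min_members = config$min_members,
                      back_min_class = config$back_min_class)
  })
  for (gname in names(recurrence)) {
    f <- path(sprintf("recurrence_%s.json", gname))
    rep <- recurrence[[gname]]
    write_report_json(
      list(glance = glance(rep), contacts = tidy(rep)), f,
      thresholds = thresholds
    )
    files <- c(files, f)
  }
  if (length(recurrence)) {
    ic <- interclock_summary(unname(recurrence))
    readr::write_csv(ic$percent, path("percent_recurrent.csv"))
    readr::write_csv(ic$interclock, path("interclock_neurons.csv"))
    files <- c(files, path("percent_recurrent.csv"),
               path("interclock_neurons.csv"))
  } else {
    ic <- NULL
  }

  if (length(groups)) {
    ca <- class_aggregate(x, groups, min_class = "medium")
    files <- c(files, write_matrix_csv(unclass_matrix(ca),
                                       path("class_aggregate.csv")))
  } else {
    ca <- NULL
  }

  np <- neuropil_profiles(x, grouped_cells, direction = "outputs",
                          basis = config$roi_basis)
  readr::write_csv(np, path("neuropil_outputs.csv"))
  files <- c(files, path("neuropil_outputs.csv"))

  manifest <- list(
    package = "clocknet", version = pkg_version(),
    config = unclass(config), config_hash = config_hash(config)
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files <- c(files, path("manifest.json"))

  invisible(list(
    connectome = x, pairwise = pw, totals = totals, jaccard = jac,
    shared = shared, recurrence = recurrence, interclock = ic,
    class_aggregate = ca, neuropil = np, files = files
  ))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}
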