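#' Specify a synthetic connectome with planted group structure
#'
#' The generator emulates the statistical skeleton of a clock-style
#' connectome: a few labelled cell groups whose members converge onto
#' per-group pools of strong shared targets, strength-stratified integer
#' weights (weak 1-2, medium 3-9, strong >= 10 by construction), a
#' background of weak noise edges, an ROI label on every connection, and a
#' planted fraction of targets that project back onto the labelled cells
#' (recurrence). Ground truth is returned alongside the table so recovery
#' by the analysis pipeline can be scored.
#'
#' @param n_groups Number of planted groups.
#' @param members_per_group Cells per group (>= 2).
#' @param shared_pool_size Strong shared targets planted per group.
#' @param cross_group_overlap Probability that a group's pool slot reuses a
#'   target already planted for an earlier group (0 = disjoint pools).
#' @param p_member_hits_target Probability that each member strongly
#'   contacts a given group target; per target, hits are redrawn until at
#'   least two members contact it, so every planted target satisfies the
#'   shared criterion.
#' @param strong_weight_mean Mean of the geometric excess over the strong
#'   floor: strong weights are `10 + Geometric(mean = strong_weight_mean)`,
#'   mimicking the heavy upper tail of empirical strong-connection weights.
#' @param background_edge_prob Probability of a noise edge between any
#'   ordered pair of distinct cells not already connected.
#' @param background_weight_max Largest background weight; the default 2
#'   keeps noise in the weak stratum so it never enters medium-plus-strong
#'   partner sets (raise to at most 9 to admit medium noise).
#' @param recurrence_prob Per-target probability of a medium back-edge onto
#'   a random group cell; scalar or one value per group.
#' @param roi_vocab ROI names available to the generator.
#' @param roi_preference Optional `n_groups x length(roi_vocab)` matrix of
#'   sampling weights; by default each group places 70% of its connections
#'   in its own preferred ROI.
#' @param n_bystanders Unlabelled cells receiving only background edges,
#'   standing in for the fragment population.
#' @param seed Integer seed driving the single RNG stream.
#' @return A `synthetic_spec` list.
#' @examples
#' synthetic_spec(seed = 1)
#' @export
synthetic_spec <- function(n_groups = 4, members_per_group = 3,
                           shared_pool_size = 30, cross_group_overlap = 0,
                           p_member_hits_target = 0.7,
                           strong_weight_mean = 8,
                           background_edge_prob = 0.01,
                           background_weight_max = 2,
                           recurrence_prob = 0.5,
                           roi_vocab = c("SLP", "SMP", "AVLP", "AME"),
                           roi_preference = NULL,
                           n_bystanders = 100, seed = 1) {
  probs <- c(cross_group_overlap, p_member_hits_target,
             background_edge_prob, recurrence_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (n_groups < 1 || members_per_group < 2 || shared_pool_size < 1) {
    abort(paste0(
      "need at least one group, two members per group and one planted ",
      "target per group"
    ))
  }
  if (!length(recurrence_prob) %in% c(1, n_groups)) {
    abort("recurrence_prob must be scalar or one value per group")
  }
  if (background_weight_max < 1 || background_weight_max > 9) {
    abort("background_weight_max must stay below the strong threshold")
  }
  if (is.null(roi_preference)) {
    roi_preference <- matrix(
      (1 - 0.7) / (length(roi_vocab) - 1),
      n_groups, length(roi_vocab),
      dimnames = list(NULL, roi_vocab)
    )
    for (g in seq_len(n_groups)) {
      roi_preference[g, ((g - 1) %% length(roi_vocab)) + 1] <- 0.7
    }
  }
  stopifnot(nrow(roi_preference) == n_groups,
            ncol(roi_preference) == length(roi_vocab))
  structure(
    list(
      n_groups = n_groups, members_per_group = members_per_group,
      shared_pool_size = shared_pool_size,
      cross_group_overlap = cross_group_overlap,
      p_member_hits_target = p_member_hits_target,
      strong_weight_mean = strong_weight_mean,
      background_edge_prob = background_edge_prob,
      background_weight_max = background_weight_max,
      recurrence_prob = rep(recurrence_prob,
                            length.out = n_groups),
      roi_vocab = roi_vocab, roi_preference = roi_preference,
      n_bystanders = n_bystanders, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic connectome with ground truth
#'
#' Draws a connectome from a [synthetic_spec()]. Output is deterministic
#' for a given spec and seed (one RNG stream; the caller's RNG state is
#' left untouched).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with components `connectome` (a [connectome()] object)
#'   and `truth` (list: `membership` tibble of `body_id`/`group` for the
#'   planted cells, `targets` per-group target id lists, `recurrent`
#'   per-group planted recurrent target ids, `roi_preference`, `spec`).
#' @examples
#' sim <- generate_connectome(synthetic_spec(seed = 42))
#' sim$connectome
#' @export
generate_connectome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  G <- spec$n_groups
  M <- spec$members_per_group
  members <- split(seq_len(G * M), rep(seq_len(G), each = M))

  # target pools: ids from 1000; later groups may reuse earlier targets
  next_id <- 1001
  pools <- vector("list", G)
  for (g in seq_len(G)) {
    pool <- numeric(spec$shared_pool_size)
    for (k in seq_len(spec$shared_pool_size)) {
      prior <- setdiff(unique(unlist(pools)), pool)
      if (length(prior) && runif(1) < spec$cross_group_overlap) {
        pool[k] <- prior[sample.int(length(prior), 1)]
      } else {
        pool[k] <- next_id
        next_id <- next_id + 1
      }
    }
    pools[[g]] <- pool
  }
  all_targets <- unique(unlist(pools))
  bystanders <- if (spec$n_bystanders > 0) {
    5000 + seq_len(spec$n_bystanders)
  } else {
    numeric()
  }

  draw_strong <- function(n) {
    10 + stats::rgeom(n, prob = 1 / (1 + spec$strong_weight_mean))
  }
  draw_roi <- function(g, n) {
    spec$roi_vocab[sample.int(length(spec$roi_vocab), n, replace = TRUE,
                              prob = spec$roi_preference[g, ])]
  }

  edges <- list()
  # planted member -> target strong edges; >= 2 hits enforced per target
  for (g in seq_len(G)) {
    for (t in pools[[g]]) {
      hits <- runif(M) < spec$p_member_hits_target
      while (sum(hits) < 2) hits <- runif(M) < spec$p_member_hits_target
      pre <- members[[g]][hits]
      edges[[length(edges) + 1]] <- tibble(
        pre = pre, post = t, roi = draw_roi(g, length(pre)),
        weight = draw_strong(length(pre))
      )
    }
  }

  # planted recurrence: medium back-edge onto a random planted cell
  owner <- stats::setNames(rep(NA_integer_, length(all_targets)),
                           all_targets)
  for (g in seq_len(G)) {
    for (t in pools[[g]]) {
      key <- as.character(t)
      if (is.na(owner[key])) owner[key] <- g
    }
  }
  all_members <- unlist(members, use.names = FALSE)
  recurrent <- stats::setNames(vector("list", G), paste0("G", seq_len(G)))
  for (t in all_targets) {
    g <- owner[as.character(t)]
    if (runif(1) < spec$recurrence_prob[g]) {
      clock <- all_members[sample.int(length(all_members), 1)]
      edges[[length(edges) + 1]] <- tibble(
        pre = t, post = clock, roi = draw_roi(g, 1),
        weight = sample(3:9, 1)
      )
      recurrent[[g]] <- c(recurrent[[g]], t)
    }
  }

  # weak background over pairs not already connected
  all_cells <- c(all_members, all_targets, bystanders)
  if (spec$background_edge_prob > 0) {
    pairs <- expand.grid(pre = all_cells, post = all_cells,
                         KEEP.OUT.ATTRS = FALSE)
    pairs <- pairs[pairs$pre != pairs$post, ]
    planted <- dplyr::bind_rows(edges)
    taken <- paste(planted$pre, planted$post)
    pairs <- pairs[!paste(pairs$pre, pairs$post) %in% taken, ]
    keep <- runif(nrow(pairs)) < spec$background_edge_prob
    bg <- pairs[keep, , drop = FALSE]
    if (nrow(bg)) {
      edges[[length(edges) + 1]] <- tibble(
        pre = bg$pre, post = bg$post,
        roi = spec$roi_vocab[sample.int(length(spec$roi_vocab), nrow(bg),
                                        replace = TRUE)],
        weight = sample(seq_len(spec$background_weight_max), nrow(bg),
                        replace = TRUE)
      )
    }
  }

  edge_tbl <- dplyr::bind_rows(edges)
  catalog <- tibble(
    body_id = all_members,
    type_label = rep(paste0("G", seq_len(G)), each = M),
    sequential_label = paste0(rep(paste0("G", seq_len(G)), each = M), "-",
                              rep(seq_len(M), G)),
    clock_class = factor("non-clock", levels = clock_class_levels),
    functional_group = factor("none", levels = functional_group_levels),
    is_fragment = FALSE
  )
  x <- connectome(edge_tbl, catalog = catalog)

  truth <- list(
    membership = tibble(
      body_id = all_members,
      group = rep(paste0("G", seq_len(G)), each = M)
    ),
    targets = stats::setNames(pools, paste0("G", seq_len(G))),
    recurrent = purrr::map(recurrent, ~ sort(unique(.x %||% numeric()))),
    roi_preference = spec$roi_preference,
    spec = spec
  )
  list(connectome = x, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score a recovered partition against planted group membership
#'
#' Compares an inferred partition of the planted cells (e.g. from
#' [cluster_by_similarity()]) with the ground truth, using the Adjusted
#' Rand Index and an exact-match flag (identical partitions up to label
#' permutation).
#'
#' @param inferred A data frame with columns `body_id` and `group`.
#' @param truth A ground-truth list from [generate_connectome()].
#' @return A tibble with columns `ari` and `exact_match`.
#' @examples
#' sim <- generate_connectome(synthetic_spec(seed = 7))
#' evaluate_recovery(sim$truth$membership, sim$truth)
#' @export
evaluate_recovery <- function(inferred, truth) {
  stopifnot(is.data.frame(inferred),
            all(c("body_id", "group") %in% names(inferred)))
  planted <- truth$membership
  if (!setequal(inferred$body_id, planted$body_id)) {
    abort("inferred partition covers a different cell universe")
  }
  ord <- match(planted$body_id, inferred$body_id)
  a <- as.integer(factor(inferred$group[ord]))
  b <- as.integer(factor(planted$group))
  ari <- mclust::adjustedRandIndex(a, b)
  exact <- identical(
    unname(split(seq_along(a), a))[order(vapply(split(seq_along(a), a),
                                                min, 1))],
    unname(split(seq_along(b), b))[order(vapply(split(seq_along(b), b),
                                                min, 1))]
  )
  tibble(ari = ari, exact_match = exact)
}
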