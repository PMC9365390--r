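test_that("generation is deterministic for a given spec and seed", {
  a <- generate_connectome(synthetic_spec(seed = 1))
  b <- generate_connectome(synthetic_spec(seed = 1))
  expect_identical(a$connectome$connections, b$connectome$connections)
  expect_identical(a$connectome$rois, b$connectome$rois)
  expect_identical(a$truth$targets, b$truth$targets)
  c_ <- generate_connectome(synthetic_spec(seed = 2))
  expect_false(identical(a$connectome$connections,
                         c_$connectome$connections))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_connectome(synthetic_spec(seed = 9)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("the noise-free limit contains only planted edges", {
  spec <- synthetic_spec(background_edge_prob = 0, recurrence_prob = 0,
                         seed = 5)
  sim <- generate_connectome(spec)
  con <- sim$connectome$connections
  members <- sim$truth$membership$body_id
  targets <- unlist(sim$truth$targets)
  expect_true(all(con$pre %in% members))
  expect_true(all(con$post %in% targets))
  expect_true(all(con$weight >= 10))
})

test_that("generated weights land in their intended strata", {
  sim <- generate_connectome(synthetic_spec(seed = 3))
  con <- sim$connectome$connections
  members <- sim$truth$membership$body_id
  targets <- unlist(sim$truth$targets)
  # member->target edges are planted strong or weak background, never medium
  fwd <- con$pre %in% members & con$post %in% targets
  expect_true(all(con$weight[fwd] >= 10 | con$weight[fwd] <= 2))
  # target->member edges are planted medium back-edges or weak background
  back <- con$pre %in% targets & con$post %in% members
  expect_true(all(con$weight[back] <= 9))
  # everything else is weak background noise
  other <- !fwd & !back
  expect_true(all(con$weight[other] <= 2))
  # planted recurrent targets all have a medium back-edge in the table
  for (g in names(sim$truth$recurrent)) {
    for (t in sim$truth$recurrent[[g]]) {
      w <- con$weight[con$pre == t & con$post %in% members]
      expect_true(any(w >= 3 & w <= 9))
    }
  }
})

test_that("every planted target satisfies the shared criterion", {
  sim <- generate_connectome(synthetic_spec(seed = 11))
  groups <- split(sim$truth$membership$body_id,
                  sim$truth$membership$group)
  for (g in names(groups)) {
    rep <- shared_strong_partners(sim$connectome, groups[[g]], "outputs")
    expect_setequal(rep$partner, sim$truth$targets[[g]])
  }
})

test_that("infeasible or malformed specs are rejected", {
  expect_error(synthetic_spec(shared_pool_size = 0), "planted")
  expect_error(synthetic_spec(members_per_group = 1), "two members")
  expect_error(synthetic_spec(p_member_hits_target = 1.2), "probabilities")
  expect_error(synthetic_spec(recurrence_prob = c(0.5, 0.5)), "per group")
  expect_error(synthetic_spec(background_weight_max = 12), "strong")
})

test_that("recovery metrics score partitions correctly", {
  sim <- generate_connectome(synthetic_spec(seed = 21))
  truth <- sim$truth
  perfect <- evaluate_recovery(truth$membership, truth)
  expect_equal(perfect$ari, 1)
  expect_true(perfect$exact_match)

  singletons <- dplyr::mutate(truth$membership,
                              group = as.character(dplyr::row_number()))
  chance <- evaluate_recovery(singletons, truth)
  expect_lt(abs(chance$ari), 0.05)
  expect_false(chance$exact_match)

  relabelled <- dplyr::mutate(truth$membership,
                              group = paste0("X", group))
  expect_true(evaluate_recovery(relabelled, truth)$exact_match)

  wrong_universe <- dplyr::mutate(truth$membership,
                                  body_id = body_id + 1000)
  expect_error(evaluate_recovery(wrong_universe, truth), "universe")
})

test_that("cross-group overlap plants shared targets across pools", {
  spec <- synthetic_spec(cross_group_overlap = 0.5, seed = 13)
  sim <- generate_connectome(spec)
  pools <- sim$truth$targets
  n_unique <- length(unique(unlist(pools)))
  n_total <- sum(lengths(pools))
  expect_lt(n_unique, n_total)
})
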