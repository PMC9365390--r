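toy <- toy_connectome()

test_that("partner sets honour direction and strength filters", {
  expect_setequal(partner_set(toy, 1, "outputs", "medium")$partner,
                  c(11, 12, 2))
  expect_setequal(partner_set(toy, 1, "outputs", "strong")$partner,
                  c(11, 12))
  expect_equal(nrow(partner_set(toy, 1, "inputs", "weak")), 0)
  expect_error(partner_set(toy, 4242, "outputs"), "unknown body id")
})

test_that("distinct strong partner counts are union sizes", {
  expect_equal(distinct_strong_partner_count(toy, c(1, 2), "outputs"), 2)
  # singleton group equals its own partner-set size
  expect_equal(distinct_strong_partner_count(toy, 1, "outputs"),
               nrow(partner_set(toy, 1, "outputs", "strong")))
})

test_that("shared strong partner reports list per-member weights", {
  rep <- shared_strong_partners(toy, c(1, 2), "outputs")
  expect_equal(rep$partner, 11)
  expect_equal(rep$n_members, 2)
  expect_equal(unname(partner_matrix(rep)[1, ]), c(12, 10))
  # min_members equal to group size gives the same single row here
  rep_all <- shared_strong_partners(toy, c(1, 2), "outputs",
                                    min_members = 2)
  expect_identical(rep_all$partner, rep$partner)
  expect_error(shared_strong_partners(toy, c(1, 2), "outputs",
                                      min_members = 3),
               "exceeds")
})

test_that("a group with no strong edges yields an empty report", {
  rep <- shared_strong_partners(toy, c(12, 13), "outputs")
  expect_equal(nrow(rep), 0)
  expect_equal(nrow(sankey_export(rep)), 0)
})

test_that("pairwise shared counts are symmetric and idempotent", {
  expect_equal(pairwise_shared_count(toy, 1, 2, "outputs"), 1)
  expect_equal(pairwise_shared_count(toy, 2, 1, "outputs"), 1)
  expect_equal(pairwise_shared_count(toy, 1, 1, "outputs"),
               nrow(partner_set(toy, 1, "outputs", "strong")))
})

test_that("sankey export conserves total flow and ignores member order", {
  rep <- shared_strong_partners(toy, c(1, 2), "outputs")
  flows <- sankey_export(rep)
  expect_equal(nrow(flows), 2)
  expect_equal(sum(flows$weight), 22)
  rep_rev <- shared_strong_partners(toy, c(2, 1), "outputs")
  flows_rev <- sankey_export(rep_rev)
  expect_equal(dplyr::arrange(flows, source),
               dplyr::arrange(flows_rev, source))
})

test_that("all partner operations agree with brute-force enumeration", {
  for (seed in 1:5) {
    rc <- random_connectome(n = 40, n_edges = 400, seed = seed)
    cells <- sample(1:40, 6)
    for (dir in c("inputs", "outputs")) {
      for (mc in c("weak", "medium", "strong")) {
        expect_setequal(
          partner_set(rc$x, cells[1], dir, mc)$partner,
          brute_partner_set(rc$edges, cells[1], dir, mc)
        )
      }
    }
    grp <- cells[1:4]
    brute_union <- unique(unlist(lapply(
      grp, brute_partner_set, edges = rc$edges,
      direction = "outputs", min_class = "strong"
    )))
    expect_equal(distinct_strong_partner_count(rc$x, grp, "outputs"),
                 length(brute_union))
    expect_setequal(
      shared_strong_partners(rc$x, grp, "outputs")$partner,
      brute_shared_partners(rc$edges, grp, 2)
    )
    expect_equal(
      pairwise_shared_count(rc$x, cells[1], cells[2], "inputs"),
      length(intersect(
        brute_partner_set(rc$edges, cells[1], "inputs", "strong"),
        brute_partner_set(rc$edges, cells[2], "inputs", "strong")
      ))
    )
  }
})

test_that("shared reports shrink (never grow) as min_members rises", {
  rc <- random_connectome(n = 25, n_edges = 300, seed = 9)
  grp <- as.numeric(1:5)
  r2 <- shared_strong_partners(rc$x, grp, "outputs", min_members = 2)
  r3 <- shared_strong_partners(rc$x, grp, "outputs", min_members = 3)
  expect_true(all(r3$partner %in% r2$partner))
})

test_that("member partners can be excluded on request", {
  rep <- shared_strong_partners(toy, c(1, 11), "outputs",
                                exclude_members = FALSE)
  rep_ex <- shared_strong_partners(toy, c(1, 11), "outputs",
                                   exclude_members = TRUE)
  expect_true(all(!rep_ex$partner %in% c(1, 11)))
  expect_true(nrow(rep_ex) <= nrow(rep))
})
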