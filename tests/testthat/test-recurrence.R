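toy <- toy_connectome()

test_that("the toy group's single shared target recurs onto the clock set", {
  rep <- recurrent_targets(toy, c(1, 2), clock_set = c(21, 1, 2))
  expect_equal(rep$target, 11)
  expect_true(rep$is_recurrent)
  contacts <- rep$contacts[[1]]
  expect_equal(contacts$clock, 21)
  expect_equal(contacts$weight, 5)
  expect_equal(percent_recurrent(rep), 100)
})

test_that("a clock set no target contacts gives zero percent recurrent", {
  rep <- recurrent_targets(toy, c(1, 2), clock_set = 13)
  expect_equal(nrow(rep), 1)
  expect_false(any(rep$is_recurrent))
  expect_equal(percent_recurrent(rep), 0)
})

test_that("percent recurrent is undefined without shared targets", {
  rep <- recurrent_targets(toy, c(12, 13), clock_set = 21)
  expect_equal(nrow(rep), 0)
  expect_true(is.na(percent_recurrent(rep)))
  expect_true(attr(rep, "percent_undefined"))
})

test_that("weak back-contacts are listed but never set the flag", {
  edges <- tibble::tibble(
    pre = c(1, 2, 11), post = c(11, 11, 21), roi = "SLP",
    weight = c(10, 10, 2)
  )
  x <- connectome(edges, catalog = clocknet:::fragment_records(c(1, 2, 11, 21)))
  rep <- recurrent_targets(x, c(1, 2), clock_set = 21)
  expect_false(rep$is_recurrent[1])
  contacts <- rep$contacts[[1]]
  expect_equal(nrow(contacts), 1)
  expect_false(contacts$qualifies)
})

test_that("raising the back-contact class never raises percent recurrent", {
  for (seed in 1:5) {
    rc <- random_connectome(n = 30, n_edges = 400, seed = seed)
    grp <- as.numeric(1:4)
    clock <- as.numeric(1:10)
    med <- recurrent_targets(rc$x, grp, clock, back_min_class = "medium")
    if (nrow(med) == 0) next
    strong <- recurrent_targets(rc$x, grp, clock,
                                back_min_class = "strong")
    expect_lte(percent_recurrent(strong), percent_recurrent(med))
  }
})

test_that("clock targets are flagged and still count as recurrent", {
  edges <- tibble::tibble(
    pre = c(1, 2, 21), post = c(21, 21, 1), roi = "SLP",
    weight = c(10, 12, 5)
  )
  x <- connectome(edges, catalog = clocknet:::fragment_records(c(1, 2, 21)))
  rep <- recurrent_targets(x, c(1, 2), clock_set = c(1, 2, 21))
  expect_equal(rep$target, 21)
  expect_true(rep$target_is_clock)
  expect_true(rep$is_recurrent)
})

test_that("every reported back-contact exists in the connection table", {
  rc <- random_connectome(n = 30, n_edges = 400, seed = 7)
  rep <- recurrent_targets(rc$x, as.numeric(1:4), as.numeric(1:10))
  audit <- tidy(rep)
  for (i in seq_len(nrow(audit))) {
    hit <- rc$edges$pre == audit$target[i] & rc$edges$post == audit$clock[i]
    expect_equal(sum(hit), 1)
    expect_equal(rc$edges$weight[hit], audit$weight[i])
  }
})

test_that("interclock summaries combine groups and reject mixed clock sets", {
  r1 <- recurrent_targets(toy, c(1, 2), clock_set = c(21, 1, 2))
  s <- interclock_summary(list(r1))
  expect_equal(s$percent$percent_recurrent, 100)
  expect_equal(s$interclock$target, 11)
  r_other <- recurrent_targets(toy, c(1, 2), clock_set = 13)
  expect_error(interclock_summary(list(r1, r_other)), "clock_set")
})

test_that("percent recurrent is invariant to target id relabelling", {
  edges <- tibble::tibble(
    pre = c(1, 2, 50), post = c(50, 50, 3), roi = "A", weight = c(10, 10, 5)
  )
  relabel <- tibble::tibble(
    pre = c(1, 2, 900), post = c(900, 900, 3), roi = "A",
    weight = c(10, 10, 5)
  )
  x1 <- connectome(edges, clocknet:::fragment_records(c(1:3, 50)))
  x2 <- connectome(relabel, clocknet:::fragment_records(c(1:3, 900)))
  p1 <- percent_recurrent(recurrent_targets(x1, c(1, 2), clock_set = 1:3))
  p2 <- percent_recurrent(recurrent_targets(x2, c(1, 2), clock_set = 1:3))
  expect_equal(p1, p2)
})
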