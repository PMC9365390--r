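write_csv_lines <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("long-format rows for one pair sum to the connection total", {
  f <- write_csv_lines(c(
    "pre_bodyId,post_bodyId,roi,weight",
    "1,11,SLP,12"
  ))
  x <- read_connections(f, "long", catalog = toy_connectome()$catalog)
  expect_equal(nrow(x$connections), 1)
  expect_equal(x$connections$weight, 12)
  expect_equal(x$rois$roi, "SLP")

  f2 <- write_csv_lines(c(
    "pre_bodyId,post_bodyId,roi,weight",
    "1,11,SLP,7",
    "1,11,SMP,5"
  ))
  x2 <- read_connections(f2, "long", catalog = toy_connectome()$catalog)
  expect_equal(nrow(x2$connections), 1)
  expect_equal(x2$connections$weight, 12)
  expect_equal(nrow(x2$rois), 2)
})

test_that("a TOTAL row may exceed its per-ROI breakdown but not vice versa", {
  f <- write_csv_lines(c(
    "pre_bodyId,post_bodyId,roi,weight",
    "1,11,TOTAL,10",
    "1,11,SLP,7"
  ))
  x <- read_connections(f, "long", catalog = toy_connectome()$catalog)
  expect_equal(x$connections$weight, 10)

  f_bad <- write_csv_lines(c(
    "pre_bodyId,post_bodyId,roi,weight",
    "1,11,TOTAL,5",
    "1,11,SLP,7"
  ))
  expect_error(read_connections(f_bad, "long",
                                catalog = toy_connectome()$catalog),
               "exceed")
})

test_that("malformed edge files raise informative errors", {
  f_cols <- write_csv_lines(c("a,b", "1,2"))
  expect_error(read_connections(f_cols, "long"), "columns")
  f_zero <- write_csv_lines(c(
    "pre_bodyId,post_bodyId,weight", "1,11,0"
  ))
  expect_error(read_connections(f_zero, "wide"), "positive integers")
  f_frac <- write_csv_lines(c(
    "pre_bodyId,post_bodyId,roi,weight", "1,11,SLP,2.5"
  ))
  expect_error(read_connections(f_frac, "long"), "positive integers")
})

test_that("wide format with roi columns matches the long-form table", {
  f <- write_csv_lines(c(
    "pre_bodyId,post_bodyId,weight,roi:SLP,roi:SMP",
    "1,11,12,7,5",
    "2,13,4,0,4"
  ))
  x <- read_connections(f, "wide", catalog = toy_connectome()$catalog)
  expect_equal(x$connections$weight, c(12, 4))
  expect_equal(nrow(x$rois), 3)
})

test_that("ingest is order-independent", {
  lines <- c(
    "1,11,SLP,7", "1,11,SMP,5", "2,11,SLP,10", "1,12,SMP,11"
  )
  hdr <- "pre_bodyId,post_bodyId,roi,weight"
  cat6 <- toy_connectome()$catalog
  a <- read_connections(write_csv_lines(c(hdr, lines)), "long", cat6)
  b <- read_connections(write_csv_lines(c(hdr, rev(lines))), "long", cat6)
  expect_identical(a$connections, b$connections)
  expect_identical(a$rois, b$rois)
})

test_that("duplicate edge keys are summed with a warning", {
  edges <- tibble::tibble(
    pre = c(1, 1), post = c(11, 11), roi = c("SLP", "SLP"),
    weight = c(4, 6)
  )
  expect_warning(x <- connectome(edges, toy_connectome()$catalog),
                 "duplicate")
  expect_equal(x$connections$weight, 10)
})

test_that("autapses are rejected unless explicitly admitted", {
  edges <- tibble::tibble(pre = 1, post = 1, roi = "SLP", weight = 5)
  expect_error(connectome(edges, toy_connectome()$catalog), "autapses")
  x <- connectome(edges, toy_connectome()$catalog, allow_autapses = TRUE)
  expect_equal(nrow(x$connections), 1)
})

test_that("uncatalogued endpoints are added as fragments", {
  edges <- tibble::tibble(pre = 1, post = 999, roi = "SLP", weight = 5)
  x <- connectome(edges, toy_connectome()$catalog)
  frag <- x$catalog[x$catalog$body_id == 999, ]
  expect_true(frag$is_fragment)
  expect_equal(as.character(frag$clock_class), "non-clock")
})

test_that("matrix CSV round-trips exactly, including edge cases", {
  m <- matrix(c(5L), 1, 1, dimnames = list("a", "b"))
  f <- tempfile(fileext = ".csv")
  write_matrix_csv(m, f)
  expect_equal(read_matrix_csv(f), m, ignore_attr = FALSE)

  toy <- toy_connectome()
  pw <- pairwise_matrix(toy, c(1, 2, 11, 12, 13))
  write_matrix_csv(clocknet:::unclass_matrix(pw), f)
  expect_equal(read_matrix_csv(f), clocknet:::unclass_matrix(pw))

  empty <- matrix(numeric(), 0, 0)
  write_matrix_csv(empty, f)
  expect_equal(nrow(read_matrix_csv(f)), 0)
})

test_that("edge-list CSV round-trips through write_connections", {
  toy <- toy_connectome()
  f <- tempfile(fileext = ".csv")
  write_connections(toy, f)
  back <- read_connections(f, "long", catalog = toy$catalog)
  expect_identical(back$connections, toy$connections)
  expect_identical(back$rois, toy$rois)
})

test_that("JSON reports embed the thresholds used", {
  toy <- toy_connectome()
  rep <- shared_strong_partners(toy, c(1, 2), "outputs")
  f <- tempfile(fileext = ".json")
  write_report_json(rep, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$metadata$thresholds$medium_min, 3)
  expect_equal(parsed$metadata$thresholds$strong_min, 10)
  expect_equal(parsed$metadata$direction, "outputs")
})
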