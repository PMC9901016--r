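consistency_toy <- function() {
  pops <- hierarchy_nodes(default_ssc_hierarchy())
  patterns <- list(
    c("CD24+CD29+"),                          # root only: consistent
    c("CD29+", "CD105+", "THY+"),             # one subtree: consistent
    c("CD24+"),                               # private leaf: consistent
    c("CD24+CD29+", "CD24+", "CD29+"),        # root + two daughters: consistent
    c("CD24+", "CD29+"),                      # two branches, no root: not
    c("CD105+", "THY+")                       # two cousins, no ancestor: not
  )
  spec <- purrr::map_dfr(seq_along(patterns), function(v) {
    af <- ifelse(pops %in% patterns[[v]], 0.1, 0)
    data.frame(population = pops, position = v * 100L, ref = "C", alt = "T",
               af_fwd = af, af_rev = af, depth = 400)
  })
  compute_heteroplasmy(toy_counts(spec))
}

test_that("single-origin inheritance patterns score as enumerated (4 of 6)", {
  m <- consistency_toy()
  res <- hierarchy_consistency(m, default_ssc_hierarchy(), tau = 0.01,
                               R = 99, seed = 1)
  expect_equal(res$score, 4 / 6, tolerance = 1e-12)
  v <- tidy(res)
  expect_equal(sum(v$consistent), 4L)
  expect_equal(v$top[v$variant == "200C>T"], "CD29+")
  expect_false(v$consistent[v$variant == "500C>T"])
  expect_false(v$consistent[v$variant == "600C>T"])
  g <- glance(res)
  expect_equal(g$n_observed, 6L)
  expect_equal(g$n_consistent, 4L)
})

test_that("the relabeling null is deterministic given the seed and sized R", {
  m <- consistency_toy()
  a <- hierarchy_consistency(m, default_ssc_hierarchy(), R = 199, seed = 5)
  b <- hierarchy_consistency(m, default_ssc_hierarchy(), R = 199, seed = 5)
  expect_identical(a$null_scores, b$null_scores)
  expect_length(a$null_scores, 199)
  expect_true(a$p_value >= 1 / 200 && a$p_value <= 1)
})

test_that("populations missing from the hierarchy raise an error", {
  m <- consistency_toy()
  h_small <- hierarchy(data.frame(parent = "CD24+CD29+", child = "CD24+"))
  expect_error(hierarchy_consistency(m, h_small), "missing from the hierarchy")
})

test_that("consistency JSON report is written and machine-readable", {
  m <- consistency_toy()
  res <- hierarchy_consistency(m, default_ssc_hierarchy(), R = 99, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_consistency(res, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$score, res$score)
  expect_equal(nrow(back$verdicts), 6L)
})
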