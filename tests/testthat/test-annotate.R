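markers12 <- names(default_cell_signatures()[[1]])

cell_row <- function(high) {
  vals <- setNames(as.list(ifelse(markers12 %in% high, 0.9, 0.04)), markers12)
  tibble::tibble(cell = 1L, roi = "r", x = 1, y = 1, area = 10L, !!!vals)
}

abs_scheme <- function() {
  default_gating_scheme(mode = "absolute",
                        thresholds = setNames(rep(0.5, length(markers12)),
                                              markers12))
}

test_that("the SSC marker pattern is annotated P1", {
  cells <- cell_row(c("CD24", "CD29", "CD200"))
  ann <- annotate_types(cells, abs_scheme())
  expect_equal(ann$type, "P1")
})

test_that("cells matching no predicate are unassigned", {
  zero <- cell_row(character(0))
  ann <- annotate_types(zero, abs_scheme())
  expect_equal(ann$type, "unassigned")
})

test_that("each signature maps to its own label under the default scheme", {
  sigs <- default_cell_signatures()
  cells <- purrr::imap_dfr(sigs, function(sig, lbl) {
    cell_row(names(sig)[sig >= 0.5])
  })
  cells$cell <- seq_len(nrow(cells))
  ann <- annotate_types(cells, abs_scheme())
  expect_equal(ann$type, names(sigs))
})

test_that("simulated images annotate to truth at default noise", {
  agree <- vapply(1:2, function(s) {
    ly <- image_layout(cell_counts = c(P1 = 12, P2 = 12, P3 = 13, P4 = 13))
    mi <- simulate_image(ly, seed = s)
    ann <- annotate_types(quantify_cells(mi, segment_cells(mi)),
                          default_gating_scheme())
    m <- match_cells(mi$cells, ann)
    mean(m$called[m$err <= 2] == mi$cells$type[m$err <= 2])
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})

test_that("schemes referencing unknown channels are rejected", {
  cells <- cell_row("CD24")
  sch <- gating_scheme(list(list(label = "X", above = "CD999", below = NULL)),
                       mode = "absolute", thresholds = c(CD999 = 1))
  expect_error(annotate_types(cells, sch), "unknown channel")
})

test_that("quantile thresholds mark the top fraction positive", {
  cells <- purrr::map_dfr(1:20, function(i) {
    r <- cell_row(character(0)); r$cell <- i; r$CD24 <- i / 20; r
  })
  sch <- gating_scheme(list(list(label = "hi", above = "CD24", below = NULL)),
                       mode = "quantile", q = 0.75)
  ann <- annotate_types(cells, sch)
  # values at/above the interpolated 75th percentile of 0.05..1.00
  expect_equal(sum(ann$type == "hi"), 5L)
})

test_that("gating schemes round-trip through JSON", {
  sch <- default_gating_scheme()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_gating_scheme(sch, tmp)
  back <- read_gating_scheme(tmp)
  expect_equal(length(back$types), length(sch$types))
  expect_equal(back$types[[1]]$label, "P1")
  expect_setequal(back$types[[1]]$above, sch$types[[1]]$above)
  expect_equal(back$mode, sch$mode)
})
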