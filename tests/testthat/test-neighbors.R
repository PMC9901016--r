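test_that("one focal and one other cell give probability 1 for that type", {
  cells <- tibble::tibble(cell = 1:2, roi = "r", x = c(0, 3), y = c(0, 0),
                          type = c("P1", "P3"))
  nn <- nearest_neighbor_composition(cells, "P1")
  expect_equal(nn$prob[nn$neighbor_type == "P3"], 1)
  expect_equal(nn$prob[nn$neighbor_type == "P1"], 0)
  expect_equal(unique(nn$n_focal), 1L)
})

test_that("composition matches the brute-force oracle on random instances", {
  types <- paste0("P", 1:4)
  for (s in 1:200) {
    n <- sample(3:60, 1)
    cc <- random_roi(n, seed = 1000 + s)
    got <- nearest_neighbor_composition(cc, "P1", types = types)
    want <- brute_force_nn(cc, "P1", types)
    if (want$n_focal == 0) {
      expect_true(all(got$degenerate))
    } else {
      expect_identical(setNames(got$count, got$neighbor_type), want$counts)
      expect_equal(unique(got$n_focal), want$n_focal)
    }
  }
})

test_that("tied distances resolve to the smallest cell id", {
  # two candidate neighbours exactly 5 px away on either side
  cells <- tibble::tibble(cell = c(4L, 9L, 2L), roi = "r",
                          x = c(0, 5, -5), y = 0,
                          type = c("P1", "P2", "P3"))
  nn <- nearest_neighbor_composition(cells, "P1")
  expect_equal(nn$count[nn$neighbor_type == "P3"], 1L)  # cell id 2 < 9
  expect_equal(nn$count[nn$neighbor_type == "P2"], 0L)
})

test_that("results are invariant under translation and rotation", {
  cc <- random_roi(80, seed = 7)
  base <- nearest_neighbor_composition(cc, "P1")
  th <- 0.83
  rot <- dplyr::mutate(cc,
                       x0 = x, y0 = y,
                       x = cos(th) * x0 - sin(th) * y0 + 112,
                       y = sin(th) * x0 + cos(th) * y0 - 40)
  moved <- nearest_neighbor_composition(rot, "P1")
  expect_equal(moved$count, base$count)
  expect_equal(moved$prob, base$prob)
})

test_that("probabilities sum to one and counts to the focal total per ROI", {
  cc <- dplyr::bind_rows(random_roi(40, seed = 11),
                         dplyr::mutate(random_roi(25, seed = 12), roi = "r2",
                                       cell = cell + 100L))
  nn <- nearest_neighbor_composition(cc, "P1")
  sums <- dplyr::summarise(dplyr::group_by(nn, roi),
                           p = sum(prob), n = sum(count),
                           nf = unique(n_focal))
  expect_equal(sums$p, c(1, 1))
  expect_equal(sums$n, as.integer(sums$nf))
})

test_that("an all-focal ROI concentrates the distribution on the focal type", {
  cc <- dplyr::mutate(random_roi(30, seed = 13), type = "P1")
  nn <- nearest_neighbor_composition(cc, "P1")
  expect_equal(nn$prob[nn$neighbor_type == "P1"], 1)
})

test_that("ROIs below two cells or with no focal cell are flagged", {
  one <- tibble::tibble(cell = 1L, roi = "r", x = 0, y = 0, type = "P1")
  expect_true(all(nearest_neighbor_composition(one, "P1")$degenerate))
  nofocal <- tibble::tibble(cell = 1:3, roi = "r", x = 1:3, y = 0, type = "P2")
  expect_true(all(nearest_neighbor_composition(nofocal, "P1")$degenerate))
})

test_that("pooling across ROIs renormalises over all focal cells", {
  cc <- dplyr::bind_rows(random_roi(40, seed = 14),
                         dplyr::mutate(random_roi(40, seed = 15), roi = "r2",
                                       cell = cell + 100L))
  nn <- nearest_neighbor_composition(cc, "P1")
  pooled <- pool_neighbors(nn)
  expect_equal(sum(pooled$prob), 1)
  expect_equal(sum(pooled$count), sum(nn$count))
})
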