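test_that("an empty layout renders noise-only channels", {
  ly <- image_layout(width = 64, height = 64, cell_counts = c(P1 = 0))
  mi <- simulate_image(ly, seed = 1)
  expect_equal(nrow(mi$cells), 0L)
  expect_equal(dim(mi$image), c(64, 64, 13))
  # pure Gaussian noise: nothing approaching a rendered cell
  expect_lt(max(mi$image), 6 * ly$noise_sd)
})

test_that("50 rendered nuclei give 50 truth rows and 50 smoothed local maxima", {
  ly <- image_layout(cell_counts = c(P1 = 25, P3 = 25))
  mi <- simulate_image(ly, seed = 2)
  expect_equal(nrow(mi$cells), 50L)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(mi$image[, , "DNA"]),
                                 sigma = 2))
  # local maxima: strictly greater than the 8-neighbourhood, above noise
  W <- nrow(sm); H <- ncol(sm)
  inner <- sm[2:(W - 1), 2:(H - 1)]
  is_max <- inner > 0.3
  for (dx in -1:1) for (dy in -1:1) {
    if (dx || dy) {
      is_max <- is_max & inner >= sm[2:(W - 1) + dx, 2:(H - 1) + dy]
    }
  }
  expect_equal(sum(is_max), 50L)
})

test_that("channel means inside a cell follow its type signature", {
  ly <- image_layout(width = 96, height = 96, cell_counts = c(P1 = 3),
                     noise_sd = 0)
  mi <- simulate_image(ly, seed = 3)
  cc <- mi$cells[1, ]
  rc <- cc$nucleus_radius * ly$cell_radius_factor
  xs <- round(cc$x) + (-2:2); ys <- round(cc$y) + (-2:2)
  for (mk in c("CD24", "CD29", "CD200")) {
    expect_true(all(mi$image[xs, ys, mk] == 1.0))
  }
  for (mk in c("THY", "CD105", "Lin")) {
    expect_true(all(mi$image[xs, ys, mk] == 0.05))
  }
})

test_that("uniform placement passes a CSR quadrat test in almost all seeds", {
  # index-of-dispersion chi-square on a 4x4 quadrat grid over the
  # placement window, two-sided at alpha = 0.01; a small hard core keeps
  # the pattern indistinguishable from CSR at this density
  ly <- image_layout(cell_counts = c(P1 = 50), min_sep = 6)
  margin <- max(ly$nucleus_radius) * ly$cell_radius_factor + 1
  lo <- qchisq(0.005, df = 15); hi <- qchisq(0.995, df = 15)
  pass <- vapply(1:100, function(s) {
    cells <- simulate_cell_positions(ly, seed = s)
    gx <- cut(cells$x, breaks = seq(margin, ly$width - margin, length.out = 5),
              include.lowest = TRUE)
    gy <- cut(cells$y, breaks = seq(margin, ly$height - margin, length.out = 5),
              include.lowest = TRUE)
    counts <- table(gx, gy)
    x2 <- sum((counts - mean(counts))^2 / mean(counts))
    x2 >= lo && x2 <= hi
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("infeasible layouts error instead of overlapping", {
  ly <- image_layout(width = 48, height = 48, cell_counts = c(P1 = 200),
                     max_tries = 50)
  expect_error(simulate_image(ly, seed = 1), "could not place")
})

test_that("image simulation is deterministic given the seed", {
  ly <- image_layout(width = 96, height = 96, cell_counts = c(P1 = 5, P2 = 5))
  a <- simulate_image(ly, seed = 8)
  b <- simulate_image(ly, seed = 8)
  expect_identical(a$image, b$image)
  expect_identical(a$cells, b$cells)
})

test_that("multi-channel TIFF round-trips with channel names", {
  ly <- image_layout(width = 64, height = 64, cell_counts = c(P1 = 3))
  mi <- simulate_image(ly, seed = 4)
  tmp <- withr::local_tempfile(fileext = ".tiff")
  write_marker_image(mi, tmp)
  withr::defer(unlink(paste0(tmp, ".channels.json")))
  back <- read_marker_image(tmp)
  expect_equal(dimnames(back)[[3]], dimnames(mi$image)[[3]])
  clamped <- pmin(pmax(mi$image, 0), 1)
  expect_lt(max(abs(back - clamped)), 1e-6)  # float32 pages
})
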