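block_counts <- function(jitter = 0) {
  # A and B share one variant block, C and D the orthogonal block
  pops <- c("A", "B", "C", "D")
  hi <- c(0.40, 0.42, 0.01, 0.01)
  lo <- c(0.01, 0.01, 0.40, 0.42)
  spec <- purrr::map_dfr(1:6, function(v) {
    af <- if (v <= 3) hi else lo
    af <- af + jitter * (v %% 3) / 100
    data.frame(population = pops, position = v * 50L, ref = "A", alt = "G",
               af_fwd = af, af_rev = af, depth = 2000)
  })
  toy_counts(spec)
}

test_that("identical allele-fraction profiles merge first at height zero", {
  m <- compute_heteroplasmy(toy_counts(data.frame(
    population = rep(c("A", "B", "C"), each = 2),
    position = rep(c(10L, 20L), 3),
    ref = "G", alt = "T",
    af_fwd = c(0.4, 0.1, 0.4, 0.1, 0.05, 0.5),
    af_rev = c(0.4, 0.1, 0.4, 0.1, 0.05, 0.5),
    depth = 1000
  )))
  den <- cluster_populations(m)
  td <- tidy(den)
  expect_equal(td$members[1], "A|B")
  expect_lt(td$height[1], 1e-10)
})

test_that("block-structured populations recover the ((A,B),(C,D)) topology", {
  den <- cluster_populations(compute_heteroplasmy(block_counts(jitter = 1)))
  co <- cophenetic_distances(den)
  expect_lt(co["A", "B"], co["A", "C"])
  expect_lt(co["A", "B"], co["A", "D"])
  expect_lt(co["C", "D"], co["C", "A"])
  expect_lt(co["C", "D"], co["B", "D"])
  # cophenetic heights reflect exactly two clades merging last
  expect_equal(co["A", "C"], co["B", "D"])
})

test_that("clustering is equivariant under population input order", {
  counts <- as.data.frame(block_counts(jitter = 1))
  perm <- counts[order(match(counts$population, c("C", "A", "D", "B"))), ]
  den1 <- cluster_populations(compute_heteroplasmy(validate_basecounts(counts)))
  den2 <- cluster_populations(compute_heteroplasmy(validate_basecounts(perm)))
  pops <- c("A", "B", "C", "D")
  expect_equal(cophenetic_distances(den1)[pops, pops],
               cophenetic_distances(den2)[pops, pops])
})

test_that("a constant profile falls back to Euclidean distance with a warning", {
  counts <- toy_counts(data.frame(
    population = rep(c("A", "B", "Z"), each = 2),
    position = rep(c(10L, 20L), 3),
    ref = "G", alt = "T",
    af_fwd = c(0.4, 0.1, 0.38, 0.12, 0, 0),
    af_rev = c(0.4, 0.1, 0.38, 0.12, 0, 0),
    depth = 1000
  ))
  m <- compute_heteroplasmy(counts)
  expect_warning(den <- cluster_populations(m), "Euclidean")
  expect_setequal(den$hclust$labels, c("A", "B", "Z"))
  # the flat population is the outgroup
  co <- cophenetic_distances(den)
  expect_lt(co["A", "B"], co["A", "Z"])
})

test_that("dendrograms serialise to newick", {
  den <- cluster_populations(compute_heteroplasmy(block_counts(jitter = 1)))
  nwk <- write_dendrogram(den)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  expect_true(ape::is.monophyletic(tr, c("C", "D")))
})
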