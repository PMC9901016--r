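ssc_events <- function(n, seed = 1,
                       fr = c("CD24+CD29+" = 0.05, "CD24+" = 0.15,
                              "CD29+" = 0.50, "CD24-CD29-" = 0.30)) {
  transform_flow(simulate_flow_events(fr, default_flow_model(), n, seed = seed))
}

test_that("an empty event table gates to all-zero counts", {
  ev <- ssc_events(0)
  rep <- apply_gating_tree(ev, default_ssc_gate_tree())
  expect_true(all(rep$count == 0))
})

test_that("gate membership equals direct predicate evaluation per event", {
  ev <- ssc_events(2000, seed = 6)
  tree <- default_ssc_gate_tree(threshold = 1.0)
  rep <- apply_gating_tree(ev, tree)
  mem <- attr(rep, "membership")
  # independent oracle: evaluate the nested predicates literally
  t <- 1.0
  lin_neg <- ev$Lin < t
  thy6c3 <- lin_neg & ev$THY < t & ev$`6C3` < t
  ssc <- thy6c3 & ev$CD200 >= t & ev$CD105 < t
  expect_equal(mem[["Lin-"]], lin_neg)
  expect_equal(mem[["THY-6C3-"]], thy6c3)
  expect_equal(mem[["SSC"]], ssc)
  expect_equal(mem[["CD24+CD29+"]], ssc & ev$CD24 >= t & ev$CD29 >= t)
  expect_equal(mem[["CD24-CD29-"]], ssc & ev$CD24 < t & ev$CD29 < t)
  # terminal labels agree with deepest membership
  labs <- gate_labels(rep)
  expect_equal(labs == "CD24+CD29+", ssc & ev$CD24 >= t & ev$CD29 >= t)
})

test_that("quadrant gates partition their parent exactly and sum to 100%", {
  ev <- ssc_events(20000, seed = 7)
  rep <- apply_gating_tree(ev, default_ssc_gate_tree())
  quads <- c("CD24+CD29+", "CD24+CD29-", "CD24-CD29+", "CD24-CD29-")
  qr <- rep[rep$node %in% quads, ]
  expect_equal(sum(qr$count), rep$count[rep$node == "SSC"])
  expect_identical(sum(qr$pct_parent), 100)
})

test_that("gated quadrant fractions recover the simulated truth within 3 binomial SE", {
  fr <- c("CD24+CD29+" = 0.05, "CD24+" = 0.15, "CD29+" = 0.50,
          "CD24-CD29-" = 0.30)
  n <- 50000
  ev <- ssc_events(n, seed = 8, fr = fr)
  rep <- apply_gating_tree(ev, default_ssc_gate_tree())
  n_ssc <- rep$count[rep$node == "SSC"]
  got <- c(rep$count[rep$node == "CD24+CD29+"],
           rep$count[rep$node == "CD24+CD29-"],
           rep$count[rep$node == "CD24-CD29+"],
           rep$count[rep$node == "CD24-CD29-"]) / n_ssc
  want <- unname(fr[c("CD24+CD29+", "CD24+", "CD29+", "CD24-CD29-")])
  se <- sqrt(want * (1 - want) / n_ssc)
  expect_true(all(abs(got - want) <= 3 * se))
})

test_that("gating is idempotent and independent of sibling order", {
  ev <- ssc_events(3000, seed = 9)
  tree <- default_ssc_gate_tree()
  rep1 <- apply_gating_tree(ev, tree)
  # shuffle gate rows (siblings and within-node condition order)
  g <- tree$gates[rev(seq_len(nrow(tree$gates))), ]
  rep2 <- apply_gating_tree(ev, gate_tree(g))
  r1 <- dplyr::arrange(as.data.frame(rep1), node)
  r2 <- dplyr::arrange(as.data.frame(rep2), node)
  expect_equal(r1$count, r2$count)
  expect_identical(apply_gating_tree(ev, tree)$count, rep1$count)
})

test_that("raising a positivity threshold never grows a positive gate", {
  ev <- ssc_events(5000, seed = 10)
  counts <- sapply(c(0.8, 1.0, 1.2, 1.5), function(t) {
    tree <- default_ssc_gate_tree()
    g <- tree$gates
    g$threshold[g$marker == "CD24" & g$side == "+"] <- t
    rep <- apply_gating_tree(ev, gate_tree(g))
    rep$count[rep$node == "CD24+CD29+"]
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("unknown markers and malformed trees are rejected", {
  ev <- ssc_events(50)
  bad <- gate_tree(tibble::tibble(node = "X", parent = "all",
                                  marker = "CD999", side = "+",
                                  threshold = 1))
  expect_error(apply_gating_tree(ev, bad), "CD999")
  expect_error(gate_tree(tibble::tibble(
    node = c("A", "B"), parent = c("B", "A"),
    marker = "CD24", side = "+", threshold = 1
  )), "cycle|root|parent")
  ev$CD24[1] <- NA
  expect_error(apply_gating_tree(ev, default_ssc_gate_tree()), "non-finite")
})

test_that("gate trees round-trip through JSON", {
  tree <- default_ssc_gate_tree()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_gate_tree(tree, tmp)
  back <- read_gate_tree(tmp)
  expect_equal(back$gates, tree$gates)
  expect_equal(back$root, tree$root)
})
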