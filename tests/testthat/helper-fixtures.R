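# shared fixtures, all generated in code

# scaled-down simulator settings for fast unit tests
small_sim_config <- function(seed = 1L, ...) {
  args <- list(
    n_founders = 8L, M = 60L, mu = 0.2, divisions_per_edge = 8L,
    n_seeds_per_edge = 15L, founder_variant_count = 30L,
    n_cells_per_pop = 80L, depth_mean = 1000, seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# build an allele-count table from per-population af/depth specs;
# af_fwd/af_rev default to the combined af on both strands
toy_counts <- function(spec) {
  # spec: data.frame(population, position, ref, alt, af_fwd, af_rev, depth)
  validate_basecounts(purrr::map_dfr(seq_len(nrow(spec)), function(i) {
    r <- spec[i, ]
    d <- r$depth / 2
    tibble::tibble(
      population = r$population, position = r$position,
      ref = r$ref, alt = r$alt, strand = c("+", "-"),
      count = as.integer(round(c(r$af_fwd, r$af_rev) * d)),
      depth = as.integer(c(d, d))
    )
  }))
}

# match annotated cells back to simulator truth by nearest centroid;
# returns truth-row -> (distance, called type)
match_cells <- function(truth, cells) {
  n <- nrow(truth)
  if (!nrow(cells)) {
    return(tibble::tibble(err = rep(Inf, n), called = NA_character_))
  }
  D <- as.matrix(dist(rbind(cbind(truth$x, truth$y), cbind(cells$x, cells$y))))
  D <- D[seq_len(n), n + seq_len(nrow(cells)), drop = FALSE]
  j <- apply(D, 1, which.min)
  called <- if ("type" %in% names(cells)) cells$type[j] else NA_character_
  tibble::tibble(err = D[cbind(seq_len(n), j)], called = called)
}

# brute-force nearest-neighbour composition, written independently of the
# package implementation: explicit loops, explicit tie-break on cell id
brute_force_nn <- function(cc, focal_type, types) {
  cc <- cc[order(cc$cell), ]
  counts <- setNames(rep(0L, length(types)), types)
  n_focal <- 0L
  for (i in seq_len(nrow(cc))) {
    if (cc$type[i] != focal_type) next
    n_focal <- n_focal + 1L
    best <- Inf; best_j <- NA_integer_
    for (j in seq_len(nrow(cc))) {
      if (j == i) next
      d <- sqrt((cc$x[i] - cc$x[j])^2 + (cc$y[i] - cc$y[j])^2)
      if (d < best || (d == best && cc$cell[j] < cc$cell[best_j])) {
        best <- d; best_j <- j
      }
    }
    tp <- cc$type[best_j]
    counts[tp] <- counts[tp] + 1L
  }
  list(counts = counts, n_focal = n_focal)
}

# random cell table for neighbour tests
random_roi <- function(n, seed, types = paste0("P", 1:4), size = 256) {
  withr::with_seed(seed, tibble::tibble(
    cell = seq_len(n), roi = "r",
    x = runif(n, 0, size), y = runif(n, 0, size),
    type = sample(types, n, replace = TRUE)
  ))
}

# Hand-built toy in which each variant trips exactly one rule:
#   100G>T  depth 50 everywhere            -> insufficient depth (rule i)
#   200G>T  af 0.99 in every population    -> homoplasmic/germline (rule ii)
#   300G>T  one strand 5x the other        -> strand imbalance (rule iii)
#   400G>T  strands anti-correlated        -> strand discordance (rule iv)
#   500G>T  clean 20% variant in A and B   -> survivor
filter_toy_counts <- function() {
  pops <- c("A", "B", "C", "D")
  spec <- rbind(
    data.frame(population = pops, position = 100L, ref = "G", alt = "T",
               af_fwd = 0.3, af_rev = 0.3, depth = 50),
    data.frame(population = pops, position = 200L, ref = "G", alt = "T",
               af_fwd = 0.99, af_rev = 0.99, depth = 200),
    data.frame(population = pops, position = 300L, ref = "G", alt = "T",
               af_fwd = c(0.40, 0, 0, 0), af_rev = c(0.08, 0, 0, 0),
               depth = 200),
    data.frame(population = pops, position = 400L, ref = "G", alt = "T",
               af_fwd = c(0.10, 0.20, 0.10, 0.20),
               af_rev = c(0.20, 0.10, 0.20, 0.10), depth = 200),
    data.frame(population = pops, position = 500L, ref = "G", alt = "T",
               af_fwd = c(0.2, 0.2, 0, 0), af_rev = c(0.2, 0.2, 0, 0),
               depth = 200)
  )
  toy_counts(spec)
}

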