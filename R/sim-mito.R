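#' Neutral heteroplasmy drift of a single variant
#'
#' The drift kernel of the simulator, exposed on its own because its
#' moments are known in closed form. Each cell division resamples the
#' mtDNA pool: `h' = Binomial(M, h) / M` (Wright-Fisher on copies), so the
#' heteroplasmy after `t` divisions is a martingale with
#' `Var(h_t) = h0 (1 - h0) (1 - (1 - 1/M)^t)`.
#'
#' @param h0 Starting heteroplasmy, a single value or one per lineage.
#' @param M mtDNA copies per cell.
#' @param divisions Number of divisions to simulate.
#' @param n_lineages Number of independent lineages (recycled over `h0`).
#' @param seed Optional integer seed; if `NULL` the caller's RNG stream is
#'   used.
#' @return Numeric vector of length `n_lineages` with final heteroplasmies.
#' @examples
#' h <- drift_heteroplasmy(0.2, M = 100, divisions = 10,
#'                         n_lineages = 1000, seed = 7)
#' mean(h) # close to 0.2: drift is a martingale
#' @export
drift_heteroplasmy <- function(h0, M, divisions, n_lineages, seed = NULL) {
  assert_scalar_number(M, "M", lower = 2)
  run <- function() {
    h <- rep_len(as.numeric(h0), n_lineages)
    for (d in seq_len(divisions)) {
      h <- rbinom(n_lineages, M, h) / M
    }
    h
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# one division applied to a cells x variants heteroplasmy matrix;
# only nonzero entries are resampled (a zero stays zero under binomial drift)
drift_step_matrix <- function(H, M) {
  nz <- which(H > 0)
  if (length(nz)) H[nz] <- rbinom(length(nz), M, H[nz]) / M
  H
}

#' Simulate mtDNA clonal drift along a differentiation tree
#'
#' Emulates lineage tracking in a mitochondrial-mutator mouse: founder stem
#' cells carry clonal variants (Beta-distributed heteroplasmy); their
#' descendants populate every node of the differentiation tree, with
#' `divisions_per_edge` cell divisions per edge during which heteroplasmy
#' drifts by per-division binomial resampling of the `M` mtDNA copies and
#' new somatic mutations arise at `Poisson(mu)` per cell per division,
#' entering at heteroplasmy `1/M` at unused genome positions. Each
#' population's sorted pool is then contaminated at rate
#' `1 - sort_purity` with cells from the other populations, and bulk
#' mitochondrial capture sequencing is emulated: per-position depth is
#' `Poisson(depth_mean)`, split over strands as `Binomial(depth, 1/2)`,
#' with a symmetric per-base error `seq_error`.
#'
#' @param config A [sim_config()].
#' @return A list of class `clonal_sim` with elements
#'   \describe{
#'     \item{counts}{long-format allele-count tibble (class
#'       `basecount_tbl`) with columns `population`, `position`, `ref`,
#'       `alt`, `strand`, `count` (alt reads) and `depth` (total strand
#'       reads), one row per population x variant x strand;}
#'     \item{truth}{a list with `variants` (tibble: `variant`, `position`,
#'       `ref`, `alt`, `origin` tree node) and `true_af` (tibble:
#'       `population`, `variant`, `true_af`), the pooled pre-sequencing
#'       heteroplasmy of each sorted (contaminated) cell pool;}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' sim <- simulate_clonal_hierarchy(sim_config(n_cells_per_pop = 50, seed = 3))
#' head(sim$counts)
#' @export
simulate_clonal_hierarchy <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed(config$seed, simulate_clonal_hierarchy_impl(config))
}

simulate_clonal_hierarchy_impl <- function(cfg) {
  tree <- cfg$tree
  pops <- hierarchy_nodes(tree)
  n_pop <- length(pops)
  ncell <- cfg$n_cells_per_pop
  M <- cfg$M

  # ---- variant registry (grows as somatic mutations arise) ----------------
  # variants are abstract ids during the simulation; genome positions are
  # assigned only to the variants that survive to be observed, so the
  # unique-position constraint never caps the mutation supply
  reg <- new.env(parent = emptyenv())
  reg$origin <- character(0)

  new_variants <- function(n, origin) {
    if (n == 0L) return(integer(0))
    ids <- length(reg$origin) + seq_len(n)
    reg$origin <- c(reg$origin, rep(origin, n))
    ids
  }

  # ---- founder pool -------------------------------------------------------
  fv <- new_variants(cfg$founder_variant_count, hierarchy_root(tree))
  founders <- matrix(0, cfg$n_founders, length(fv),
                     dimnames = list(NULL, as.character(fv)))
  if (length(fv)) {
    owner <- rep_len(seq_len(cfg$n_founders), length(fv))
    h0 <- rbeta(length(fv), cfg$founder_af_beta[1], cfg$founder_af_beta[2])
    founders[cbind(owner, seq_along(fv))] <- h0
  }

  # derive a pool of `ncell` cells from a parent pool through an explicit
  # Wright-Fisher pedigree: a bottleneck of `n_seeds_per_edge` progenitors
  # is drawn from the parent, the compartment doubles each division until
  # it reaches `ncell` and is then maintained at that size by resampling.
  # Every daughter cell binomially resamples its mother's mtDNA pool and
  # may acquire Poisson(mu) new mutations; because daughters share
  # pedigree ancestors, a mutation can expand clonally within the pool
  # and be transmitted to downstream compartments.
  derive_pool <- function(parent, node) {
    H <- parent[sample.int(nrow(parent), cfg$n_seeds_per_edge,
                           replace = TRUE), , drop = FALSE]
    for (d in seq_len(cfg$divisions_per_edge)) {
      n_next <- min(2L * nrow(H), ncell)
      H <- H[sample.int(nrow(H), n_next, replace = TRUE), , drop = FALSE]
      H <- drift_step_matrix(H, M)
      n_new <- rpois(1L, cfg$mu * n_next)
      if (n_new > 0L) {
        ids <- new_variants(n_new, node)
        cells <- sample.int(n_next, n_new, replace = TRUE)
        add <- matrix(0, n_next, n_new,
                      dimnames = list(NULL, as.character(ids)))
        add[cbind(cells, seq_len(n_new))] <- 1 / M
        H <- cbind(H, add)
      }
      H <- H[, colSums(H) > 0, drop = FALSE]  # extinct variants carry no signal
    }
    if (nrow(H) < ncell) {
      H <- H[sample.int(nrow(H), ncell, replace = TRUE), , drop = FALSE]
    }
    H
  }

  pools <- vector("list", n_pop)
  names(pools) <- pops
  pools[[hierarchy_root(tree)]] <- derive_pool(founders, hierarchy_root(tree))
  # breadth-first order guarantees parents are built first
  ord <- pops[order(node_depths(tree))]
  for (nd in ord[-1]) {
    pools[[nd]] <- derive_pool(pools[[tree$parent[[nd]]]], nd)
  }

  # ---- FACS impurity: swap cells in from other populations ----------------
  n_var <- length(reg$origin)
  true_af <- matrix(0, n_pop, n_var, dimnames = list(pops, NULL))
  swap_sets <- lapply(pops, function(p) which(runif(ncell) > cfg$sort_purity))
  names(swap_sets) <- pops
  for (p in pops) {
    swaps <- swap_sets[[p]]
    own <- pools[[p]]
    keep <- setdiff(seq_len(ncell), swaps)
    acc <- numeric(n_var)
    if (length(keep)) {
      s <- colSums(own[keep, , drop = FALSE])
      acc[as.integer(colnames(own))] <- s
    }
    if (length(swaps) && n_pop > 1L) {
      donor_pop <- sample(setdiff(pops, p), length(swaps), replace = TRUE)
      donor_row <- sample.int(ncell, length(swaps), replace = TRUE)
      for (k in seq_along(swaps)) {
        dp <- pools[[donor_pop[k]]]
        ids <- as.integer(colnames(dp))
        acc[ids] <- acc[ids] + dp[donor_row[k], ]
      }
    }
    true_af[p, ] <- acc / ncell
  }

  # ---- keep variants that survive anywhere; place them on the genome ------
  alive <- which(colSums(true_af) > 0)
  if (length(alive) > cfg$genome_length) {
    abort("genome exhausted: more surviving variants than positions")
  }
  pos <- sort(sample.int(cfg$genome_length, length(alive)))
  ref <- sample(DNA_BASES, length(alive), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                character(1))
  variants <- tibble::tibble(
    variant = variant_key(pos, ref, alt),
    position = pos,
    ref = ref,
    alt = alt,
    origin = reg$origin[alive]
  )
  true_af <- true_af[, alive, drop = FALSE]
  colnames(true_af) <- variants$variant

  # ---- bulk capture sequencing -------------------------------------------
  nv <- nrow(variants)
  counts <- NULL
  if (nv > 0L) {
    af <- as.vector(t(true_af))                       # pop-major, variant fast
    pop_col <- rep(pops, each = nv)
    depth_tot <- rpois(n_pop * nv, cfg$depth_mean)
    d_fwd <- rbinom(n_pop * nv, depth_tot, 0.5)
    d_rev <- depth_tot - d_fwd
    e <- cfg$seq_error
    p_alt <- af * (1 - e) + (1 - af) * e / 3
    counts <- tibble::tibble(
      population = rep(pop_col, 2L),
      position = rep(rep(variants$position, n_pop), 2L),
      ref = rep(rep(variants$ref, n_pop), 2L),
      alt = rep(rep(variants$alt, n_pop), 2L),
      strand = rep(c("+", "-"), each = n_pop * nv),
      count = c(rbinom(n_pop * nv, d_fwd, p_alt),
                rbinom(n_pop * nv, d_rev, p_alt)),
      depth = c(d_fwd, d_rev)
    )
    counts <- dplyr::arrange(counts, .data$population, .data$position,
                             .data$strand)
  } else {
    counts <- tibble::tibble(
      population = character(), position = integer(), ref = character(),
      alt = character(), strand = character(), count = integer(),
      depth = integer()
    )
  }
  class(counts) <- c("basecount_tbl", class(counts))

  truth <- list(
    variants = variants,
    true_af = if (nrow(variants)) {
      tibble::as_tibble(true_af, rownames = "population") %>%
        tidyr::pivot_longer(-"population", names_to = "variant",
                            values_to = "true_af")
    } else {
      tibble::tibble(population = character(), variant = character(),
                     true_af = numeric())
    }
  )
  structure(list(counts = counts, truth = truth, config = cfg),
            class = "clonal_sim")
}

#' @export
print.clonal_sim <- function(x, ...) {
  cat("<clonal_sim> ", nrow(x$truth$variants), " variants across ",
      length(hierarchy_nodes(x$config$tree)), " populations (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}
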