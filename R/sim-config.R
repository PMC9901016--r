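#' Configuration for the clonal mtDNA drift simulator
#'
#' Bundles and validates all parameters of the mutator-mouse simulation:
#' a rooted differentiation tree over sorted population labels, the number
#' of founder stem cells, the per-cell mtDNA copy number governing drift,
#' the somatic mutation rate, and the bulk capture-sequencing model.
#'
#' @param tree `ssc_hierarchy` over population labels; every node is a
#'   sorted population. Default: the eight-population SSC model.
#' @param n_founders Number of founder stem cells whose descendants populate
#'   the tree. Few founders means strong clonal structure.
#' @param M mtDNA copies per cell (integer >= 2; realistic values are in the
#'   hundreds). Heteroplasmy is resampled each division as
#'   `Binomial(M, h)/M`, so smaller `M` drifts faster.
#' @param mu Expected new somatic mutations per cell per division
#'   (Poisson), each placed at an unused genome position with initial
#'   heteroplasmy `1/M`.
#' @param genome_length mtDNA genome length in bp (mouse: 16299).
#' @param divisions_per_edge Cell divisions along each tree edge (and from
#'   the founders into the root population pool).
#' @param n_seeds_per_edge Progenitor bottleneck: the number of cells drawn
#'   (with replacement) from the parent pool to seed each daughter
#'   population. A narrow bottleneck makes clone frequencies drift and
#'   segregate down the tree, which is what renders shared variants
#'   informative about the hierarchy.
#' @param founder_variant_count Total clonal variants pre-existing in the
#'   founder pool, assigned round-robin to founders; these are the
#'   high-heteroplasmy clone barcodes.
#' @param founder_af_beta Length-2 `c(shape1, shape2)` of the Beta
#'   distribution for founder-variant initial heteroplasmy.
#' @param n_cells_per_pop Cells sorted (and pooled) per population.
#' @param sort_purity Probability a sorted cell truly belongs to its gate;
#'   with probability `1 - sort_purity` it is replaced by a uniform draw
#'   from the other populations (FACS impurity).
#' @param depth_mean Mean capture-sequencing depth per position (Poisson).
#' @param seq_error Per-base sequencing error rate, symmetric over the three
#'   alternative bases.
#' @param seed Integer RNG seed; the simulation is a pure function of the
#'   config including this seed.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_clonal_hierarchy()]
#' @export
sim_config <- function(tree = default_ssc_hierarchy(),
                       n_founders = 24L,
                       M = 80L,
                       mu = 0.5,
                       genome_length = 16299L,
                       divisions_per_edge = 15L,
                       n_seeds_per_edge = 50L,
                       founder_variant_count = 100L,
                       founder_af_beta = c(2, 2),
                       n_cells_per_pop = 300L,
                       sort_purity = 0.98,
                       depth_mean = 2000,
                       seq_error = 5e-4,
                       seed = 1L) {
  if (!inherits(tree, "ssc_hierarchy")) {
    abort("`tree` must be an `ssc_hierarchy` (see `hierarchy()`)")
  }
  assert_scalar_number(M, "M", lower = 2)
  assert_scalar_number(n_founders, "n_founders", lower = 1)
  assert_scalar_number(mu, "mu", lower = 0)
  assert_scalar_number(genome_length, "genome_length", lower = 1)
  assert_scalar_number(divisions_per_edge, "divisions_per_edge", lower = 0)
  assert_scalar_number(n_seeds_per_edge, "n_seeds_per_edge", lower = 1)
  assert_scalar_number(founder_variant_count, "founder_variant_count", lower = 0)
  if (length(founder_af_beta) != 2L || any(founder_af_beta <= 0)) {
    abort("`founder_af_beta` must be two positive Beta shape parameters")
  }
  assert_scalar_number(n_cells_per_pop, "n_cells_per_pop", lower = 1)
  if (!is.numeric(sort_purity) || length(sort_purity) != 1L ||
      sort_purity <= 0 || sort_purity > 1) {
    abort("`sort_purity` must be in (0, 1]")
  }
  assert_scalar_number(depth_mean, "depth_mean", lower = 0)
  assert_scalar_number(seq_error, "seq_error", lower = 0, upper = 1)
  if (founder_variant_count + 1 > genome_length) {
    abort("`genome_length` too small for the requested founder variants")
  }
  structure(list(
    tree = tree,
    n_founders = as.integer(n_founders),
    M = as.integer(M),
    mu = mu,
    genome_length = as.integer(genome_length),
    divisions_per_edge = as.integer(divisions_per_edge),
    n_seeds_per_edge = as.integer(n_seeds_per_edge),
    founder_variant_count = as.integer(founder_variant_count),
    founder_af_beta = as.numeric(founder_af_beta),
    n_cells_per_pop = as.integer(n_cells_per_pop),
    sort_purity = sort_purity,
    depth_mean = depth_mean,
    seq_error = seq_error,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Read a simulator configuration from YAML
#'
#' The YAML file may contain any subset of the [sim_config()] arguments;
#' the tree may be given as a newick string under the key `tree`.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$tree) && is.character(y$tree)) {
    y$tree <- read_hierarchy(text = y$tree)
  }
  do.call(sim_config, y)
}
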