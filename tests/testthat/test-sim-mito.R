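test_that("no mutation sources means no alternate alleles anywhere", {
  cfg <- small_sim_config(mu = 0, founder_variant_count = 0, seq_error = 0)
  sim <- simulate_clonal_hierarchy(cfg)
  expect_equal(nrow(sim$counts), 0L)
  expect_equal(nrow(sim$truth$variants), 0L)
})

test_that("the default design covers exactly the eight sorted populations", {
  sim <- simulate_clonal_hierarchy(small_sim_config(seed = 3))
  expect_setequal(unique(sim$counts$population),
                  c("CD24+CD29+", "CD24+", "CD29+", "CD24-CD29-",
                    "CD105+", "THY+", "6C3+", "THY+6C3+"))
})

test_that("emitted counts are a valid allele-count table", {
  sim <- simulate_clonal_hierarchy(small_sim_config(seed = 5))
  expect_s3_class(sim$counts, "basecount_tbl")
  expect_true(all(sim$counts$count <= sim$counts$depth))
  expect_true(all(sim$counts$strand %in% c("+", "-")))
  expect_true(all(sim$counts$position >= 1 &
                    sim$counts$position <= 16299))
  # every emitted variant has a recorded origin node
  keys <- unique(paste0(sim$counts$position, sim$counts$ref, sim$counts$alt))
  expect_equal(length(keys), nrow(sim$truth$variants))
  expect_true(all(sim$truth$variants$origin %in%
                    hierarchy_nodes(sim$config$tree)))
})

test_that("with perfect sorting and no errors, bulk AF is binomial around truth", {
  cfg <- small_sim_config(seed = 7, sort_purity = 1, seq_error = 0,
                          depth_mean = 1500)
  sim <- simulate_clonal_hierarchy(cfg)
  m <- compute_heteroplasmy(sim$counts)
  truth <- sim$truth$true_af
  df <- dplyr::inner_join(as.data.frame(m)[c("population", "variant", "af", "depth")],
                          truth, by = c("population", "variant"))
  df <- df[df$depth >= 200, ]
  alt <- round(df$af * df$depth)
  ci_lo <- qbeta(0.005, alt, df$depth - alt + 1)
  ci_hi <- qbeta(0.995, alt + 1, df$depth - alt)
  covered <- df$true_af >= ci_lo & df$true_af <= ci_hi
  expect_gte(mean(covered), 0.99)
})

test_that("the same seed reproduces the simulation exactly", {
  a <- simulate_clonal_hierarchy(small_sim_config(seed = 11))
  b <- simulate_clonal_hierarchy(small_sim_config(seed = 11))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_clonal_hierarchy(small_sim_config(seed = 12))
  expect_false(identical(a$counts, c$counts))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(M = 1), "M")
  expect_error(sim_config(sort_purity = 0), "sort_purity")
  expect_error(sim_config(sort_purity = 1.5), "sort_purity")
  expect_error(sim_config(mu = -1), "mu")
  expect_error(sim_config(tree = "not a tree"), "ssc_hierarchy")
})

test_that("a sim config round-trips through YAML", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(M = 70, mu = 0.3, n_founders = 10,
                        tree = write_hierarchy(default_ssc_hierarchy()),
                        seed = 4),
                   tmp)
  cfg <- read_sim_config(tmp)
  expect_equal(cfg$M, 70L)
  expect_equal(cfg$mu, 0.3)
  expect_equal(hierarchy_root(cfg$tree), "CD24+CD29+")
})
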