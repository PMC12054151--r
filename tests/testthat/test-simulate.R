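test_that("depth profile simulator honors zero-mean and dropout contracts", {
  p0 <- simulate_depth_profile(100, mean_depth = 0, dropout = 0, seed = 1)
  expect_equal(p0$depths, rep(0, 100))

  pd <- simulate_depth_profile(1000, mean_depth = 10, dropout = 0.6, seed = 2)
  expect_lte(breadth_of_coverage(pd), 0.4)
  expect_true(all(pd$depths >= 0))
  expect_true(all(pd$depths == floor(pd$depths)))

  expect_error(simulate_depth_profile(0, 10), ">= 1")
  expect_error(simulate_depth_profile(10, -1), ">= 0")
  expect_error(simulate_depth_profile(10, 1, dropout = 1.5), "\\[0, 1\\]")
  expect_error(
    simulate_depth_profile(10, 1, outlier_fraction = 0.5), "\\[0, 0.25\\]"
  )
})

test_that("simulated Poisson depths hit the requested mean", {
  p <- simulate_depth_profile(
    10000, mean_depth = 10, dropout = 0, outlier_fraction = 0,
    overdispersion = 0, seed = 1
  )
  se <- sqrt(10 / 10000)
  expect_lt(abs(mean(p$depths) - 10), 3 * se)
})

test_that("fixed seed gives bit-identical profiles; seeds differ", {
  a <- simulate_depth_profile(500, 5, dropout = 0.2, outlier_fraction = 0.1,
                              outlier_multiplier = 5, overdispersion = 1,
                              seed = 9)
  b <- simulate_depth_profile(500, 5, dropout = 0.2, outlier_fraction = 0.1,
                              outlier_multiplier = 5, overdispersion = 1,
                              seed = 9)
  expect_identical(a$depths, b$depths)
  c_ <- simulate_depth_profile(500, 5, dropout = 0.2, outlier_fraction = 0.1,
                               outlier_multiplier = 5, overdispersion = 1,
                               seed = 10)
  expect_false(identical(a$depths, c_$depths))
})

test_that("realized breadth tracks 1 - dropout at high depth", {
  p <- simulate_depth_profile(100000, mean_depth = 50, dropout = 0.3, seed = 4)
  expect_lt(abs(breadth_of_coverage(p) - 0.7), 0.01)
})

test_that("raising mean_depth never lowers any position's depth", {
  for (seed in c(1, 8, 33)) {
    lo <- simulate_depth_profile(2000, 4, dropout = 0.2,
                                 outlier_fraction = 0.1,
                                 outlier_multiplier = 3,
                                 overdispersion = 0.5, seed = seed)
    hi <- simulate_depth_profile(2000, 9, dropout = 0.2,
                                 outlier_fraction = 0.1,
                                 outlier_multiplier = 3,
                                 overdispersion = 0.5, seed = seed)
    expect_true(all(hi$depths >= lo$depths))
    expect_gte(q2q3_mean_depth(hi), q2q3_mean_depth(lo))
  }
})

test_that("community simulation returns consistent tables and truth", {
  cfg <- strong_community_config(
    c(c1 = "TD"), seed = 55, samples_per_site = 3, genome_length = 300,
    off_depth = 0
  )
  sim <- simulate_community(cfg)
  expect_equal(nrow(sim$summary), 3 * 8) # one row per (genome, sample)
  expect_equal(nrow(sim$site_map), 24)
  expect_equal(sim$truth$preferred_sites, "TD")

  # flat preferences mean no preferred sites in the truth table
  flat <- simulation_config(
    sites = c("TD", "BM"), samples_per_site = 2,
    genomes = data.frame(genome_id = "g1", clade_id = "c1", length = 100),
    preference = matrix(5, 1, 2, dimnames = list("c1", c("TD", "BM"))),
    seed = 3
  )
  expect_equal(simulate_community(flat)$truth$preferred_sites, "")

  expect_error(
    simulation_config(
      sites = character(0), samples_per_site = 2,
      genomes = data.frame(genome_id = "g1", clade_id = "c1", length = 100),
      preference = matrix(5, 1, 1, dimnames = list("c1", "TD"))
    ),
    "at least one site"
  )
})

test_that("adding a sample does not perturb existing profiles", {
  cfg3 <- strong_community_config(
    c(c1 = "TD"), seed = 77, samples_per_site = 3, genome_length = 200
  )
  cfg4 <- strong_community_config(
    c(c1 = "TD"), seed = 77, samples_per_site = 4, genome_length = 200
  )
  sim3 <- simulate_community(cfg3)
  sim4 <- simulate_community(cfg4)
  key <- function(p) paste(p$genome_id, p$sample_id)
  p3 <- setNames(sim3$profiles, vapply(sim3$profiles, key, character(1)))
  p4 <- setNames(sim4$profiles, vapply(sim4$profiles, key, character(1)))
  for (k in names(p3)) {
    expect_identical(p3[[k]]$depths, p4[[k]]$depths)
  }
})

test_that("function table simulator plants presence patterns as configured", {
  groups <- data.frame(
    genome_id = paste0("g", 1:10), group = rep(c("in", "out"), each = 5)
  )
  planted <- data.frame(
    function_id = "F1", group = "in",
    presence_prob_in = 1, presence_prob_out = 0
  )
  fn <- simulate_function_table(groups, planted, seed = 5)
  present <- fn$genome_id[fn$count == 1]
  expect_setequal(present, paste0("g", 1:5))

  # no background: exactly the enriched functions appear
  expect_setequal(unique(fn$accession), "F1")
  expect_equal(nrow(fn), 10)

  expect_error(
    simulate_function_table(
      groups,
      data.frame(function_id = "F2", group = "nope",
                 presence_prob_in = 1, presence_prob_out = 0)
    ),
    "not present among genomes"
  )
})

test_that("null function tables produce calibrated p-values", {
  groups <- data.frame(
    genome_id = paste0("g", 1:20), group = rep(c("A", "B"), each = 10)
  )
  fn <- simulate_function_table(
    groups, background_functions = 1000, background_prob = 0.5, seed = 3
  )
  res <- enrich_by_habitat(fn, groups)
  expect_equal(nrow(res), 1000)
  expect_equal(sum(res$significant), 0)
})
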