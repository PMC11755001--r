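small_design <- function(...) {
  args <- list(...)
  defaults <- list(n_species = 20L, stems_per_species = 30L,
                   seedlings_per_species = 20L, plot_dims = c(50, 50),
                   n_seedling_plots = 100L, n_traps = 50L)
  defaults[names(args)] <- args
  do.call(simulation_design, defaults)
}

test_that("species parameters are seeded, centered, and axis-structured", {
  d <- small_design()
  t1 <- draw_species_parameters(d, seed = 5)
  t2 <- draw_species_parameters(d, seed = 5)
  t3 <- draw_species_parameters(d, seed = 6)
  expect_identical(t1, t2)
  expect_false(identical(t1$species$axis1, t3$species$axis1))
  # noise-free limit with axis 1 alone driving the rates: the
  # growth-minus-survival contrast is a monotone image of axis 1
  L <- simulation_design()$axis_loadings
  L[2, ] <- 1e-8 * sign(L[2, ])
  d0 <- small_design(n_species = 60L, rate_noise_sd = 0, trait_noise_sd = 0,
                     axis_loadings = L)
  t0 <- draw_species_parameters(d0, seed = 2)
  contrast <- modulus_transform(t0$growth[, "overstory"]) -
    lifespan_transform(t0$survival[, "overstory"])
  expect_equal(cor(contrast, t0$species$axis1, method = "spearman"), 1)
  # Monte-Carlo check: sample mean of the axes within 3 SE of zero
  big <- draw_species_parameters(small_design(n_species = 500L), seed = 3)
  expect_lt(abs(mean(big$species$axis1)), 3 / sqrt(500))
  expect_lt(abs(mean(big$species$axis2)), 3 / sqrt(500))
})

test_that("design validation enforces the planted trade-off sign structure", {
  expect_error(simulation_design(n_species = 0L), "at least one species")
  bad <- matrix(0.5, 2, 9)  # growth and survival same sign on axis 1
  expect_error(small_design(axis_loadings = bad), "oppose")
})

test_that("tree simulator honours degenerate rate limits", {
  d <- small_design(n_censuses = 3L)
  truth <- draw_species_parameters(d, seed = 1)
  truth$survival[, ] <- 1 - 1e-15
  trees <- simulate_tree_census(truth, seed = 2)
  expect_false(any(trees$status == "dead"))
  # zero growth, zero noise: dbh constant up to the 0.1 mm truncation floor
  truth2 <- draw_species_parameters(
    small_design(growth_sd_tree = 1e-12), seed = 1)
  truth2$growth[, ] <- 0
  truth2$survival[, ] <- 1 - 1e-15
  trees2 <- simulate_tree_census(truth2, seed = 3)
  rng <- tapply(trees2$dbh, trees2$tree_id, function(v) diff(range(v)))
  expect_lt(max(rng), 0.21)   # two intervals x 0.1 mm floor
})

test_that("survivor fraction matches the closed form s^t", {
  d <- simulation_design(n_species = 1L, stems_per_species = 1000L,
                         n_censuses = 2L, interval_years = 5,
                         plot_dims = c(100, 100), seedlings_per_species = 0L)
  truth <- draw_species_parameters(d, seed = 4)
  truth$survival[, ] <- 0.9
  trees <- simulate_tree_census(truth, seed = 5)
  surv <- sum(trees$census_index == 2 & trees$status == "alive") / 1000
  p <- 0.9^5
  ci <- qnorm(c(0.005, 0.995), p, sqrt(p * (1 - p) / 1000))
  expect_gt(surv, ci[1]); expect_lt(surv, ci[2])
})

test_that("seed and recruit streams follow their distributions", {
  d <- small_design(n_species = 5L, n_traps = 100L, trap_area = 0.5,
                    n_censuses = 2L, interval_years = 1)
  truth <- draw_species_parameters(d, seed = 6)
  truth$species$seed_rain <- rep(10 / 0.5 * 1e4, 5)  # 10 seeds/trap/yr
  # transition = 1: recruits per ha equal seeds per ha in expectation
  truth$species$transition <- rep(1, 5)
  sim <- simulate_seedlings_and_seeds(truth, seed = 7)
  total <- sum(sim$seed_traps$count)
  lam <- 10 * 100 * 5  # rate x traps x species
  expect_gt(total, qpois(0.005, lam)); expect_lt(total, qpois(0.995, lam))
  recruits <- sim$seedlings[grepl("^r", sim$seedlings$seedling_id), ]
  first <- recruits[!duplicated(recruits$seedling_id), ]
  rec_per_ha <- nrow(first) / (d$n_seedling_plots * d$seedling_plot_area / 1e4)
  seeds_per_ha <- truth$species$seed_rain[1] * 5
  expect_lt(abs(rec_per_ha - seeds_per_ha) / seeds_per_ha, 0.15)
  # transition = 0: no recruits ever
  truth$species$transition <- rep(0, 5)
  sim0 <- simulate_seedlings_and_seeds(truth, seed = 8)
  expect_false(any(grepl("^r", sim0$seedlings$seedling_id)))
})

test_that("generated tables pass every data_io validator", {
  community <- simulate_community(small_design(), seed = 11)
  expect_equal(nrow(validate_stem_table(community$trees, c(50, 50))$rejected), 0L)
  expect_equal(nrow(validate_seedling_table(community$seedlings)$rejected), 0L)
  expect_equal(nrow(validate_seed_trap_table(community$seed_traps)$rejected), 0L)
  expect_equal(nrow(validate_allometry_table(community$allometry)$rejected), 0L)
  expect_equal(nrow(validate_trait_table(community$traits)$rejected), 0L)
})

test_that("the true rate matrix is aligned with the planted axes", {
  d <- simulation_design(n_species = 200L)
  truth <- draw_species_parameters(d, seed = 12)
  tm <- true_rates_matrix(truth)
  pc <- pca_axes(scale(tm))
  ax <- cbind(truth$species$axis1, truth$species$axis2)
  cong <- vapply(1:2, function(k) {
    max(congruence(pc$scores[, k], ax[, 1]), congruence(pc$scores[, k], ax[, 2]))
  }, numeric(1))
  expect_true(all(cong >= 0.95))
})
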