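test_that("crown area follows the power allometry exactly", {
  a <- 0.03615016; b <- 1.281928
  expect_equal(crown_area(1, a, b), a, tolerance = 1e-12)       # 1^b = 1
  expect_equal(crown_area(1, 1, 1), 1, tolerance = 1e-15)
  # frozen value from an arbitrary-precision evaluation of a * 100^b
  expect_equal(crown_area(100, a, b), 13.24238541794237, tolerance = 1e-13)
  expect_equal(crown_area(250, a, b), 42.86439153556655, tolerance = 1e-13)
  expect_error(crown_area(-10, a, b), "positive")
  expect_error(crown_area(10, 0, b), "positive")
})

test_that("subplot grid tiles the plot, keeping partial edge tiles", {
  g <- grid_subplots(c(63, 63))
  expect_equal(nrow(g), 4L)
  expect_equal(g$area, rep(31.5^2, 4L))
  # 50 x 50: 31.5/18.5 remainders
  g2 <- grid_subplots(c(50, 50))
  expect_equal(nrow(g2), 4L)
  expect_setequal(round(g2$area, 2), c(992.25, 582.75, 582.75, 342.25))
  expect_equal(sum(g2$area), 2500)
  # half-open convention: a point exactly on an internal boundary belongs to
  # the next tile
  expect_equal(subplot_of(31.5, 0, c(63, 63)), "s001_000")
  expect_equal(subplot_of(31.49, 0, c(63, 63)), "s000_000")
  expect_error(subplot_of(70, 0, c(63, 63)), "outside")
})

test_that("packing rule includes the threshold-crossing stem in the overstory", {
  # crowns 1500, 600, 10 in one 31.5 m subplot (area 992.25, threshold 1984.5):
  # the second stem crosses the threshold and is still overstory
  dbh <- c(1500, 600, 10)   # with a = b = 1, crown area == dbh
  stems <- data.frame(tree_id = c("a", "b", "c"), species = "sp",
                      x = c(1, 2, 3), y = c(1, 2, 3), census_index = 1L,
                      dbh = dbh, status = "alive", stringsAsFactors = FALSE)
  res <- assign_layers(stems, unit_allometry(), c(31.5, 31.5))
  expect_equal(res$layer[match(c("a", "b", "c"), res$tree_id)],
               c("overstory", "overstory", "understory"))
  # stricter reading: the crossing stem is already understory
  res2 <- assign_layers(stems, unit_allometry(), c(31.5, 31.5),
                        include_crossing = FALSE)
  expect_equal(res2$layer[match(c("a", "b", "c"), res2$tree_id)],
               c("overstory", "understory", "understory"))
  # a single stem is always overstory
  one <- assign_layers(stems[1, ], unit_allometry(), c(31.5, 31.5))
  expect_equal(one$layer, "overstory")
})

test_that("equal-dbh ties break by tree id, deterministically", {
  stems <- data.frame(tree_id = c("z9", "a1"), species = "sp",
                      x = c(1, 2), y = c(1, 2), census_index = 1L,
                      dbh = c(3000, 3000), status = "alive",
                      stringsAsFactors = FALSE)
  r1 <- assign_layers(stems, unit_allometry(), c(31.5, 31.5))
  r2 <- assign_layers(stems[2:1, ], unit_allometry(), c(31.5, 31.5))
  expect_identical(r1, r2[match(r1$tree_id, r2$tree_id), ],
                   ignore_attr = TRUE)
  expect_equal(r1$tree_id[r1$layer == "overstory"], "a1")
})

test_that("partition, overshoot and monotonicity invariants hold on random maps", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(5:120, 1)
    stems <- data.frame(
      tree_id = sprintf("t%03d", seq_len(n)), species = "sp",
      x = runif(n, 0, 63), y = runif(n, 0, 63), census_index = 1L,
      dbh = 10 + rexp(n, 1 / 200), status = "alive", stringsAsFactors = FALSE)
    res <- assign_layers(stems, unit_allometry(), c(63, 63), multiplier = 0.05)
    # partition: every alive stem in exactly one layer
    expect_equal(nrow(res), n)
    expect_true(all(res$layer %in% c("overstory", "understory")))
    # overshoot bounded by the smallest overstory crown, per subplot
    for (sp_id in unique(res$subplot_id)) {
      o <- res[res$subplot_id == sp_id & res$layer == "overstory", ]
      threshold <- 0.05 * 31.5^2
      if (nrow(o) > 0) {
        expect_lte(sum(o$crown_area) - threshold, min(o$crown_area) + 1e-9)
      }
    }
    # monotonicity: raising the multiplier never demotes a stem
    res_hi <- assign_layers(stems, unit_allometry(), c(63, 63), multiplier = 0.2)
    promoted <- res$layer == "overstory"
    still <- res_hi$layer[match(res$tree_id[promoted], res_hi$tree_id)]
    expect_true(all(still == "overstory"))
  }
})

test_that("species without coefficients fall back to the default or error", {
  stems <- data.frame(tree_id = "a", species = "mystery", x = 1, y = 1,
                      census_index = 1L, dbh = 50, status = "alive",
                      stringsAsFactors = FALSE)
  no_default <- data.frame(species = "other", a = 1, b = 1,
                           stringsAsFactors = FALSE)
  expect_error(assign_layers(stems, no_default, c(31.5, 31.5)), "mystery")
  ok <- assign_layers(stems, unit_allometry(), c(31.5, 31.5))
  expect_equal(ok$crown_area, 50)
})
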