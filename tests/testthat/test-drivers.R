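# Driver analyses use reduced forest/bootstrap sizes where the check is
# qualitative; the acceptance suite runs the planted-driver recovery at the
# published settings (ntree = 500, nodesize = 1).

planted_cells <- function(seed = 1, bias = 4, nx = 20, ny = 20) {
  g <- small_landscape(seed = seed, nx = nx, ny = ny)
  scn <- placement_scenario("biased", target_variable = "population",
                            bias_strength = bias, point_fraction = 0,
                            total_protected_fraction = 0.12, n_units = 30)
  net <- generate_protected_network(g, scn, seed = seed)
  cells <- g$cells
  gt <- attr(net, "ground_truth")
  cells$protected_km2 <- gt$cell$protected_km2
  cells$period <- 2016
  cells
}

test_that("driver histograms concentrate PEx where placement was planted", {
  cc <- planted_cells(seed = 21, bias = 5)
  hh <- driver_histograms(cc, territory = "T1", period = 2016)
  expect_named(hh, c("tourism", "dist_frontiers", "population", "dist_roads",
                     "cropland_suitability"))
  hp <- hh$population
  expect_equal(which.max(hp$pex_pct), 1L)     # protection sits at low population
  expect_gt(hp$pex_pct[1], 5 * max(hp$pex_pct[6:10], 1e-9))
  # an unplanted uniform network is flat along the same gradient
  cc$protected_km2 <- cc$area_km2 * 0.1
  expect_equal(driver_histograms(cc)$population$pex_pct, rep(10, 10))
  # empty network: all-zero PEx
  cc$protected_km2 <- 0
  expect_true(all(driver_histograms(cc)$dist_roads$pex_pct == 0))
})

test_that("mtry selection returns a candidate, reproducibly, with guardrails", {
  cc <- planted_cells(seed = 22)
  m1 <- select_mtry(cc, candidates = 1:5, ntree = 100, seed = 9)
  m2 <- select_mtry(cc, candidates = 1:5, ntree = 100, seed = 9)
  expect_true(as.integer(m1) %in% 1:5)
  expect_equal(as.integer(m1), as.integer(m2))
  expect_length(attr(m1, "oob_mse"), 5)
  expect_error(select_mtry(cc[1:30, ]), "insufficient cells")
})

test_that("bootstrap importance is reproducible and degenerates sanely", {
  cc <- planted_cells(seed = 23)
  a <- vi_bootstrap(cc, B = 3, ntree = 50, mtry = 2, seed = 4)
  b <- vi_bootstrap(cc, B = 3, ntree = 50, mtry = 2, seed = 4)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_equal(sum(a$vi_mean), 100, tolerance = 1e-9)
  # B = 1: sd reported as 0 and flagged
  one <- vi_bootstrap(cc, B = 1, ntree = 50, mtry = 2, seed = 4)
  expect_true(all(one$vi_sd == 0))
  expect_true(attr(one, "settings")$sd_degenerate)
  # binary response mode runs and is reproducible too
  b1 <- vi_bootstrap(cc, B = 2, ntree = 50, mtry = 2, seed = 4,
                     response = "binary")
  b2 <- vi_bootstrap(cc, B = 2, ntree = 50, mtry = 2, seed = 4,
                     response = "binary")
  expect_equal(as.data.frame(b1), as.data.frame(b2))
  # constant response
  cc0 <- cc; cc0$protected_km2 <- cc0$area_km2 * 0.5
  expect_error(vi_bootstrap(cc0, B = 2, ntree = 50, mtry = 2),
               "no variance to explain")
})

test_that("noise responses leave no driver standing out", {
  # Deep forests carry a small positive permutation-importance offset that is
  # shared by all predictors under the null (y independent of X); the
  # informative check is exchangeability: no variable dominates, relative VI
  # stays near the equal share of 100/5 = 20, and no variable wins the top
  # rank with any consistency.
  cc <- planted_cells(seed = 24)
  set.seed(31)
  cc$protected_km2 <- cc$area_km2 * runif(nrow(cc))  # independent of drivers
  vi <- vi_bootstrap(cc, B = 30, ntree = 100, mtry = 2, seed = 6)
  expect_true(all(abs(vi$vi_mean - 20) < 2.5 * pmax(vi$vi_sd, 1)))
  expect_lt(max(vi$top_rank_share), 0.95)
})

test_that("a planted driver takes the top importance rank", {
  cc <- planted_cells(seed = 25, bias = 4)
  vi <- vi_bootstrap(cc, B = 20, ntree = 200, seed = 7)
  expect_equal(vi$variable[which.max(vi$vi_mean)], "population")
  expect_gte(vi$top_rank_share[vi$variable == "population"], 0.95)
})

test_that("a duplicated driver shares importance above the noise floor", {
  cc <- planted_cells(seed = 26, bias = 4)
  cc$tourism <- cc$population + 1e-9 * seq_len(nrow(cc))  # near-copy
  vi <- vi_bootstrap(cc, B = 10, ntree = 200, mtry = 2, seed = 8)
  pop <- vi$vi_mean[vi$variable == "population"]
  tou <- vi$vi_mean[vi$variable == "tourism"]
  others <- vi$vi_mean[!vi$variable %in% c("population", "tourism")]
  expect_gt(pop, max(others))
  expect_gt(tou, max(others))
})
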