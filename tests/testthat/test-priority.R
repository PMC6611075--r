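mk_hist <- function(pex, v, edges = 0:(length(pex))) {
  n <- length(pex)
  h <- data.frame(territory = "T1", variable = v, period = 2016,
                  bin = seq_len(n), lo = edges[-(n + 1)], hi = edges[-1],
                  area_km2 = 1, protected_km2 = pex / 100, pex_pct = pex,
                  empty = FALSE)
  class(h) <- c("eq_histogram", "data.frame")
  h
}

test_that("Pr is the mean shortfall from complete protection", {
  cells <- data.frame(cell_id = 1:3, a = c(0.5, 1.5, 0.5), b = c(0.5, 1.5, 1.5))
  hh <- list(a = mk_hist(c(100, 100), "a"), b = mk_hist(c(100, 100), "b"))
  expect_equal(cell_priority(cells, hh)$pr, c(0, 0, 0))
  hh0 <- list(a = mk_hist(c(0, 0), "a"), b = mk_hist(c(0, 0), "b"))
  expect_equal(cell_priority(cells, hh0)$pr, c(100, 100, 100))
  # m = 2, bin PEx (20, 60): Pr = ((100-20) + (100-60)) / 2 = 60
  hh2 <- list(a = mk_hist(c(20, 99), "a"), b = mk_hist(c(99, 60), "b"))
  out <- cell_priority(cells, hh2)$pr
  expect_equal(out[3], 60)            # bins (1,2): PEx (20, 60) -> (80+40)/2
  expect_equal(out[1], (80 + 1) / 2)  # bins (1,1): PEx (20, 99)
})

test_that("cells missing some variables are scored on the rest and flagged", {
  cells <- data.frame(cell_id = 1:2, a = c(0.5, 0.5), b = c(NA, 1.5))
  hh <- list(a = mk_hist(c(40, 40), "a"), b = mk_hist(c(80, 80), "b"))
  out <- cell_priority(cells, hh)
  expect_equal(out$pr, c(60, 40))
  expect_true(out$flagged[1]); expect_false(out$flagged[2])
})

test_that("lowering a bin's PEx never decreases its cells' priority", {
  set.seed(7)
  cells <- data.frame(cell_id = 1:100, a = runif(100))
  pex <- runif(10, 0, 100)
  e <- seq(0, 1, 0.1)
  pr1 <- cell_priority(cells, list(a = mk_hist(pex, "a", e)))$pr
  pex2 <- pex; pex2[4] <- pex2[4] / 2
  pr2 <- cell_priority(cells, list(a = mk_hist(pex2, "a", e)))$pr
  expect_true(all(pr2 >= pr1 - 1e-12))
})

test_that("quantile classes are balanced with deterministic tie-breaks", {
  p <- data.frame(cell_id = 1:8, pr = c(5, 3, 8, 1, 9, 2, 7, 4))
  cl <- classify_quantiles(p, 4)
  expect_equal(as.vector(table(cl$class)), rep(2L, 4))
  expect_equal(cl$class[cl$pr == 9], 4L)
  # degenerate all-equal scores stay balanced and are flagged
  pd <- data.frame(cell_id = 1:8, pr = rep(50, 8))
  cld <- classify_quantiles(pd, 4)
  expect_equal(as.vector(table(cld$class)), rep(2L, 4))
  expect_true(attr(cld, "degenerate"))
  expect_error(classify_quantiles(p[1:3, ], 4), "fewer scored cells")
})

test_that("with a single territory national and continental maps coincide", {
  g <- small_landscape(seed = 13, n_territories = 1)
  scn <- placement_scenario("biased", target_variable = "temperature",
                            bias_strength = 2, n_units = 12, point_fraction = 0)
  cells <- build_cell_table(
    g, buffer_points(filter_strict_categories(
      generate_protected_network(g, scn, seed = 2))), periods = 2016)
  nat <- priority_map(cells, "national")
  con <- priority_map(cells, "continental")
  o <- order(nat$cell_id)
  expect_equal(nat$pr[o], con$pr[order(con$cell_id)])
  expect_equal(nat$class[o], con$class[order(con$cell_id)])
})

test_that("conditions rare continentally outrank their national class", {
  # country A: cold, unprotected; country B: warm, partially protected.
  # A's cells are ordinary nationally but top continental priorities.
  set.seed(8)
  nA <- 100; nB <- 900
  mkv <- function(n, mu) {
    out <- data.frame(temperature = rnorm(n, mu, 2),
                      precipitation = runif(n, 0, 100),
                      elevation = runif(n, 0, 2), slope = runif(n, 0, 5),
                      soil_fertility = runif(n, 0, 10))
    out
  }
  # B protects a uniform 20% of every cell so shared-gradient bins carry
  # (nearly) equal PEx and the only systematic contrast is the cold condition
  cc <- rbind(
    cbind(data.frame(cell_id = 1:nA, territory_id = "A", area_km2 = 1,
                     protected_km2 = 0, period = 2016), mkv(nA, 0)),
    cbind(data.frame(cell_id = nA + 1:nB, territory_id = "B", area_km2 = 1,
                     protected_km2 = 0.2, period = 2016), mkv(nB, 20)))
  class(cc) <- c("eq_cells", "data.frame")
  nat <- priority_map(cc, "national", k_classes = 4)
  con <- priority_map(cc, "continental", k_classes = 4)
  a_nat <- mean(nat$class[nat$territory_id == "A"])
  a_con <- mean(con$class[con$territory_id == "A"])
  expect_gt(a_con, a_nat)
  expect_true(all(con$class[con$territory_id == "A"] == 4))
})
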