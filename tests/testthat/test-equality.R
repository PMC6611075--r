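test_that("the rank-form Gini matches its analytic anchor points", {
  expect_equal(gini(rep(5, 10)), 0)
  expect_equal(equality_index(rep(5, 10)), 1)
  # all mass in one of ten bins: G = 0.9 exactly under the rank formula
  expect_equal(gini(c(rep(0, 9), 8)), 0.9)
  expect_equal(equality_index(c(10, rep(0, 9))), 0.1)
  expect_error(gini(rep(0, 10)), "no protection")
  expect_error(gini(5), "at least 2")
  expect_error(gini(c(-1, 2)))
})

test_that("rank-form Gini equals the mean-absolute-difference oracle", {
  set.seed(1)
  for (i in 1:1000) {
    n <- sample(2:25, 1)
    x <- round(runif(n, 0, 100), 2)
    if (sum(x) == 0) x[1] <- 1
    expect_equal(gini(x), gini_mad(x), tolerance = 1e-12)
  }
})

test_that("G' is scale and permutation invariant and bounded in [1/n, 1]", {
  set.seed(2)
  for (i in 1:10000) {
    x <- rexp(10) * rbinom(10, 1, 0.7)
    if (sum(x) == 0) x[sample(10, 1)] <- 1
    g <- equality_index(x)
    expect_gte(g, 0.1 - 1e-12)
    expect_lte(g, 1 + 1e-12)
    if (i <= 100) {
      expect_equal(equality_index(3.7 * x), g, tolerance = 1e-12)
      expect_equal(equality_index(sample(x)), g, tolerance = 1e-12)
    }
  }
})

test_that("Kendall's tau matches a brute-force pair-counting oracle", {
  expect_equal(kendall_tau(1:10, 1:10), 1)
  expect_equal(kendall_tau(1:10, 10:1), -1)
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 3, 2)), 1 / 3, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    x <- sample(1:6, 15, replace = TRUE)  # ties exercised
    y <- sample(1:6, 15, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y), tau_b_brute(x, y), tolerance = 1e-12)
  }
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
})

test_that("consecutive-pair pruning eliminates the earlier variable", {
  set.seed(4)
  n <- 200
  base <- data.frame(v1 = rnorm(n))
  base$v2 <- base$v1                      # tau(v1, v2) = 1
  base$v3 <- rnorm(n)                     # independent of v2
  base$v4 <- rnorm(n)
  base$v5 <- rnorm(n)
  pr <- prune_collinear(base, paste0("v", 1:5))
  expect_equal(pr$retained, c("v2", "v3", "v4", "v5"))
  expect_equal(pr$report$dropped[1], "v1")
  # all |tau| below threshold: everything retained
  ind <- as.data.frame(matrix(rnorm(n * 5), n))
  pr2 <- prune_collinear(ind, names(ind))
  expect_equal(pr2$retained, names(ind))
  # determinism
  expect_identical(pr, prune_collinear(base, paste0("v", 1:5)))
})

test_that("pruning a chain stops once the active pair decorrelates", {
  set.seed(5)
  n <- 400
  d <- data.frame(v2 = rnorm(n))
  d$v1 <- d$v2 + 0.1 * rnorm(n)           # |tau(1,2)| > 0.55 -> drop v1
  d$v3 <- rnorm(n)                        # |tau(2,3)| small
  d$v4 <- rnorm(n); d$v5 <- rnorm(n)
  pr <- prune_collinear(d, paste0("v", 1:5))
  expect_equal(pr$retained, c("v2", "v3", "v4", "v5"))
})

test_that("territory equality averages per-variable G' over retained variables", {
  mk_hist <- function(pex, v) {
    h <- data.frame(territory = "T1", variable = v, period = 2016,
                    bin = 1:10, lo = 0:9, hi = 1:10,
                    area_km2 = 1, protected_km2 = pex / 100,
                    pex_pct = pex, empty = FALSE)
    class(h) <- c("eq_histogram", "data.frame")
    h
  }
  h1 <- mk_hist(rep(10, 10), "a")             # G' = 1
  h2 <- mk_hist(c(10, rep(0, 9)), "b")        # G' = 0.1
  eq <- territory_equality(list(h1, h2))
  expect_equal(attr(eq, "mean_gprime"), 0.55)
  expect_equal(eq$gprime, c(1, 0.1))
  # all-zero variable: undefined, mean over the defined ones, warned
  h3 <- mk_hist(rep(0, 10), "c")
  expect_warning(eq2 <- territory_equality(list(h1, h3)), "all zero")
  expect_equal(attr(eq2, "mean_gprime"), 1)
})

test_that("ecoregion equality refuses single-ecoregion territories", {
  tab <- data.frame(territory = "U", period = 2016, ecoregion_id = "E1",
                    area_km2 = 100, protected_km2 = 10, pex_pct = 10)
  res <- ecoregion_equality(tab)
  expect_true(is.na(res$gprime))
  expect_match(res$reason, "single ecoregion")
  tab2 <- rbind(tab, within(tab, { ecoregion_id <- "E2"; pex_pct <- 30
                                   protected_km2 <- 30 }))
  expect_false(is.na(ecoregion_equality(tab2)$gprime))
})

test_that("trajectories track extent and equality across cumulative periods", {
  set.seed(6)
  n <- 400
  vals <- data.frame(matrix(rnorm(n * 5), n))
  names(vals) <- c("temperature", "precipitation", "elevation", "slope",
                   "soil_fertility")
  mk_period <- function(p, frac) {
    cc <- cbind(toy_cells(vals$temperature), vals[-1])
    cc$period <- p
    cc$protected_km2 <- cc$area_km2 * frac
    cc
  }
  # uniform infill: every cell gains the same fraction each decade
  tab <- rbind(mk_period(1960, 0.02), mk_period(1970, 0.05),
               mk_period(1980, 0.08), mk_period(1990, 0.08))
  tr <- trajectory(tab)
  expect_true(all(diff(tr$extent_pct) >= 0))
  expect_equal(tr$mean_gprime, rep(1, 4))
  # efficiency 0 while growing uniformly, undefined once frozen
  expect_equal(tr$efficiency[2:3], c(0, 0))
  expect_true(is.na(tr$efficiency[4]))
})
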