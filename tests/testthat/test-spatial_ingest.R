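make_records <- function(n_strict = 4, n_other = 6) {
  geoms <- lapply(seq_len(n_strict + n_other), function(i)
    geom_rect(i, 0, i + 0.5, 0.5))
  pa_records(geoms,
             category = c(rep(c("I", "II", "III", "IV"), length.out = n_strict),
                          rep(c("V", "VI", "Not Reported"), length.out = n_other)),
             status_year = 2000)
}

test_that("strict-category filtering keeps exactly the allowed set", {
  rec <- make_records(4, 6)
  kept <- filter_strict_categories(rec)
  expect_equal(n_records(kept), 4L)
  expect_true(all(kept$table$category %in% c("I", "II", "III", "IV")))
  expect_equal(attr(kept, "excluded")$n, 6L)
  # empty input
  empty <- pa_records(list(), category = character())
  expect_equal(n_records(filter_strict_categories(empty)), 0L)
})

test_that("category recoding is applied before filtering", {
  # mirrors national recategorisation of 'Not Reported' units
  rec <- pa_records(lapply(1:3, function(i) geom_rect(i, 0, i + 0.5, 0.5)),
                    category = c("Not Reported", "Not Reported", "V"))
  kept <- filter_strict_categories(rec, recode = c("Not Reported" = "II"))
  expect_equal(n_records(kept), 2L)
  expect_true(all(kept$table$category == "II"))
})

test_that("missing categories are excluded and counted, never dropped silently", {
  rec <- pa_records(lapply(1:3, function(i) geom_rect(i, 0, i + 0.5, 0.5)),
                    category = c("II", NA, ""))
  kept <- filter_strict_categories(rec)
  expect_equal(n_records(kept), 1L)
  expect_equal(attr(kept, "excluded")$n_missing_category, 2L)
})

test_that("point buffering conserves extent and applies the polygon rule", {
  poly <- geom_rect(0, 0, 1, 1)
  recs <- pa_records(
    list(poly,
         list(lon = 0.5, lat = 0.5),    # inside the polygon -> excluded
         list(lon = 5, lat = 5),        # far away -> retained
         list(lon = 5.05, lat = 5)),    # overlaps the previous POINT -> retained
    category = "II", status_year = 2000,
    reported_extent = c(NA, 50, 120, 120))
  out <- buffer_points(recs)
  expect_equal(n_records(out), 3L)
  expect_equal(attr(out, "buffered")$excluded, "PA0002")
  expect_true(all(out$table$geom_type == "polygon"))
  # buffered circle area equals the reported extent within 1%
  circ <- out$geometry[[2]]
  expect_lt(abs(geom_area(circ) - 120) / 120, 0.01)
})

test_that("nonpositive point extents are rejected", {
  recs <- pa_records(list(list(lon = 0, lat = 0)), reported_extent = 0)
  expect_error(buffer_points(recs), "reported_extent > 0")
})

test_that("dissolved snapshots union overlaps and are cumulative", {
  g1 <- geom_rect(0, 0, 1, 1)
  recs <- pa_records(list(g1, g1, geom_rect(2, 0, 3, 1)),
                     status_year = c(1950, 1950, 1975))
  s60 <- dissolve_network(recs, 1960)
  s80 <- dissolve_network(recs, 1980)
  # two identical 1950 polygons contribute their area once
  expect_equal(s60$area_km2, geom_area(g1), tolerance = 1e-9)
  expect_equal(s80$area_km2, geom_area(g1) + geom_area(geom_rect(2, 0, 3, 1)),
               tolerance = 1e-9)
  expect_lte(s60$area_km2, s80$area_km2)
})

test_that("missing establishment years follow the configured policy", {
  recs <- pa_records(list(geom_rect(0, 0, 1, 1)), status_year = NA)
  expect_gt(dissolve_network(recs, 1960, "include")$area_km2, 0)
  expect_equal(dissolve_network(recs, 1960, "exclude")$area_km2, 0)
})

test_that("unbuffered points cannot be dissolved", {
  recs <- pa_records(list(list(lon = 0, lat = 0)), reported_extent = 10)
  expect_error(dissolve_network(recs, 2016), "unbuffered points")
})

test_that("a fully protected cell grids to its exact geodesic area", {
  grid <- analysis_grid(-61, -31, 10, 10)
  grid$cells$territory_id <- "T1"
  snap <- dissolve_network(
    pa_records(list(geom_rect(-60.8, -30.9, -60.7, -30.8)), status_year = 1950),
    2016)
  gp <- grid_protection(snap, grid)
  expect_equal(nrow(gp), 1L)
  expect_equal(gp$protected_km2,
               grid$cells$area_km2[grid$cells$cell_id == gp$cell_id],
               tolerance = 1e-9)
})

test_that("split cells attribute protection to each territory's own share", {
  grid <- analysis_grid(0, 0, 2, 1, res = 1)
  # territory border at 60% of the first cell
  terrs <- list(A = geom_rect(0, 0, 0.6, 1), B = geom_rect(0.6, 0, 2, 1))
  snap <- dissolve_network(
    pa_records(list(geom_rect(0, 0, 1, 1)), status_year = 1950), 2016)
  gp <- grid_protection(snap, grid, territories = terrs)
  a <- gp$protected_km2[gp$territory_id == "A"]
  b <- gp$protected_km2[gp$territory_id == "B"]
  expect_equal(a / (a + b), 0.6, tolerance = 1e-9)
  expect_equal(a + b, geom_area(geom_rect(0, 0, 1, 1)), tolerance = 1e-9)
})

test_that("empty snapshots grid to all zeros and CRS mismatches error", {
  grid <- analysis_grid(0, 0, 5, 5)
  grid$cells$territory_id <- "T1"
  empty <- dissolve_network(pa_records(list(), category = character()), 2016)
  expect_equal(nrow(grid_protection(empty, grid)), 0L)
  bad <- empty; bad$crs <- "EPSG:3857"
  expect_error(grid_protection(bad, grid), "CRS mismatch")
})

test_that("raster sampling follows the per-variable semantics", {
  grid <- analysis_grid(0, 0, 2, 2, res = 1)
  ras <- function(m) list(data = m, lon0 = 0, lat0 = 0, nx = 4, ny = 4, res = 0.5)
  const <- ras(matrix(7, 4, 4))
  pop <- ras(matrix(1, 4, 4))
  rd <- ras(matrix(c(0, rep(5, 15)), 4, 4))
  photos <- ras(matrix(2, 4, 4))
  g <- sample_layers(list(temperature = const, population = pop,
                          dist_roads = rd, tourism = pop, photos = photos),
                     grid)
  expect_equal(g$cells$temperature, rep(7, 4))          # mean of a constant
  expect_equal(g$cells$population, rep(4, 4))           # sum of 4 subcells
  expect_equal(min(g$cells$dist_roads), 0)              # min semantics
  expect_equal(g$cells$tourism, rep(2 * 4 / 4, 4))      # photos / population
})

test_that("all-missing cells are flagged missing and skipped in histograms", {
  grid <- analysis_grid(0, 0, 2, 1, res = 1)
  m <- matrix(rep(c(NA, NA, 3, 3), each = 2), 2, 4)  # first cell all NA
  g <- sample_layers(list(temperature = list(data = m, lon0 = 0, lat0 = 0,
                                             nx = 4, ny = 2, res = 0.5)), grid)
  expect_true(is.na(g$cells$temperature[1]))
  cc <- g$cells
  cc$protected_km2 <- 0
  h <- build_histogram(cc, "temperature", c(0, 1, 4))
  expect_equal(attr(h, "skipped_km2"), cc$area_km2[1])
})

test_that("mean-sampled layers reject rasters coarser than the grid", {
  grid <- analysis_grid(0, 0, 4, 4, res = 0.5)
  coarse <- list(data = matrix(1, 2, 2), lon0 = 0, lat0 = 0, nx = 2, ny = 2,
                 res = 1)
  expect_error(sample_layers(list(temperature = coarse), grid),
               "resolution exceeds")
})

test_that("gridded protection conserves the dissolved area per period", {
  g <- small_landscape(seed = 12, nx = 20, ny = 20, n_territories = 2)
  scn <- placement_scenario("biased", target_variable = "population",
                            bias_strength = 2, total_protected_fraction = 0.15,
                            n_units = 20, point_fraction = 0.1)
  rec <- buffer_points(filter_strict_categories(
    generate_protected_network(g, scn, seed = 3)))
  prev <- -1
  for (yr in c(1960, 1980, 2000, 2016)) {
    snap <- dissolve_network(rec, yr)
    expect_gte(snap$area_km2, prev)      # cumulative snapshots
    prev <- snap$area_km2
    if (snap$area_km2 > 0) {
      gp <- grid_protection(snap, g)
      expect_lt(abs(attr(gp, "total_km2") - snap$area_km2) / snap$area_km2,
                0.005)
    }
  }
})
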