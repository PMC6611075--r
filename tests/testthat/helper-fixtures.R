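# Shared fixtures: small landscapes and hand-built cell tables, all generated
# in code at test time.

small_landscape <- function(seed = 1, nx = 20, ny = 20, n_territories = 1,
                            n_ecoregions = 4, ...) {
  generate_landscape(landscape_spec(
    extent = c(-62, -33, -62 + nx * 0.1, -33 + ny * 0.1),
    n_territories = n_territories, n_ecoregions = n_ecoregions,
    seed = seed, ...))
}

# minimal cell table (one territory, one period) from explicit vectors
toy_cells <- function(values, area = 1, protected = 0,
                      variable = "temperature") {
  n <- length(values)
  d <- data.frame(cell_id = seq_len(n), lon = seq_len(n), lat = 0,
                  territory_id = "T1", ecoregion_id = "E1",
                  area_km2 = rep_len(area, n),
                  protected_km2 = rep_len(protected, n),
                  period = 2016)
  d[[variable]] <- values
  d
}

# histogram object with a prescribed PEx vector (for priority arithmetic)
hist_from_pex <- function(pex, v, edges = seq(0, length(pex))) {
  n <- length(pex)
  h <- data.frame(territory = "T1", variable = v, period = 2016,
                  bin = seq_len(n), lo = edges[-(n + 1)], hi = edges[-1],
                  area_km2 = 1, protected_km2 = pex / 100, pex_pct = pex,
                  empty = FALSE)
  class(h) <- c("eq_histogram", "data.frame")
  h
}

# independent mean-absolute-difference Gini oracle
gini_mad <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# brute-force Kendall tau-b oracle over all pairs
tau_b_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}
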