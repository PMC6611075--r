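# Per-territory protection histograms along continuous gradients: the PEx_ij
# surface (percent of each bin's area under protection) that feeds the
# equality index, the priority score and the driver characterisation.

#' Area-weighted quantile with linear interpolation
#'
#' Generalises the classic type-7 quantile (linear interpolation between order
#' statistics) to weighted observations: sorted values x_(k) with weights w_(k)
#' sit at plotting positions p_k = (C_k - w_k) / (S - w_k), where C_k is the
#' cumulative weight and S the total; with equal weights this reduces exactly
#' to type 7. Positions are made non-decreasing before interpolation.
#'
#' @param x numeric values
#' @param w nonnegative weights (cell areas); equal weights recover
#'   `quantile(x, p, type = 7)`
#' @param p probabilities in \[0, 1\]
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), p) {
  stopifnot(length(x) == length(w), all(w >= 0), all(p >= 0 & p <= 1))
  ok <- is.finite(x) & w > 0
  x <- x[ok]; w <- w[ok]
  if (length(x) == 0L) stop("no finite values with positive weight")
  if (length(x) == 1L) return(rep(x, length(p)))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w); s <- cw[length(cw)]
  pos <- cummax((cw - w) / (s - w))
  vapply(p, function(pp) stats::approx(pos, x, xout = pp, rule = 2,
                                       ties = "ordered")$y, 0)
}

#' Percentile-trimmed equal-width bin edges
#'
#' Divides the \[q_lo, q_hi\] weighted-quantile range of a variable into `n`
#' equal-width intervals, then extends the outer edges to the data minimum and
#' maximum so that tail observations are grouped into the first and last bins
#' rather than discarded.
#'
#' @param values variable values over cells
#' @param weights cell areas (km^2); default unweighted
#' @param n number of bins (default 10)
#' @param p_lo,p_hi trimming percentiles (defaults 0.025 / 0.975)
#' @return numeric vector of n + 1 ascending edges
#' @export
trimmed_equal_width_edges <- function(values, weights = rep(1, length(values)),
                                      n = 10, p_lo = 0.025, p_hi = 0.975) {
  ok <- is.finite(values)
  v <- values[ok]; w <- weights[ok]
  if (length(unique(v)) < 2L)
    stop("degenerate gradient: variable is constant, equality undefined on it")
  stopifnot(n >= 1, p_lo < p_hi)
  q <- weighted_quantile(v, w, c(p_lo, p_hi))
  if (q[1] == q[2]) q <- range(v)  # heavy ties: fall back to full range
  edges <- seq(q[1], q[2], length.out = n + 1)
  edges[1] <- min(v)
  edges[n + 1] <- max(v)
  if (any(diff(edges) < 0)) edges <- cummax(edges)
  edges
}

#' Sturges-rule bin edges with the same percentile trimming
#'
#' Number of bins is `ceiling(1 + log2(N))` for N cells carrying the variable.
#'
#' @inheritParams trimmed_equal_width_edges
#' @export
sturges_edges <- function(values, weights = rep(1, length(values)),
                          p_lo = 0.025, p_hi = 0.975) {
  n_cells <- sum(is.finite(values))
  stopifnot(n_cells >= 2)
  trimmed_equal_width_edges(values, weights,
                            n = ceiling(1 + log2(n_cells)),
                            p_lo = p_lo, p_hi = p_hi)
}

# bin assignment: half-open [lo, hi), last interval closed; values clamped
.assign_bins <- function(x, edges) {
  n <- length(edges) - 1L
  b <- findInterval(x, edges, rightmost.closed = TRUE)
  pmin(pmax(b, 1L), n)
}

#' Build a protection histogram along one variable
#'
#' Each cell is assigned to exactly one bin by its variable value (half-open
#' intervals, last closed); cell land area and protected area accumulate per
#' bin; PEx_j = 100 * protected_j / area_j. Empty bins carry PEx = 0 and an
#' `empty` flag. Cells with a missing variable value are skipped and their
#' area recorded in the `skipped_km2` attribute.
#'
#' @param cells data frame with columns `area_km2`, `protected_km2` and the
#'   variable column
#' @param variable name of the variable column
#' @param edges ascending bin edges (n + 1 values)
#' @param territory,period optional labels carried into the result
#' @return a data frame of class `eq_histogram` with one row per bin:
#'   (territory, variable, period, bin, lo, hi, area_km2, protected_km2,
#'    pex_pct, empty)
#' @export
build_histogram <- function(cells, variable, edges,
                            territory = NA_character_, period = NA) {
  stopifnot(variable %in% names(cells),
            all(c("area_km2", "protected_km2") %in% names(cells)),
            !is.unsorted(edges), length(edges) >= 2)
  v <- cells[[variable]]
  ok <- is.finite(v)
  n <- length(edges) - 1L
  b <- .assign_bins(v[ok], edges)
  area <- as.vector(rowsum(cells$area_km2[ok], b, reorder = TRUE))
  prot <- as.vector(rowsum(cells$protected_km2[ok], b, reorder = TRUE))
  full_area <- full_prot <- numeric(n)
  idx <- sort(unique(b))
  full_area[idx] <- area; full_prot[idx] <- prot
  if (any(full_prot > full_area + 1e-6))
    stop("protected area exceeds land area in a bin; upstream double counting?")
  pex <- ifelse(full_area > 0, 100 * full_prot / full_area, 0)
  out <- data.frame(territory = territory, variable = variable, period = period,
                    bin = seq_len(n), lo = edges[-(n + 1)], hi = edges[-1],
                    area_km2 = full_area, protected_km2 = full_prot,
                    pex_pct = pmin(pex, 100), empty = full_area == 0)
  attr(out, "skipped_km2") <- sum(cells$area_km2[!ok])
  class(out) <- c("eq_histogram", "data.frame")
  out
}

#' Per-ecoregion protection extent within a territory
#'
#' PEx per ecoregion = 100 * protected / total area of that ecoregion's cells
#' within the territory. Ecoregions absent from the territory do not appear.
#'
#' @param cells cell table rows for one territory and period, with columns
#'   `ecoregion_id`, `area_km2`, `protected_km2`
#' @param territory,period optional labels
#' @return data frame (territory, period, ecoregion_id, area_km2,
#'   protected_km2, pex_pct)
#' @export
ecoregion_pex <- function(cells, territory = NA_character_, period = NA) {
  stopifnot(all(c("ecoregion_id", "area_km2", "protected_km2") %in% names(cells)))
  eco <- sort(unique(cells$ecoregion_id))
  area <- as.vector(rowsum(cells$area_km2, cells$ecoregion_id))
  prot <- as.vector(rowsum(cells$protected_km2, cells$ecoregion_id))
  data.frame(territory = territory, period = period, ecoregion_id = eco,
             area_km2 = area, protected_km2 = prot,
             pex_pct = ifelse(area > 0, pmin(100 * prot / area, 100), 0))
}
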