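# Protection equality: one minus the Gini coefficient of per-bin protection
# percentages. The rank form used here,
#   G = (2/n) * sum_j j * x_(j) / sum_j x_(j) - (n + 1)/n,
# with x sorted ascending and j the rank, is algebraically identical to the
# mean-absolute-difference Gini sum|x_a - x_b| / (2 n^2 mu); the test suite
# asserts the equivalence to 1e-12 on random vectors.

#' Gini coefficient of a nonnegative vector (rank form)
#'
#' Values are sorted ascending before ranking, so the statistic is permutation
#' invariant and scale invariant. For n bins the result lies in
#' \[0, (n-1)/n\]: 0 for a constant positive vector, (n-1)/n when a single
#' entry carries all mass.
#'
#' @param x nonnegative values (e.g., the PEx vector over bins); length >= 2
#' @return G in \[0, (n-1)/n\]
#' @export
gini <- function(x) {
  if (length(x) < 2L) stop("Gini needs at least 2 values")
  if (any(!is.finite(x)) || any(x < 0)) stop("Gini needs finite nonnegative values")
  s <- sum(x)
  if (s == 0) stop("undefined equality: no protection (all-zero vector)")
  x <- sort(x)
  n <- length(x)
  (2 / n) * sum(seq_len(n) * x) / s - (n + 1) / n
}

#' Protection-equality index G' = 1 - Gini
#'
#' Equals 1 when every bin holds the same positive protection percentage
#' (perfectly even representation, regardless of its level) and 1/n when all
#' protection sits in a single bin.
#'
#' @param pex vector of per-bin protection percentages
#' @export
equality_index <- function(pex) 1 - gini(pex)

#' Kendall's tau (tie-corrected, tau-b) between two paired samples
#'
#' @param x,y equal-length numeric vectors, length >= 2
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("Kendall's tau undefined: a margin is constant")
  stats::cor(x, y, method = "kendall")
}

#' Prune collinear variables by consecutive-pair Kendall's tau
#'
#' A single left-to-right pass over the variables in their fixed order: if the
#' |tau| between a variable and the *next still-active* variable exceeds the
#' threshold, the earlier variable of the pair is eliminated. An iterative
#' variant re-scans until no pair exceeds the threshold.
#'
#' @param cells cell table (one period) carrying the variable columns
#' @param variables variable names in their fixed order
#' @param threshold |tau| above which the earlier variable is dropped
#'   (default 0.55)
#' @param iterative re-scan after eliminations (default `FALSE`, single pass)
#' @return list with `retained` (character vector) and `report` (data frame of
#'   every pairwise decision: var_a, var_b, tau, dropped)
#' @export
prune_collinear <- function(cells, variables, threshold = 0.55,
                            iterative = FALSE) {
  stopifnot(all(variables %in% names(cells)))
  rep_rows <- list()
  # a variable constant over the unit is a degenerate gradient: tau (and the
  # histogram) are undefined on it, so it is set aside up front and recorded
  degen <- vapply(variables, function(v)
    length(unique(cells[[v]][is.finite(cells[[v]])])) < 2L, TRUE)
  for (v in variables[degen])
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      var_a = v, var_b = NA_character_, tau = NA_real_, dropped = v)
  active <- variables[!degen]
  repeat {
    dropped_any <- FALSE
    i <- 1L
    while (i < length(active)) {
      tau <- kendall_tau(cells[[active[i]]], cells[[active[i + 1L]]])
      drop_i <- abs(tau) > threshold
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        var_a = active[i], var_b = active[i + 1L], tau = tau,
        dropped = if (drop_i) active[i] else NA_character_)
      if (drop_i) {
        active <- active[-i]
        dropped_any <- TRUE
        # stay at the same position: the new pair (i, i+1) is examined next
      } else i <- i + 1L
    }
    if (!iterative || !dropped_any) break
  }
  if (length(active) < 2L)
    warning("fewer than 2 variables retained after pruning; ",
            "mean G' will use the single survivor")
  list(retained = active,
       report = if (length(rep_rows)) do.call(rbind, rep_rows)
                else data.frame(var_a = character(), var_b = character(),
                                tau = numeric(), dropped = character()))
}

#' Territory-level equality from per-variable histograms
#'
#' Averages the per-variable equality indices G'_i over the retained variables.
#' Variables whose PEx vector is all zero are reported as undefined and the
#' mean is taken over the defined ones (with a warning); if no variable is
#' defined the mean is `NA`.
#'
#' @param histograms list of `eq_histogram` (one per variable, same
#'   territory/period)
#' @param retained character vector of retained variable names
#' @return data frame of class `eq_equality`: one row per retained variable
#'   (G_i, G'_i, defined) plus attributes `mean_gprime`, `extent_pct`
#' @export
territory_equality <- function(histograms, retained = NULL) {
  stopifnot(length(histograms) >= 1)
  vars <- vapply(histograms, function(h) h$variable[1], "")
  if (is.null(retained)) retained <- vars
  use <- match(retained, vars)
  if (anyNA(use)) stop("missing histogram for: ",
                       paste(retained[is.na(use)], collapse = ", "))
  rows <- lapply(use, function(i) {
    h <- histograms[[i]]
    defined <- sum(h$pex_pct) > 0
    g <- if (defined) gini(h$pex_pct) else NA_real_
    data.frame(territory = h$territory[1], period = h$period[1],
               variable = h$variable[1], gini = g, gprime = 1 - g,
               defined = defined)
  })
  out <- do.call(rbind, rows)
  if (any(!out$defined))
    warning("PEx all zero for: ", paste(out$variable[!out$defined], collapse = ", "),
            "; mean G' over the defined variables")
  h1 <- histograms[[use[1]]]
  area <- sum(h1$area_km2); prot <- sum(h1$protected_km2)
  attr(out, "mean_gprime") <- if (any(out$defined)) mean(out$gprime[out$defined])
                              else NA_real_
  attr(out, "extent_pct") <- if (area > 0) 100 * prot / area else NA_real_
  class(out) <- c("eq_equality", "data.frame")
  out
}

#' Equality on the biogeographical (ecoregion) basis
#'
#' G' of the per-ecoregion PEx vector within a territory. With a single
#' ecoregion equality is undefined (returned as `NA` with reason), mirroring
#' territories whose land falls in one biogeographical unit.
#'
#' @param pex_table output of [ecoregion_pex()]
#' @return list(gprime, n_ecoregions, extent_pct, reason)
#' @export
ecoregion_equality <- function(pex_table) {
  n <- nrow(pex_table)
  ext <- 100 * sum(pex_table$protected_km2) / sum(pex_table$area_km2)
  if (n < 2L)
    return(list(gprime = NA_real_, n_ecoregions = n, extent_pct = ext,
                reason = "equality undefined: single ecoregion"))
  if (sum(pex_table$pex_pct) == 0)
    return(list(gprime = NA_real_, n_ecoregions = n, extent_pct = ext,
                reason = "equality undefined: no protection"))
  list(gprime = equality_index(pex_table$pex_pct), n_ecoregions = n,
       extent_pct = ext, reason = NA_character_)
}

#' Decadal extent-equality trajectory for one territory
#'
#' For each cutoff period computes the protection extent (%), the mean G' over
#' retained physical variables, and the decade-to-decade efficiency
#' (delta G' / delta extent, undefined when the extent did not change).
#'
#' @param cell_table an `eq_cells` table (all periods) for one territory
#' @param variables physical variable names (default the five physical layers)
#' @param threshold Kendall pruning threshold
#' @param n_bins histogram bins (default 10)
#' @return data frame of class `eq_trajectory`
#' @export
trajectory <- function(cell_table, variables = PHYSICAL_VARS, threshold = 0.55,
                       n_bins = 10) {
  periods <- sort(unique(cell_table$period))
  cur <- cell_table[cell_table$period == periods[length(periods)], ]
  pr <- prune_collinear(cur, variables, threshold)
  edges <- lapply(pr$retained, function(v)
    trimmed_equal_width_edges(cur[[v]], cur$area_km2, n = n_bins))
  names(edges) <- pr$retained
  rows <- lapply(periods, function(p) {
    cc <- cell_table[cell_table$period == p, ]
    hh <- lapply(pr$retained, function(v)
      build_histogram(cc, v, edges[[v]], territory = cc$territory_id[1],
                      period = p))
    defined <- vapply(hh, function(h) sum(h$pex_pct) > 0, TRUE)
    gp <- if (any(defined))
      mean(vapply(hh[defined], function(h) equality_index(h$pex_pct), 0))
    else NA_real_
    data.frame(period = p,
               extent_pct = 100 * sum(cc$protected_km2) / sum(cc$area_km2),
               mean_gprime = gp)
  })
  out <- do.call(rbind, rows)
  d_ext <- c(NA, diff(out$extent_pct))
  d_gp <- c(NA, diff(out$mean_gprime))
  out$efficiency <- ifelse(is.na(d_ext) | d_ext == 0, NA_real_, d_gp / d_ext)
  attr(out, "retained") <- pr$retained
  class(out) <- c("eq_trajectory", "data.frame")
  out
}
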