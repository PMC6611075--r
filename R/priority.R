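# Conservation priority: the per-cell mean shortfall from complete protection
# across retained physical gradients, Pr_k = (1/m) sum_i (100 - PEx_i), where
# PEx_i is the protection percentage of the bin the cell falls into along
# variable i. Higher Pr = more underrepresented conditions.

#' Priority score of cells from current-period histograms
#'
#' @param cells cell table rows (one scope and period) with the variable
#'   columns
#' @param histograms named list of `eq_histogram` (one per retained variable,
#'   same scope/period; names are variable names)
#' @param retained character vector of retained variable names (size m)
#' @return data frame (cell_id, pr, n_vars_used, flagged) where `flagged`
#'   marks cells scored on fewer than m variables; cells missing every
#'   variable get `NA`
#' @export
cell_priority <- function(cells, histograms, retained = names(histograms)) {
  stopifnot(all(retained %in% names(histograms)))
  m <- length(retained)
  shortfall <- matrix(NA_real_, nrow(cells), m)
  for (i in seq_len(m)) {
    h <- histograms[[retained[i]]]
    edges <- c(h$lo, h$hi[nrow(h)])
    v <- cells[[retained[i]]]
    ok <- is.finite(v)
    b <- .assign_bins(v[ok], edges)
    shortfall[ok, i] <- 100 - h$pex_pct[b]
  }
  used <- rowSums(!is.na(shortfall))
  pr <- ifelse(used > 0, rowMeans(shortfall, na.rm = TRUE), NA_real_)
  data.frame(cell_id = cells$cell_id, pr = pr, n_vars_used = used,
             flagged = used > 0 & used < m)
}

#' Classify priority scores into balanced quantile classes
#'
#' Rank-based classes of equal cell count (plus or minus one), quartiles or
#' deciles; ties are broken by `cell_id` so maps are reproducible. Class 1 is
#' the lowest priority, class `k_classes` the highest.
#'
#' @param priority output of [cell_priority()] (rows with `NA` scores are
#'   dropped)
#' @param k_classes 4 (quartiles) or 10 (deciles)
#' @return the priority table with a `class` column; attribute `degenerate`
#'   flags all-equal scores
#' @export
classify_quantiles <- function(priority, k_classes = 4) {
  stopifnot(k_classes %in% c(4L, 10L) || k_classes >= 2)
  p <- priority[!is.na(priority$pr), , drop = FALSE]
  n <- nrow(p)
  if (n < k_classes)
    stop("fewer scored cells (", n, ") than classes (", k_classes, ")")
  o <- order(p$pr, p$cell_id)
  cls <- integer(n)
  cls[o] <- floor((seq_len(n) - 1) * k_classes / n) + 1L
  p$class <- cls
  attr(p, "degenerate") <- length(unique(p$pr)) == 1L
  p
}

#' National or continental priority map
#'
#' Builds current-period histograms per scope (each territory separately, or
#' the whole extent as a single unit), prunes collinear variables per scope,
#' scores every cell with [cell_priority()] and classifies the scores.
#'
#' @param cell_table an `eq_cells` table; the latest period is used
#' @param scope `"national"` or `"continental"`
#' @param variables candidate physical variables
#' @param threshold Kendall pruning threshold
#' @param k_classes quantile classes (4 or 10)
#' @param n_bins histogram bins
#' @return data frame (cell_id, territory_id, pr, class, ...) for the scope
#' @export
priority_map <- function(cell_table, scope = c("national", "continental"),
                         variables = PHYSICAL_VARS, threshold = 0.55,
                         k_classes = 4, n_bins = 10) {
  scope <- match.arg(scope)
  period <- max(cell_table$period)
  cur <- cell_table[cell_table$period == period, ]
  score_unit <- function(cc, label) {
    pr <- prune_collinear(cc, variables, threshold)
    hh <- lapply(pr$retained, function(v)
      build_histogram(cc, v, trimmed_equal_width_edges(cc[[v]], cc$area_km2,
                                                       n = n_bins),
                      territory = label, period = period))
    names(hh) <- pr$retained
    out <- cell_priority(cc, hh, pr$retained)
    out$territory_id <- if ("territory_id" %in% names(cc)) cc$territory_id
                        else label
    out
  }
  scored <- if (scope == "continental") {
    classify_quantiles(score_unit(cur, "continent"), k_classes)
  } else {
    do.call(rbind, lapply(split(cur, cur$territory_id), function(cc)
      classify_quantiles(score_unit(cc, cc$territory_id[1]), k_classes)))
  }
  rownames(scored) <- NULL
  scored$scope <- scope
  scored
}
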