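# Human drivers of protection placement: histograms of PEx along the five
# human-factor gradients, and a random-forest ranking of their importance via
# out-of-bag permutation %MSE increase with bootstrap uncertainty. The
# regression response is the per-cell protected fraction (continuous, 0-1).

#' Protection histograms along the human-factor gradients
#'
#' Identical contract to [build_histogram()], applied to the human variables
#' with the same percentile trimming as the physical histograms.
#'
#' @param cells cell table rows for one territory and period
#' @param variables human-factor variable names (default the five human layers)
#' @param n_bins bins (default 10); `"sturges"` for the Sturges rule
#' @param territory,period labels carried into the histograms
#' @return named list of `eq_histogram`
#' @export
driver_histograms <- function(cells, variables = HUMAN_VARS, n_bins = 10,
                              territory = NA_character_, period = NA) {
  out <- lapply(variables, function(v) {
    edges <- if (identical(n_bins, "sturges"))
      sturges_edges(cells[[v]], cells$area_km2)
    else trimmed_equal_width_edges(cells[[v]], cells$area_km2, n = n_bins)
    build_histogram(cells, v, edges, territory = territory, period = period)
  })
  names(out) <- variables
  out
}

# fit one regression forest on the per-cell protected fraction (or, behind a
# flag, on binary presence/absence of protection)
.fit_forest <- function(cells, predictors, ntree, mtry, nodesize,
                        importance = TRUE, response = "fraction") {
  X <- as.matrix(cells[, predictors, drop = FALSE])
  y <- switch(response,
              fraction = cells$protected_km2 / cells$area_km2,
              binary = as.numeric(cells$protected_km2 > 0),
              stop("unknown response mode: ", response))
  ok <- stats::complete.cases(X) & is.finite(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (stats::var(y) == 0) stop("no variance to explain: constant response")
  fit <- .rf_forest(X, y, as.integer(ntree), as.integer(mtry),
                    as.integer(nodesize), importance)
  fit$predictors <- predictors
  fit$n <- length(y)
  fit
}

#' Select mtry by out-of-bag mean squared error
#'
#' Fits one forest per candidate (each from the same seed so OOB errors are
#' comparable) and returns the candidate with the lowest OOB-MSE; ties go to
#' the smallest mtry.
#'
#' @param cells cell table rows for one territory (one period)
#' @param predictors human-factor variable names
#' @param candidates candidate mtry values (default 1..p)
#' @param ntree,nodesize forest settings (defaults 500 and 1)
#' @param seed RNG seed
#' @return the selected mtry; attribute `oob_mse` holds the per-candidate
#'   errors
#' @export
select_mtry <- function(cells, predictors = HUMAN_VARS,
                        candidates = seq_along(predictors),
                        ntree = 500, nodesize = 1, seed = 1) {
  if (nrow(cells) < 50)
    stop("insufficient cells for RF: ", nrow(cells), " < 50")
  stopifnot(length(candidates) >= 1,
            all(candidates >= 1 & candidates <= length(predictors)))
  errs <- vapply(candidates, function(m) {
    .with_seed(seed,
      .fit_forest(cells, predictors, ntree, m, nodesize,
                  importance = FALSE)$oob_mse)
  }, 0)
  best <- candidates[order(errs, candidates)][1]
  attr(best, "oob_mse") <- stats::setNames(errs, candidates)
  best
}

#' Bootstrap variable importance of the human drivers
#'
#' For each of `B` bootstrap resamples of the cells (with replacement, full
#' size) a regression forest is fitted on the per-cell protected fraction and
#' the per-variable OOB permutation MSE increase is recorded. Importances are
#' reported both raw and normalised to sum to 100 within the territory
#' (relative VI in %MSE, the layout of published driver tables); the mean and
#' standard deviation over the B replicates quantify uncertainty.
#'
#' @param cells cell table rows for one territory (one period)
#' @param predictors human-factor variable names
#' @param B bootstrap replicates (default 1000; reduce for quick runs)
#' @param ntree,nodesize forest settings (defaults 500 and 1)
#' @param mtry fixed mtry, or `NULL` to select it via [select_mtry()]
#' @param seed RNG seed; the whole computation is reproducible from it
#' @param territory label carried into the result
#' @param response `"fraction"` (default, the continuous per-cell protected
#'   fraction) or `"binary"` (presence/absence of protection)
#' @return an `eq_importance` object: data frame (variable, vi_mean, vi_sd,
#'   raw_mean, raw_sd, top_rank_share) with the settings and the B x p matrix
#'   of relative VIs as attributes
#' @export
vi_bootstrap <- function(cells, predictors = HUMAN_VARS, B = 1000,
                         ntree = 500, nodesize = 1, mtry = NULL, seed = 1,
                         territory = NA_character_, response = "fraction") {
  if (nrow(cells) < 50)
    stop("insufficient cells for RF: ", nrow(cells), " < 50")
  stopifnot(B >= 1)
  if (is.null(mtry))
    mtry <- select_mtry(cells, predictors, ntree = ntree,
                        nodesize = nodesize, seed = seed)
  p <- length(predictors)
  .with_seed(seed, {
    rel <- matrix(NA_real_, B, p, dimnames = list(NULL, predictors))
    raw <- matrix(NA_real_, B, p, dimnames = list(NULL, predictors))
    for (b in seq_len(B)) {
      rows <- sample.int(nrow(cells), replace = TRUE)
      fit <- .fit_forest(cells[rows, , drop = FALSE], predictors,
                         ntree, mtry, nodesize, response = response)
      raw[b, ] <- fit$imp_mean
      pos <- pmax(fit$imp_mean, 0)
      rel[b, ] <- if (sum(pos) > 0) 100 * pos / sum(pos) else rep(100 / p, p)
    }
    top <- apply(rel, 1, which.max)
    out <- data.frame(
      territory = territory, variable = predictors,
      vi_mean = colMeans(rel),
      vi_sd = if (B > 1) apply(rel, 2, stats::sd) else rep(0, p),
      raw_mean = colMeans(raw),
      raw_sd = if (B > 1) apply(raw, 2, stats::sd) else rep(0, p),
      top_rank_share = tabulate(top, nbins = p) / B)
    rownames(out) <- NULL
    attr(out, "settings") <- list(ntree = ntree, nodesize = nodesize,
                                  mtry = as.integer(mtry), B = B, seed = seed,
                                  n_cells = nrow(cells),
                                  sd_degenerate = B == 1)
    attr(out, "replicates") <- rel
    class(out) <- c("eq_importance", "data.frame")
    out
  })
}
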