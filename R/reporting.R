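# Reporting and orchestration: the descriptive extent-equality regression
# across territories and the end-to-end pipeline runner driven by a
# serialisable config.

#' Ordinary least squares of mean G' on protection extent across territories
#'
#' Descriptive cross-territory regression; configured territories (e.g., the
#' continental aggregate or territories with undefined equality) are excluded
#' and logged in the result.
#'
#' @param results data frame with columns `territory`, `extent_pct`,
#'   `mean_gprime`
#' @param exclude territory labels to leave out
#' @return list(slope, intercept, r_squared, n, excluded)
#' @export
extent_equality_regression <- function(results, exclude = character()) {
  keep <- !(results$territory %in% exclude) & is.finite(results$mean_gprime) &
    is.finite(results$extent_pct)
  d <- results[keep, ]
  if (nrow(d) < 3) stop("need >= 3 territory points for the regression, have ",
                        nrow(d))
  fit <- stats::lm(mean_gprime ~ extent_pct, data = d)
  sst <- sum((d$mean_gprime - mean(d$mean_gprime))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(stats::resid(fit)^2) / sst
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = nrow(d),
       excluded = results$territory[!keep])
}

#' Read a pipeline run configuration (JSON or YAML)
#' @param path config file; format chosen by extension
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the full synthetic pipeline
#'
#' Generates the landscape and protected network, ingests them (filter,
#' buffer, dissolve, grid) into the canonical cell table, and computes
#' histograms, per-territory equality and trajectories (physical and
#' ecoregion bases), national and continental priority maps, and driver
#' importance. All tabular artifacts are written as CSV under `out_dir`
#' together with a JSON manifest carrying seeds, settings and md5 checksums.
#'
#' @param config a list (or path handled by [read_run_config()]) with entries:
#'   `landscape` (arguments of [landscape_spec()]), `scenario` (arguments of
#'   [placement_scenario()]), `seed`, and optionally `periods`, `bins` (a
#'   number or `"sturges"`), `tau_threshold`, `scopes`, `k_classes`,
#'   `rf` (list: B, ntree, nodesize, mtry), `drivers` (logical)
#' @param out_dir output directory, created if missing
#' @return invisibly, a list with the in-memory results and the manifest
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  periods <- if (is.null(config$periods)) c(seq(1960, 2010, 10), 2016)
             else as.numeric(config$periods)
  bins <- if (is.null(config$bins)) 10 else config$bins
  tau <- if (is.null(config$tau_threshold)) 0.55 else config$tau_threshold
  k_classes <- if (is.null(config$k_classes)) 4 else config$k_classes
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] %.2fs", name, as.numeric(Sys.time() - t0, "secs")))
    res
  }
  spec <- stage("synth", do.call(landscape_spec,
    c(config$landscape, if (is.null(config$landscape$seed)) list(seed = seed))))
  grid <- stage("landscape", generate_landscape(spec))
  scn <- do.call(placement_scenario, config$scenario)
  raw <- stage("network", generate_protected_network(grid, scn, seed = seed))
  rec <- stage("ingest-filter", filter_strict_categories(raw))
  rec <- stage("ingest-buffer", buffer_points(rec))
  cells <- stage("ingest-grid", build_cell_table(grid, rec, periods = periods))
  write_cell_table(cells, file.path(out_dir, "cells.csv"))
  cur <- cells[cells$period == max(periods), ]
  terrs <- sort(unique(cur$territory_id))

  edges_for <- function(cc, v) {
    if (identical(bins, "sturges")) sturges_edges(cc[[v]], cc$area_km2)
    else trimmed_equal_width_edges(cc[[v]], cc$area_km2, n = as.numeric(bins))
  }
  # per-territory equality (physical + ecoregion bases) and trajectories
  eq_rows <- list(); hist_rows <- list(); traj_rows <- list()
  for (tt in terrs) {
    cc <- cur[cur$territory_id == tt, ]
    pr <- prune_collinear(cc, PHYSICAL_VARS, tau)
    hh <- lapply(pr$retained, function(v)
      build_histogram(cc, v, edges_for(cc, v), territory = tt,
                      period = max(periods)))
    eqr <- suppressWarnings(territory_equality(hh))
    eco <- ecoregion_equality(ecoregion_pex(cc, territory = tt,
                                            period = max(periods)))
    eq_rows[[tt]] <- data.frame(
      territory = tt,
      extent_pct = attr(eqr, "extent_pct"),
      mean_gprime = attr(eqr, "mean_gprime"),
      gprime_ecoregion = eco$gprime,
      n_ecoregions = eco$n_ecoregions,
      retained = paste(pr$retained, collapse = ";"))
    hist_rows[[tt]] <- do.call(rbind, hh)
    tr <- trajectory(cells[cells$territory_id == tt, ], threshold = tau,
                     n_bins = if (identical(bins, "sturges")) 10
                              else as.numeric(bins))
    tr$territory <- tt
    traj_rows[[tt]] <- tr
  }
  equality_tab <- do.call(rbind, eq_rows)
  utils::write.csv(equality_tab, file.path(out_dir, "equality.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, hist_rows),
                   file.path(out_dir, "histograms.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, traj_rows),
                   file.path(out_dir, "trajectory.csv"), row.names = FALSE)
  reg <- if (sum(is.finite(equality_tab$mean_gprime)) >= 3)
    extent_equality_regression(equality_tab) else NULL
  # priority maps
  prio <- lapply(c("national", "continental"), function(sc)
    priority_map(cells, sc, threshold = tau, k_classes = k_classes))
  names(prio) <- c("national", "continental")
  utils::write.csv(rbind(prio$national, prio$continental),
                   file.path(out_dir, "priority.csv"), row.names = FALSE)
  # drivers
  imp <- NULL
  if (!isFALSE(config$drivers)) {
    rf <- config$rf
    imp <- do.call(rbind, lapply(terrs, function(tt) {
      cc <- cur[cur$territory_id == tt, ]
      # territories too small for a forest or without variance in the
      # protected fraction (e.g., fully unprotected) have no drivers to rank
      if (nrow(cc) < 50 || stats::var(cc$protected_km2 / cc$area_km2) == 0)
        return(NULL)
      vi_bootstrap(cc,
                   B = if (is.null(rf$B)) 50 else rf$B,
                   ntree = if (is.null(rf$ntree)) 500 else rf$ntree,
                   nodesize = if (is.null(rf$nodesize)) 1 else rf$nodesize,
                   mtry = rf$mtry, seed = seed, territory = tt)
    }))
    if (!is.null(imp))
      utils::write.csv(imp, file.path(out_dir, "importance.csv"),
                       row.names = FALSE)
  }
  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("equirep")),
    seed = seed, periods = periods, bins = bins, tau_threshold = tau,
    artifacts = basename(files),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))),
    regression = reg)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(grid = grid, records = rec, cells = cells,
                 equality = equality_tab, trajectory = do.call(rbind, traj_rows),
                 priority = prio, importance = imp, regression = reg,
                 manifest = manifest))
}
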