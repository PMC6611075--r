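# Synthetic protected-area networks with planted placement structure: the
# ground truth (which cells are protected, along which driver the placement
# was biased, per-bin protected areas) is emitted alongside the vector records
# so that every downstream statistic can be checked against construction.

#' Specify a protected-area placement scenario
#'
#' Three placement modes are supported. `"uniform"` is the idealised balanced
#' network: every cell holds the same protected fraction of its area (a
#' centred sub-rectangle), so each bin's PEx equals the target fraction by
#' construction. `"single_bin"` places all protection inside cells of one bin
#' of one variable (bins from [trimmed_equal_width_edges()] over the whole
#' grid). `"biased"` samples cells without replacement with log-odds weight
#' `-bias_strength` per standard deviation of the driver variable, so positive
#' strengths concentrate protection where the driver is low (e.g., sparsely
#' populated cells); `bias_strength = 0` is unbiased random placement.
#'
#' @param name one of `"uniform"`, `"single_bin"`, `"biased"`
#' @param target_variable driver / binned variable (single_bin and biased)
#' @param target_bin bin index 1..n_bins (single_bin)
#' @param bias_strength nonnegative log-odds weight (biased)
#' @param total_protected_fraction target protected fraction of land in (0, 1)
#' @param establishment_years named probability vector over decade start years
#'   (default: uniform over 1930, 1940, ..., 2010)
#' @param n_units number of protected-area records to emit
#' @param point_fraction fraction of units emitted as point-plus-extent records
#'   (exercises the buffering path); ignored for `"uniform"`
#' @param nonstrict_fraction extra units (relative to `n_units`) added with a
#'   non-strict category label, excluded from the ground truth
#' @param n_bins bins used for single_bin targeting (default 10)
#' @export
placement_scenario <- function(name = c("uniform", "single_bin", "biased"),
                               target_variable = NULL, target_bin = NULL,
                               bias_strength = 0,
                               total_protected_fraction = 0.1,
                               establishment_years = NULL,
                               n_units = 25, point_fraction = 0.05,
                               nonstrict_fraction = 0, n_bins = 10) {
  name <- match.arg(name)
  stopifnot(total_protected_fraction > 0, total_protected_fraction < 1,
            bias_strength >= 0, n_units >= 0)
  if (name == "single_bin")
    stopifnot(!is.null(target_variable), !is.null(target_bin),
              target_bin >= 1, target_bin <= n_bins)
  if (name == "biased") stopifnot(!is.null(target_variable))
  if (is.null(establishment_years)) {
    establishment_years <- rep(1 / 9, 9)
    names(establishment_years) <- seq(1930, 2010, by = 10)
  }
  structure(list(name = name, target_variable = target_variable,
                 target_bin = target_bin, bias_strength = bias_strength,
                 total_protected_fraction = total_protected_fraction,
                 establishment_years = establishment_years,
                 n_units = n_units, point_fraction = point_fraction,
                 nonstrict_fraction = nonstrict_fraction, n_bins = n_bins),
            class = "placement_scenario")
}

# container for vector protected-area records
.pa_records <- function(table, geometry, crs = "EPSG:4326") {
  structure(list(table = table, geometry = geometry, crs = crs),
            class = "pa_records")
}

#' Assemble protected-area records from geometries
#'
#' @param geometry list of geometries: `eq_geom` polygons/ellipses from
#'   [geom_polygon()] and friends, or point locations given as
#'   `list(lon =, lat =)` (which require `reported_extent`)
#' @param category protection class labels (IUCN I-IV analogues or excluded
#'   classes), recycled
#' @param status_year establishment years (NA allowed), recycled
#' @param reported_extent extents in km^2 for point records, recycled
#' @param unit_id unit identifiers (default PA0001, ...)
#' @param crs coordinate reference tag
#' @return a `pa_records` object
#' @export
pa_records <- function(geometry, category = "II", status_year = NA_integer_,
                       reported_extent = NA_real_, unit_id = NULL,
                       crs = "EPSG:4326") {
  if (inherits(geometry, "eq_geom")) geometry <- list(geometry)
  n <- length(geometry)
  geom_type <- vapply(geometry, function(g)
    if (inherits(g, "eq_geom")) "polygon" else "point", "")
  if (is.null(unit_id)) unit_id <- sprintf("PA%04d", seq_len(n))
  tab <- data.frame(unit_id = unit_id,
                    category = rep_len(as.character(category), n),
                    status_year = rep_len(as.integer(status_year), n),
                    reported_extent = rep_len(as.numeric(reported_extent), n),
                    geom_type = geom_type)
  .pa_records(tab, geometry, crs)
}

#' @export
print.pa_records <- function(x, ...) {
  cat(sprintf("<pa_records> %d units (%d polygon, %d point), %s\n",
              nrow(x$table), sum(x$table$geom_type == "polygon"),
              sum(x$table$geom_type == "point"), x$crs))
  invisible(x)
}

#' Number of protected-area records
#' @param x a `pa_records`
#' @export
n_records <- function(x) nrow(x$table)

# centred sub-rectangle covering `frac` of one cell
.cell_subrect <- function(grid, cell_id, frac) {
  col <- (cell_id - 1L) %% grid$nx + 1L
  row <- (cell_id - 1L) %/% grid$nx + 1L
  cx <- grid$lon0 + (col - 0.5) * grid$res
  cy <- grid$lat0 + (row - 0.5) * grid$res
  h <- grid$res * sqrt(frac) / 2
  geom_rect(cx - h, cy - h, cx + h, cy + h)
}

#' Generate a synthetic protected-area network
#'
#' Emits polygon and point-plus-extent records whose aggregate protected area
#' approximates `total_protected_fraction` of the land area to within one
#' cell, each carrying a strict (I-IV) or excluded category and an
#' establishment year. The planted ground truth (per-cell strictly protected
#' km^2, target bin edges, driver) is attached as attribute `ground_truth`.
#'
#' @param grid an `eq_grid` from [generate_landscape()]
#' @param scenario a [placement_scenario()]
#' @param seed integer RNG seed
#' @return a `pa_records` object
#' @export
generate_protected_network <- function(grid, scenario, seed = 1) {
  stopifnot(inherits(grid, "eq_grid"), inherits(scenario, "placement_scenario"))
  cells <- grid$cells
  land <- sum(cells$area_km2 * cells$land_frac)
  target <- scenario$total_protected_fraction * land
  .with_seed(seed, {
    if (scenario$n_units == 0L) {
      rec <- .pa_records(
        data.frame(unit_id = character(), category = character(),
                   status_year = integer(), reported_extent = numeric(),
                   geom_type = character()),
        list(), grid$crs)
      attr(rec, "ground_truth") <- list(
        scenario = scenario,
        cell = data.frame(cell_id = cells$cell_id, protected_km2 = 0),
        total_km2 = 0)
      return(rec)
    }
    geoms <- list(); type <- character(); extent <- numeric()
    truth_prot <- numeric(nrow(cells))
    edges <- NULL
    if (scenario$name == "uniform") {
      frac <- scenario$total_protected_fraction
      chunk <- as.integer(cut(seq_len(nrow(cells)), scenario$n_units))
      for (k in seq_len(scenario$n_units)) {
        ids <- cells$cell_id[chunk == k]
        rects <- lapply(ids, .cell_subrect, grid = grid, frac = frac)
        rings <- unlist(lapply(rects, `[[`, "rings"), recursive = FALSE)
        geoms[[k]] <- geom_polygon(rings)
        type[k] <- "polygon"; extent[k] <- NA_real_
      }
      truth_prot <- cells$area_km2 * frac
    } else {
      if (scenario$name == "single_bin") {
        edges <- trimmed_equal_width_edges(cells[[scenario$target_variable]],
                                           cells$area_km2, n = scenario$n_bins)
        b <- .assign_bins(cells[[scenario$target_variable]], edges)
        cand <- which(b == scenario$target_bin)
        if (!length(cand))
          stop("target bin ", scenario$target_bin, " holds no cells")
        cand <- cand[sample.int(length(cand))]
      } else {
        # bias acts on the driver's quantile ranks (transform invariant, so a
        # skewed field like population biases placement as strongly as a
        # symmetric one): log-odds weight -bias_strength per sd of the rank
        v <- cells[[scenario$target_variable]]
        z <- scale(rank(v, ties.method = "average"))[, 1]
        w <- exp(-scenario$bias_strength * z)
        cand <- sample.int(nrow(cells), prob = w)
      }
      avail <- sum(cells$area_km2[cand])
      if (avail < target)
        stop(sprintf(
          "requested protected area %.1f km^2 exceeds the %.1f km^2 available %s",
          target, avail,
          if (scenario$name == "single_bin") "in the target bin" else "on land"))
      csum <- cumsum(cells$area_km2[cand])
      take <- cand[seq_len(which(csum >= target)[1])]
      n_pt <- if (scenario$point_fraction > 0)
        min(round(scenario$point_fraction * scenario$n_units), length(take)) else 0L
      pt_cells <- if (n_pt > 0) take[seq_len(n_pt)] else integer()
      poly_cells <- setdiff(take, pt_cells)
      # point records: circles inscribed well inside their cell
      for (cid in pt_cells) {
        i <- match(cid, cells$cell_id)
        r_km <- 0.35 * grid$res * KM_PER_DEG * min(1, cos(cells$lat[i] * pi / 180))
        a <- pi * r_km^2
        geoms[[length(geoms) + 1L]] <-
          list(lon = cells$lon[i], lat = cells$lat[i])  # raw point
        type <- c(type, "point"); extent <- c(extent, a)
        truth_prot[i] <- truth_prot[i] + a
      }
      n_poly_units <- max(scenario$n_units - n_pt, 1L)
      if (length(poly_cells)) {
        chunk <- as.integer(cut(seq_along(poly_cells),
                                min(n_poly_units, length(poly_cells))))
        for (k in sort(unique(chunk))) {
          ids <- poly_cells[chunk == k]
          rects <- lapply(ids, cell_rect, grid = grid)
          rings <- unlist(lapply(rects, `[[`, "rings"), recursive = FALSE)
          geoms[[length(geoms) + 1L]] <- geom_polygon(rings)
          type <- c(type, "polygon"); extent <- c(extent, NA_real_)
          truth_prot[match(ids, cells$cell_id)] <-
            truth_prot[match(ids, cells$cell_id)] +
            cells$area_km2[match(ids, cells$cell_id)]
        }
      }
    }
    n <- length(geoms)
    yrs <- as.integer(names(scenario$establishment_years))
    status_year <- pmin(sample(yrs, n, replace = TRUE,
                               prob = scenario$establishment_years) +
                          sample.int(10, n, replace = TRUE) - 1L, 2016L)
    category <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                       prob = c(0.15, 0.45, 0.15, 0.25))
    tab <- data.frame(unit_id = sprintf("PA%04d", seq_len(n)),
                      category = category, status_year = status_year,
                      reported_extent = extent, geom_type = type)
    # optional non-strict decoys on random cells (excluded from ground truth)
    n_ns <- round(scenario$nonstrict_fraction * scenario$n_units)
    if (n_ns > 0) {
      for (k in seq_len(n_ns)) {
        cid <- sample(cells$cell_id, 1)
        geoms[[length(geoms) + 1L]] <- cell_rect(grid, cid)
      }
      tab <- rbind(tab, data.frame(
        unit_id = sprintf("NS%04d", seq_len(n_ns)),
        category = sample(c("V", "VI", "Not Reported"), n_ns, replace = TRUE),
        status_year = sample(yrs, n_ns, replace = TRUE),
        reported_extent = NA_real_,
        geom_type = "polygon"))
    }
    rec <- .pa_records(tab, geoms, grid$crs)
    gt <- list(scenario = scenario,
               cell = data.frame(cell_id = cells$cell_id,
                                 protected_km2 = truth_prot),
               total_km2 = sum(truth_prot),
               target_km2 = target)
    if (!is.null(edges)) {
      gt$bin_edges <- edges
      b <- .assign_bins(cells[[scenario$target_variable]], edges)
      gt$per_bin_km2 <- vapply(seq_len(scenario$n_bins),
                               function(j) sum(truth_prot[b == j]), 0)
    }
    attr(rec, "ground_truth") <- gt
    rec
  })
}
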