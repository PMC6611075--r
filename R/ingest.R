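# Ingest rules for protected-area records: strict-category filtering, point
# buffering with the polygon-intersection exclusion rule, cumulative network
# dissolves per cutoff year, and raster-layer sampling onto the grid.

#' Filter records to strict protection categories
#'
#' Keeps exactly the records whose category is in `allowed` (IUCN I-IV by
#' default). An optional `recode` map is applied first, mirroring national
#' re-categorisations of "Not Reported" units. Records with a missing category
#' are excluded and counted, never silently dropped.
#'
#' @param records a `pa_records`
#' @param allowed character vector of retained categories
#' @param recode optional named character vector, `old -> new`
#' @return filtered `pa_records`; attribute `excluded` holds the counts
#'   (total, missing_category) and the excluded unit ids
#' @export
filter_strict_categories <- function(records, allowed = c("I", "II", "III", "IV"),
                                     recode = NULL) {
  stopifnot(inherits(records, "pa_records"))
  cat_ <- records$table$category
  if (!is.null(recode)) {
    hit <- cat_ %in% names(recode)
    cat_[hit] <- recode[cat_[hit]]
  }
  missing <- is.na(cat_) | !nzchar(trimws(as.character(cat_)))
  keep <- !missing & cat_ %in% allowed
  out <- .pa_records(records$table[keep, , drop = FALSE],
                     records$geometry[keep], records$crs)
  out$table$category <- cat_[keep]
  rownames(out$table) <- NULL
  attr(out, "excluded") <- list(
    n = sum(!keep), n_missing_category = sum(missing),
    unit_id = records$table$unit_id[!keep])
  attr(out, "ground_truth") <- attr(records, "ground_truth")
  out
}

#' Buffer point records into circles, excluding those that intersect polygons
#'
#' Each point becomes a circle of area equal to its reported extent (radius
#' sqrt(extent/pi), locally geodesic). A buffered circle intersecting any
#' existing protected-area *polygon* is discarded; circles overlapping only
#' each other are retained (the exclusion rule is applied against the polygon
#' set only).
#'
#' @param records a `pa_records` possibly mixing polygons and points
#' @return `pa_records` of polygons only; attribute `buffered` lists kept and
#'   excluded point unit ids
#' @export
buffer_points <- function(records) {
  stopifnot(inherits(records, "pa_records"))
  is_pt <- records$table$geom_type == "point"
  if (!any(is_pt)) {
    attr(records, "buffered") <- list(kept = character(), excluded = character())
    return(records)
  }
  ext <- records$table$reported_extent[is_pt]
  if (any(!is.finite(ext) | ext <= 0))
    stop("point records require reported_extent > 0; offending units: ",
         paste(records$table$unit_id[is_pt][!is.finite(ext) | ext <= 0],
               collapse = ", "))
  polys <- records$geometry[!is_pt]
  pb <- if (length(polys))
    vapply(polys, `[[`, numeric(4), "bbox") else NULL
  keep <- rep(TRUE, nrow(records$table))
  geoms <- records$geometry
  for (i in which(is_pt)) {
    p <- geoms[[i]]
    circ <- geom_circle_km(p$lon, p$lat, records$table$reported_extent[i])
    hit <- FALSE
    if (length(polys)) {
      near <- which(pb[1, ] < circ$bbox[3] & pb[3, ] > circ$bbox[1] &
                    pb[2, ] < circ$bbox[4] & pb[4, ] > circ$bbox[2])
      for (k in near) if (geoms_intersect(circ, polys[[k]])) { hit <- TRUE; break }
    }
    if (hit) keep[i] <- FALSE else geoms[[i]] <- circ
  }
  out <- .pa_records(records$table[keep, , drop = FALSE], geoms[keep],
                     records$crs)
  out$table$geom_type[out$table$geom_type == "point"] <- "polygon"
  rownames(out$table) <- NULL
  attr(out, "buffered") <- list(
    kept = records$table$unit_id[is_pt & keep],
    excluded = records$table$unit_id[is_pt & !keep])
  attr(out, "ground_truth") <- attr(records, "ground_truth")
  out
}

#' Dissolve the network into a cumulative snapshot at a cutoff year
#'
#' Unions all geometries with `status_year <= cutoff_year`; overlapping units
#' contribute area once. Records with a missing year are included in every
#' snapshot under the default policy (configurable to `"exclude"`).
#'
#' @param records filtered and buffered `pa_records` (polygons only)
#' @param cutoff_year calendar year
#' @param missing_year `"include"` (default) or `"exclude"`
#' @return an `eq_snapshot`: list(cutoff_year, geoms, area_km2, crs)
#' @export
dissolve_network <- function(records, cutoff_year,
                             missing_year = c("include", "exclude")) {
  stopifnot(inherits(records, "pa_records"))
  missing_year <- match.arg(missing_year)
  if (any(records$table$geom_type == "point"))
    stop("records contain unbuffered points; run buffer_points() first")
  yr <- records$table$status_year
  sel <- !is.na(yr) & yr <= cutoff_year
  if (missing_year == "include") sel <- sel | is.na(yr)
  geoms <- records$geometry[sel]
  structure(list(cutoff_year = cutoff_year, geoms = geoms,
                 area_km2 = geom_area(geoms), crs = records$crs),
            class = "eq_snapshot")
}

#' @export
print.eq_snapshot <- function(x, ...) {
  cat(sprintf("<eq_snapshot> cutoff %s: %d units, %.1f km^2\n",
              x$cutoff_year, length(x$geoms), x$area_km2))
  invisible(x)
}

#' Default per-variable raster aggregation semantics
#'
#' Mean for the climatic/topographic/edaphic layers, distance-to-frontiers and
#' cropland suitability; sum for population; minimum for distance-to-roads;
#' tourism attractiveness is the ratio of total photos to total population in
#' the cell.
#' @export
default_layer_agg <- function() {
  c(temperature = "mean", precipitation = "mean", elevation = "mean",
    slope = "mean", soil_fertility = "mean", dist_frontiers = "mean",
    cropland_suitability = "mean", population = "sum", dist_roads = "min",
    tourism = "ratio_photos_population")
}

#' Sample raster layers onto the grid
#'
#' @param rasters named list of `eq_raster` objects (see [read_ascii_grid()]);
#'   the tourism ratio additionally requires a `photos` raster
#' @param grid an `eq_grid`
#' @param agg named character vector of aggregation rules (see
#'   [default_layer_agg()]); unnamed layers default to `"mean"`
#' @return the grid with sampled value columns added to `cells`; cells where a
#'   layer has no finite pixel get `NA` for that layer
#' @export
sample_layers <- function(rasters, grid, agg = default_layer_agg()) {
  stopifnot(inherits(grid, "eq_grid"))
  cell_of <- function(r) {
    px <- r$lon0 + (rep(seq_len(r$nx), times = r$ny) - 0.5) * r$res
    py <- r$lat0 + (rep(seq_len(r$ny), each = r$nx) - 0.5) * r$res
    cx <- floor((px - grid$lon0) / grid$res) + 1
    cy <- floor((py - grid$lat0) / grid$res) + 1
    ok <- cx >= 1 & cx <= grid$nx & cy >= 1 & cy <= grid$ny
    list(idx = (cy - 1) * grid$nx + cx, ok = ok,
         val = as.vector(t(r$data))) # data stored [row, col], row 1 = south
  }
  agg_one <- function(r, how) {
    if (r$res > grid$res + 1e-12 && how == "mean")
      stop("raster resolution exceeds grid resolution for a mean-sampled layer")
    m <- cell_of(r)
    ok <- m$ok & is.finite(m$val)
    f <- switch(how, mean = mean, sum = sum, min = min,
                stop("unknown aggregation: ", how))
    out <- rep(NA_real_, grid$nx * grid$ny)
    if (any(ok)) {
      v <- tapply(m$val[ok], m$idx[ok], f)
      out[as.integer(names(v))] <- as.vector(v)
    }
    out
  }
  for (nm in setdiff(names(rasters), "photos")) {
    how <- if (nm %in% names(agg)) agg[[nm]] else "mean"
    if (how == "ratio_photos_population") {
      if (is.null(rasters$photos))
        stop("tourism ratio requires a 'photos' raster")
      ph <- agg_one(rasters$photos, "sum")
      po <- agg_one(rasters[[if (!is.null(rasters$population)) "population" else nm]], "sum")
      grid$cells[[nm]] <- ifelse(po > 0, ph / po, NA_real_)
    } else {
      grid$cells[[nm]] <- agg_one(rasters[[nm]], how)
    }
  }
  grid
}

#' Build the canonical per-cell analysis table
#'
#' Runs the dissolve-and-grid pipeline for every cutoff period and assembles
#' one row per cell x territory x period with geodesic land area, protected
#' km^2 and all layer values. This table is the input of every downstream
#' module.
#'
#' @param grid an `eq_grid` carrying layer values and (if `territories` is
#'   `NULL`) a `territory_id` column
#' @param records filtered, buffered `pa_records`
#' @param periods cutoff years (default `c(1960, 1970, ..., 2010, 2016)`)
#' @param territories optional named list of territory polygons
#' @param missing_year policy passed to [dissolve_network()]
#' @return data frame of class `eq_cells`
#' @export
build_cell_table <- function(grid, records,
                             periods = c(seq(1960, 2010, 10), 2016),
                             territories = NULL,
                             missing_year = "include") {
  stopifnot(inherits(grid, "eq_grid"))
  vars <- intersect(c(PHYSICAL_VARS, HUMAN_VARS), names(grid$cells))
  base_cols <- c("cell_id", "lon", "lat", "area_km2", "land_frac",
                 intersect(c("territory_id", "ecoregion_id"), names(grid$cells)),
                 vars)
  out <- vector("list", length(periods))
  for (p in seq_along(periods)) {
    snap <- dissolve_network(records, periods[p], missing_year)
    gp <- grid_protection(snap, grid, territories)
    tab <- grid$cells[, base_cols]
    # histogram weights use land area only (partial-sea cells count their
    # land share); synthetic grids have land_frac = 1 throughout
    tab$area_km2 <- tab$area_km2 * tab$land_frac
    if (is.null(territories)) {
      tab$protected_km2 <- 0
      m <- match(gp$cell_id, tab$cell_id)
      tab$protected_km2[m] <- gp$protected_km2
    } else {
      # one row per cell x territory piece; piece land area from the territory
      # polygon itself so split cells weight each country's own share
      tab <- do.call(rbind, lapply(names(territories), function(tid) {
        tt <- tab
        tt$territory_id <- tid
        frac <- .territory_cell_fractions(grid, territories[[tid]])
        tt$area_km2 <- tt$area_km2 * frac
        tt[frac > 1e-12, , drop = FALSE]
      }))
      key <- paste(tab$cell_id, tab$territory_id)
      tab$protected_km2 <- 0
      m <- match(paste(gp$cell_id, gp$territory_id), key)
      tab$protected_km2[m] <- gp$protected_km2
    }
    tab$protected_km2 <- pmin(tab$protected_km2, tab$area_km2)
    tab$period <- periods[p]
    out[[p]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "periods") <- periods
  attr(res, "variables") <- vars
  class(res) <- c("eq_cells", "data.frame")
  res
}

# fraction of each cell's area inside a territory polygon (scanline)
.territory_cell_fractions <- function(grid, terr_geom) {
  snap <- structure(list(cutoff_year = NA, geoms = list(terr_geom),
                         area_km2 = NA, crs = grid$crs), class = "eq_snapshot")
  g2 <- grid
  g2$cells$territory_id <- "all"
  gp <- grid_protection(snap, g2)
  frac <- numeric(grid$nx * grid$ny)
  frac[gp$cell_id] <- gp$protected_km2 / grid$cells$area_km2[gp$cell_id]
  pmin(frac, 1)
}
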