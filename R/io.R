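# Plain-text I/O: GeoJSON for vector protected areas and territory polygons,
# ESRI ASCII grids (.asc) for rasters, CSV for the canonical cell table.
# Ellipses (buffered points) are polygonised with 64 vertices on write.

.geom_to_geojson <- function(g) {
  if (inherits(g, "eq_geom") && g$type == "ellipse") {
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    g <- geom_polygon(cbind(g$cx + g$rx * cos(th), g$cy + g$ry * sin(th)))
  }
  if (is.list(g) && !inherits(g, "eq_geom") && !is.null(g$lon))
    return(list(type = "Point", coordinates = c(g$lon, g$lat)))
  close_ring <- function(r) rbind(r, r[1, , drop = FALSE])
  rings <- lapply(g$rings, function(r) unname(close_ring(as.matrix(r))))
  if (length(rings) == 1L)
    list(type = "Polygon", coordinates = rings)
  else
    list(type = "MultiPolygon", coordinates = lapply(rings, list))
}

.geojson_to_geom <- function(gj) {
  switch(gj$type,
    Point = list(lon = gj$coordinates[[1]], lat = gj$coordinates[[2]]),
    Polygon = geom_polygon(lapply(gj$coordinates, function(r)
      do.call(rbind, lapply(r, unlist)))),
    MultiPolygon = geom_polygon(unlist(lapply(gj$coordinates, function(pp)
      lapply(pp, function(r) do.call(rbind, lapply(r, unlist)))),
      recursive = FALSE)),
    stop("unsupported GeoJSON geometry: ", gj$type))
}

#' Write protected-area records (or named territory polygons) as GeoJSON
#' @param x a `pa_records`, or a named list of `eq_geom`
#' @param path output file
#' @export
write_geojson <- function(x, path) {
  feats <- if (inherits(x, "pa_records")) {
    lapply(seq_len(nrow(x$table)), function(i) {
      pr <- as.list(x$table[i, , drop = FALSE])
      pr$geom_type <- NULL
      list(type = "Feature", properties = pr,
           geometry = .geom_to_geojson(x$geometry[[i]]))
    })
  } else {
    lapply(names(x), function(nm)
      list(type = "Feature", properties = list(id = nm),
           geometry = .geom_to_geojson(x[[nm]])))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read protected-area records from GeoJSON
#'
#' Expects Feature properties `unit_id`, `category`, `status_year` and (for
#' points) `reported_extent`.
#' @param path GeoJSON file
#' @param crs coordinate reference tag to attach (default WGS84)
#' @return a `pa_records`
#' @export
read_pa_geojson <- function(path, crs = "EPSG:4326") {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  n <- length(gj$features)
  getp <- function(f, nm, default = NA) {
    v <- f$properties[[nm]]
    if (is.null(v)) default else v
  }
  geoms <- lapply(gj$features, function(f) .geojson_to_geom(f$geometry))
  tab <- data.frame(
    unit_id = vapply(gj$features, getp, "", nm = "unit_id", default = NA_character_),
    category = vapply(gj$features, function(f)
      as.character(getp(f, "category", NA_character_)), ""),
    status_year = vapply(gj$features, function(f)
      as.integer(getp(f, "status_year", NA_integer_)), 0L),
    reported_extent = vapply(gj$features, function(f)
      as.numeric(getp(f, "reported_extent", NA_real_)), 0),
    geom_type = vapply(gj$features, function(f)
      if (f$geometry$type == "Point") "point" else "polygon", ""))
  .pa_records(tab, geoms, crs)
}

#' Read territory/ecoregion polygons from GeoJSON as a named geometry list
#' @param path GeoJSON file; features need an `id` (or `territory_id`) property
#' @export
read_zones_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  out <- lapply(gj$features, function(f) .geojson_to_geom(f$geometry))
  names(out) <- vapply(gj$features, function(f) {
    id <- f$properties$id
    if (is.null(id)) id <- f$properties$territory_id
    as.character(id)
  }, "")
  out
}

#' Read an ESRI ASCII grid (.asc) raster
#' @param path .asc file
#' @return an `eq_raster`: list(data (row 1 = southmost), lon0, lat0, nx, ny,
#'   res)
#' @export
read_ascii_grid <- function(path) {
  hdr <- list()
  lines <- readLines(path, n = 6)
  for (l in lines) {
    kv <- strsplit(trimws(l), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  dat <- as.matrix(utils::read.table(path, skip = 6))
  if (!is.null(hdr$nodata_value)) dat[dat == hdr$nodata_value] <- NA
  # .asc rows run north -> south; flip so row 1 is the southmost row
  dat <- dat[rev(seq_len(nrow(dat))), , drop = FALSE]
  dimnames(dat) <- NULL
  list(data = dat, lon0 = hdr$xllcorner, lat0 = hdr$yllcorner,
       nx = as.integer(hdr$ncols), ny = as.integer(hdr$nrows),
       res = hdr$cellsize)
}

#' Write an ESRI ASCII grid (.asc) raster
#' @param r an `eq_raster` (see [read_ascii_grid()])
#' @param path output file
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", r$nx), paste("nrows", r$ny),
    paste("xllcorner", r$lon0), paste("yllcorner", r$lat0),
    paste("cellsize", r$res), "NODATA_value -9999"), con)
  d <- r$data
  d[!is.finite(d)] <- -9999
  utils::write.table(d[rev(seq_len(nrow(d))), , drop = FALSE], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Grid cell values as an `eq_raster` layer
#' @param grid an `eq_grid`; @param column cell column to rasterise
#' @export
grid_to_raster <- function(grid, column) {
  v <- grid$cells[[column]][order(grid$cells$cell_id)]
  list(data = matrix(v, grid$ny, grid$nx, byrow = TRUE),
       lon0 = grid$lon0, lat0 = grid$lat0, nx = grid$nx, ny = grid$ny,
       res = grid$res)
}

#' Write the canonical per-cell table as CSV
#' @param cell_table an `eq_cells` data frame
#' @param path output file
#' @export
write_cell_table <- function(cell_table, path) {
  utils::write.csv(cell_table, path, row.names = FALSE)
  invisible(path)
}

#' Read a cell table written by [write_cell_table()]
#' @param path CSV file
#' @export
read_cell_table <- function(path) {
  res <- utils::read.csv(path)
  attr(res, "periods") <- sort(unique(res$period))
  attr(res, "variables") <- intersect(c(PHYSICAL_VARS, HUMAN_VARS), names(res))
  class(res) <- c("eq_cells", "data.frame")
  res
}
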