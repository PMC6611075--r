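# The analysis grid: a regular 0.1-degree (by default) lon/lat lattice whose
# cells carry geodesic areas, territory/ecoregion assignment and layer values.
# It is the sampling backbone for every downstream statistic.

#' Create an analysis grid
#'
#' @param lon0,lat0 lower-left corner of the extent (degrees)
#' @param nx,ny number of cells along longitude / latitude
#' @param res cell edge in degrees (default 0.1)
#' @param crs coordinate reference tag (records must match)
#' @return an object of class `eq_grid` with a `cells` data frame
#'   (cell_id, col, row, lon, lat centre coordinates, area_km2, land_frac)
#' @export
analysis_grid <- function(lon0, lat0, nx, ny, res = 0.1, crs = "EPSG:4326") {
  stopifnot(res > 0, nx >= 1, ny >= 1)
  col <- rep(seq_len(nx), times = ny)
  row <- rep(seq_len(ny), each = nx)
  lat_lo <- lat0 + (row - 1) * res
  cells <- data.frame(
    cell_id = seq_len(nx * ny),
    col = col, row = row,
    lon = lon0 + (col - 0.5) * res,
    lat = lat_lo + res / 2,
    area_km2 = geodesic_cell_area(lat_lo, lat_lo + res, res),
    land_frac = 1
  )
  structure(list(lon0 = lon0, lat0 = lat0, nx = nx, ny = ny, res = res,
                 crs = crs, cells = cells),
            class = "eq_grid")
}

#' @export
print.eq_grid <- function(x, ...) {
  cat(sprintf("<eq_grid> %d x %d cells of %g deg, origin (%g, %g), %s\n",
              x$nx, x$ny, x$res, x$lon0, x$lat0, x$crs))
  extra <- setdiff(names(x$cells),
                   c("cell_id", "col", "row", "lon", "lat", "area_km2", "land_frac"))
  if (length(extra)) cat(" layers:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Rectangle geometry of one grid cell
#' @param grid an `eq_grid`; @param cell_id cell index
#' @keywords internal
cell_rect <- function(grid, cell_id) {
  col <- (cell_id - 1L) %% grid$nx + 1L
  row <- (cell_id - 1L) %/% grid$nx + 1L
  geom_rect(grid$lon0 + (col - 1) * grid$res, grid$lat0 + (row - 1) * grid$res,
            grid$lon0 + col * grid$res, grid$lat0 + row * grid$res)
}

# distribute x-intervals `m` (2-col) to grid columns; returns list(col, len)
.split_by_columns <- function(m, lon0, res, nx) {
  a <- m[, 1]; b <- m[, 2]
  # snap endpoints sitting on cell boundaries (within 1e-9 cell) so aligned
  # geometry does not leak slivers into the neighbouring column
  ca <- pmin(pmax(floor((a - lon0) / res + 1e-9) + 1L, 1L), nx)
  cb <- pmin(pmax(ceiling((b - lon0) / res - 1e-9), ca), nx)
  one <- ca == cb
  cols <- ca[one]; lens <- (b - a)[one]
  for (i in which(!one)) {
    cc <- ca[i]:cb[i]
    lo <- pmax(lon0 + (cc - 1) * res, a[i])
    hi <- pmin(lon0 + cc * res, b[i])
    keep <- hi > lo
    cols <- c(cols, cc[keep]); lens <- c(lens, (hi - lo)[keep])
  }
  list(col = cols, len = lens)
}

#' Grid a dissolved protection snapshot to per-cell, per-territory areas
#'
#' Intersects the dissolved protection geometry with every grid cell and
#' territory, returning protected km^2 with the cos(lat) geodesic weighting.
#' In cells shared by two or more territories each territory sees only its own
#' share. Territories are either cell-aligned (a `territory_id` column on the
#' grid cells) or arbitrary polygons.
#'
#' @param snapshot an `eq_snapshot` from [dissolve_network()]
#' @param grid an `eq_grid`
#' @param territories `NULL` to use `grid$cells$territory_id`, or a named list
#'   of `eq_geom` territory polygons
#' @return data frame (cell_id, territory_id, protected_km2) for cells with
#'   nonzero protection; attribute `total_km2` holds the grand total
#' @export
grid_protection <- function(snapshot, grid, territories = NULL) {
  stopifnot(inherits(snapshot, "eq_snapshot"), inherits(grid, "eq_grid"))
  if (!identical(snapshot$crs, grid$crs))
    stop("CRS mismatch: snapshot is ", snapshot$crs, ", grid is ", grid$crs,
         " (no silent reprojection)")
  geoms <- snapshot$geoms
  cell_terr <- is.null(territories)
  if (cell_terr && is.null(grid$cells$territory_id))
    stop("grid has no territory_id column and no territory polygons supplied")
  terr_ids <- if (cell_terr) sort(unique(grid$cells$territory_id))
              else names(territories)
  nt <- length(terr_ids)
  acc <- matrix(0, nrow = grid$nx * grid$ny, ncol = nt,
                dimnames = list(NULL, terr_ids))
  if (length(geoms) == 0L) {
    out <- data.frame(cell_id = integer(), territory_id = character(),
                      protected_km2 = numeric())
    attr(out, "total_km2") <- 0
    return(out)
  }
  gb <- vapply(geoms, `[[`, numeric(4), "bbox")
  xlim <- c(grid$lon0, grid$lon0 + grid$nx * grid$res)
  # per-row cell-aligned territory runs
  if (cell_terr) {
    tid_mat <- matrix(grid$cells$territory_id[order(grid$cells$cell_id)],
                      nrow = grid$nx)  # col x row
  }
  for (r in seq_len(grid$ny)) {
    ylo <- grid$lat0 + (r - 1) * grid$res; yhi <- ylo + grid$res
    act <- which(gb[2, ] < yhi & gb[4, ] > ylo)
    if (!length(act)) next
    ag <- geoms[act]
    nd <- .scan_nodes(ylo, yhi, unlist(lapply(ag, .geom_ybreaks)))
    if (cell_terr) {
      rl <- rle(as.vector(tid_mat[, r]))
      run_hi <- cumsum(rl$lengths)
      runs <- cbind(grid$lon0 + (run_hi - rl$lengths) * grid$res,
                    grid$lon0 + run_hi * grid$res)
      run_tid <- match(rl$values, terr_ids)
    }
    row_off <- (r - 1L) * grid$nx
    for (i in seq_along(nd$y)) {
      y <- nd$y[i]
      u <- .union_x_at(ag, y, xlim)
      if (is.null(u)) next
      wgt <- nd$w[i] * cos(y * pi / 180) * KM_PER_DEG^2
      if (cell_terr) {
        for (k in seq_len(nrow(runs))) {
          v <- .intersect_intervals(u, runs[k, , drop = FALSE])
          if (is.null(v)) next
          sp <- .split_by_columns(v, grid$lon0, grid$res, grid$nx)
          idx <- row_off + sp$col
          acc[cbind(idx, run_tid[k])] <- acc[cbind(idx, run_tid[k])] + sp$len * wgt
        }
      } else {
        for (k in seq_len(nt)) {
          tu <- .union_x_at(list(territories[[k]]), y)
          v <- .intersect_intervals(u, tu)
          if (is.null(v)) next
          sp <- .split_by_columns(v, grid$lon0, grid$res, grid$nx)
          idx <- row_off + sp$col
          acc[cbind(idx, k)] <- acc[cbind(idx, k)] + sp$len * wgt
        }
      }
    }
  }
  nz <- which(acc > 1e-9, arr.ind = TRUE)  # drop sub-m^2 quadrature noise
  out <- data.frame(cell_id = as.integer(nz[, 1]),
                    territory_id = terr_ids[nz[, 2]],
                    protected_km2 = acc[nz])
  out <- out[order(out$cell_id, out$territory_id), ]
  rownames(out) <- NULL
  attr(out, "total_km2") <- sum(acc)
  out
}
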