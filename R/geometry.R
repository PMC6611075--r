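# Planar lon/lat geometry on the WGS84 graticule with an authalic-sphere area
# approximation. All areas are computed by latitude scanlines: at a fixed
# latitude y the union of a geometry set is a union of longitude intervals,
# whose total length L(y) (degrees) is exact; areas follow from
#   A = K^2 * integral L(y) cos(y) dy,   K = km per degree on the sphere.
# The integral is evaluated with Gauss-Legendre quadrature between "breaks"
# (polygon vertex latitudes, ellipse extrema plus refinement knots), so
# piecewise-linear interval bounds (polygons) integrate exactly and the
# sqrt-shaped ellipse bounds to ~1e-6 relative error.

#' Kilometres per degree of arc on the authalic sphere (R = 6371.0088 km)
#' @keywords internal
KM_PER_DEG <- pi * 6371.0088 / 180

# 6-point Gauss-Legendre nodes/weights on [-1, 1]
.GL_X <- c(-0.9324695142031521, -0.6612093864662645, -0.2386191860831969,
           0.2386191860831969, 0.6612093864662645, 0.9324695142031521)
.GL_W <- c(0.1713244923791704, 0.3607615730481386, 0.4679139345726910,
           0.4679139345726910, 0.3607615730481386, 0.1713244923791704)

# latitude knots refining ellipse quadrature pieces (fraction of ry from centre;
# clustered toward the poles of the ellipse where the chord varies like sqrt)
.ELL_KNOTS <- c(-0.998, -0.98, -0.92, -0.8, -0.6, -0.3,
                0, 0.3, 0.6, 0.8, 0.92, 0.98, 0.998)

#' Construct a polygon geometry
#'
#' Rings are 2-column (lon, lat) matrices; multiple rings are interpreted with
#' the even-odd rule, so holes and multi-part polygons are both supported.
#'
#' @param rings a 2-column matrix or a list of 2-column matrices (degrees)
#' @return an object of class `eq_geom`
#' @export
geom_polygon <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  stopifnot(length(rings) >= 1L, all(vapply(rings, ncol, 0L) == 2L))
  # edge table over all rings (wrapping each ring)
  e <- do.call(rbind, lapply(rings, function(r) {
    r <- unname(as.matrix(r))
    if (nrow(r) >= 2L && all(r[1L, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3L) stop("polygon ring needs >= 3 distinct vertices")
    nxt <- c(seq_len(nrow(r))[-1L], 1L)
    cbind(r, r[nxt, , drop = FALSE])
  }))
  structure(list(type = "polygon", rings = rings,
                 edges = e,  # x1 y1 x2 y2
                 bbox = c(min(e[, 1]), min(e[, 2]), max(e[, 1]), max(e[, 2]))),
            class = "eq_geom")
}

#' Construct an axis-aligned rectangle geometry
#' @param x0,y0,x1,y1 corners in degrees
#' @export
geom_rect <- function(x0, y0, x1, y1) {
  geom_polygon(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)))
}

#' Construct an ellipse geometry (axis-aligned, degrees)
#' @param cx,cy centre; @param rx,ry semi-axes in degrees
#' @export
geom_ellipse <- function(cx, cy, rx, ry) {
  stopifnot(rx > 0, ry > 0)
  structure(list(type = "ellipse", cx = cx, cy = cy, rx = rx, ry = ry,
                 bbox = c(cx - rx, cy - ry, cx + rx, cy + ry)),
            class = "eq_geom")
}

#' Circle of a given area centred at a lon/lat point
#'
#' The circle is constructed in local kilometre coordinates (radius
#' `sqrt(area/pi)`) and mapped to degrees, which yields an ellipse in lon/lat
#' whose geodesic area equals `area_km2` under the cos(lat) approximation.
#'
#' @param lon,lat centre in degrees
#' @param area_km2 target area (km^2), must be positive
#' @export
geom_circle_km <- function(lon, lat, area_km2) {
  if (!is.finite(area_km2) || area_km2 <= 0)
    stop("circle area must be positive, got ", area_km2)
  r_km <- sqrt(area_km2 / pi)
  geom_ellipse(lon, lat, r_km / (KM_PER_DEG * cos(lat * pi / 180)),
               r_km / KM_PER_DEG)
}

# ---- scanline primitives ----------------------------------------------------

# x-intervals of one geometry at latitude y: 2-col matrix (start, end)
.geom_xints <- function(g, y) {
  if (y <= g$bbox[2] || y >= g$bbox[4]) return(NULL)
  if (g$type == "ellipse") {
    t <- (y - g$cy) / g$ry
    dx <- g$rx * sqrt(max(0, 1 - t * t))
    if (dx <= 0) return(NULL)
    return(cbind(g$cx - dx, g$cx + dx))
  }
  e <- g$edges
  hit <- (e[, 2] <= y & e[, 4] > y) | (e[, 4] <= y & e[, 2] > y)
  if (!any(hit)) return(NULL)
  e <- e[hit, , drop = FALSE]
  x <- e[, 1] + (y - e[, 2]) * (e[, 3] - e[, 1]) / (e[, 4] - e[, 2])
  x <- sort(x)
  if (length(x) %% 2L == 1L) x <- x[-length(x)]  # numerical guard
  matrix(x, ncol = 2L, byrow = TRUE)
}

# merge a 2-col interval matrix into a disjoint union
.union_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(NULL)
  m <- m[order(m[, 1]), , drop = FALSE]
  s <- m[, 1]; e <- m[, 2]
  keep_start <- c(TRUE, s[-1L] > cummax(e[-length(e)]))
  grp <- cumsum(keep_start)
  cbind(tapply(s, grp, min)[unique(grp)], tapply(e, grp, max)[unique(grp)],
        deparse.level = 0)
}

# intersection of two disjoint-interval sets (2-col matrices, sorted)
.intersect_intervals <- function(a, b) {
  if (is.null(a) || is.null(b) || nrow(a) == 0L || nrow(b) == 0L) return(NULL)
  out <- vector("list", nrow(b))
  for (k in seq_len(nrow(b))) {
    lo <- pmax(a[, 1], b[k, 1]); hi <- pmin(a[, 2], b[k, 2])
    ok <- hi > lo
    if (any(ok)) out[[k]] <- cbind(lo[ok], hi[ok])
  }
  m <- do.call(rbind, out)
  if (is.null(m) || nrow(m) == 0L) NULL else m[order(m[, 1]), , drop = FALSE]
}

# union-of-geoms x-intervals at latitude y, clipped to xlim
.union_x_at <- function(geoms, y, xlim = NULL) {
  ints <- do.call(rbind, lapply(geoms, .geom_xints, y = y))
  u <- .union_intervals(ints)
  if (is.null(u)) return(NULL)
  if (!is.null(xlim)) {
    u[, 1] <- pmax(u[, 1], xlim[1]); u[, 2] <- pmin(u[, 2], xlim[2])
    u <- u[u[, 2] > u[, 1], , drop = FALSE]
    if (nrow(u) == 0L) return(NULL)
  }
  u
}

# latitude breakpoints of one geometry (including ellipse refinement knots)
.geom_ybreaks <- function(g) {
  if (g$type == "ellipse") g$cy + g$ry * .ELL_KNOTS else unique(g$edges[, 2])
}

# Gauss-Legendre nodes/weights over pieces of [ylo, yhi] split at `breaks`;
# pieces narrower than ~1e-9 degrees are floating-point slivers (e.g., a ring
# edge one ulp away from a row bound) and are dropped so that geometry aligned
# on cell boundaries contributes exact zeros to its neighbours
.scan_nodes <- function(ylo, yhi, breaks) {
  b <- sort(unique(c(ylo, yhi, breaks[breaks > ylo & breaks < yhi])))
  lo <- b[-length(b)]; hi <- b[-1L]
  ok <- (hi - lo) > 1e-9
  lo <- lo[ok]; hi <- hi[ok]
  mid <- (lo + hi) / 2; half <- (hi - lo) / 2
  list(y = as.vector(outer(.GL_X, mid, function(x, m) m) +
                       outer(.GL_X, half, `*`)),
       w = as.vector(outer(.GL_W, half, `*`)))
}

# ---- public area operations -------------------------------------------------

#' Union area of a geometry set (km^2)
#'
#' Computes the area of the union of `geoms`, optionally intersected with the
#' union of `clip`, by latitude scanline integration with cos(lat) geodesic
#' weighting. Overlapping geometries are counted once.
#'
#' @param geoms a list of `eq_geom` (or a single one)
#' @param clip optional list of `eq_geom` to intersect with
#' @return area in km^2
#' @export
geom_area <- function(geoms, clip = NULL) {
  if (inherits(geoms, "eq_geom")) geoms <- list(geoms)
  if (length(geoms) == 0L) return(0)
  if (!is.null(clip) && inherits(clip, "eq_geom")) clip <- list(clip)
  bb <- vapply(geoms, `[[`, numeric(4), "bbox")
  ylo <- min(bb[2, ]); yhi <- max(bb[4, ])
  if (!is.null(clip)) {
    cb <- vapply(clip, `[[`, numeric(4), "bbox")
    ylo <- max(ylo, min(cb[2, ])); yhi <- min(yhi, max(cb[4, ]))
    if (yhi <= ylo) return(0)
  }
  breaks <- unlist(lapply(c(geoms, clip), .geom_ybreaks))
  nd <- .scan_nodes(ylo, yhi, breaks)
  tot <- 0
  for (i in seq_along(nd$y)) {
    y <- nd$y[i]
    u <- .union_x_at(geoms, y)
    if (is.null(u)) next
    if (!is.null(clip)) {
      cu <- .union_x_at(clip, y)
      u <- .intersect_intervals(u, cu)
      if (is.null(u)) next
    }
    tot <- tot + nd$w[i] * sum(u[, 2] - u[, 1]) * cos(y * pi / 180)
  }
  tot * KM_PER_DEG^2
}

#' Do two geometry sets intersect with positive area?
#' @param a,b lists of `eq_geom` (or single geometries)
#' @param tol area tolerance in km^2 below which overlap is ignored
#' @export
geoms_intersect <- function(a, b, tol = 1e-9) {
  geom_area(a, clip = b) > tol
}

#' Exact geodesic area of a graticule-aligned cell (km^2)
#' @param lat_lo,lat_hi cell latitude bounds (degrees)
#' @param dlon cell width in degrees of longitude
#' @export
geodesic_cell_area <- function(lat_lo, lat_hi, dlon) {
  KM_PER_DEG^2 * dlon * (180 / pi) *
    (sin(lat_hi * pi / 180) - sin(lat_lo * pi / 180))
}
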