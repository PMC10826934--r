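# Planar geometry on small (building- to county-scale) polygons.
# Polygons are unclosed two-column lon/lat matrices in WGS84; metric work
# happens in a local azimuthal-equidistant frame (distance + bearing from a
# center point), which is exact for distances from the center and has
# negligible distortion at the sub-kilometre scales buffered here.

EARTH_RADIUS_M <- 6371008.8  # IUGG mean Earth radius

#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd ray casting with an explicit on-edge check, so points lying on
#' a polygon edge or vertex count as inside. Coordinates are treated as
#' planar, which is adequate for the building- and region-scale polygons
#' used here.
#'
#' @param lon,lat numeric vectors of point coordinates.
#' @param polygon unclosed two-column `lon`/`lat` matrix.
#' @param eps tolerance (degrees) for the on-edge test.
#' @return logical vector.
#' @export
point_in_polygon <- function(lon, lat, polygon, eps = 1e-12) {
  px <- polygon[, 1]; py <- polygon[, 2]
  n <- length(px)
  inside <- rep(FALSE, length(lon))
  on_edge <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    # on-segment: collinear within eps and inside bounding box
    cross <- (xj - xi) * (lat - yi) - (yj - yi) * (lon - xi)
    seg_len2 <- (xj - xi)^2 + (yj - yi)^2
    col_ok <- abs(cross) <= eps * max(1, sqrt(seg_len2))
    bb_ok <- lon >= pmin(xi, xj) - eps & lon <= pmax(xi, xj) + eps &
      lat >= pmin(yi, yj) - eps & lat <= pmax(yi, yj) + eps
    on_edge <- on_edge | (col_ok & bb_ok)
    # ray casting (half-open vertex rule avoids double counting)
    crosses <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

# spherical initial bearing (degrees) from p1 to each point of p2;
# consistent with the spherical haversine/destination formulas
sphere_bearing <- function(p1, lon, lat) {
  to_rad <- pi / 180
  phi1 <- p1[2] * to_rad; phi2 <- lat * to_rad
  dlam <- (lon - p1[1]) * to_rad
  atan2(sin(dlam) * cos(phi2),
        cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)) / to_rad
}

# Project lon/lat to metres in an azimuthal-equidistant frame centered at
# `center` (lon, lat): x east, y north.
project_local <- function(lon, lat, center) {
  p <- cbind(lon, lat)
  d <- geosphere::distHaversine(center, p, r = EARTH_RADIUS_M)
  az <- sphere_bearing(center, lon, lat)
  az[is.na(az)] <- 0  # point coincides with center
  rad <- az * pi / 180
  cbind(x = d * sin(rad), y = d * cos(rad))
}

# Inverse of project_local.
unproject_local <- function(xy, center) {
  d <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  az <- atan2(xy[, 1], xy[, 2]) * 180 / pi
  out <- geosphere::destPoint(center, az, d, r = EARTH_RADIUS_M)
  out[d == 0, 1] <- center[1]
  out[d == 0, 2] <- center[2]
  colnames(out) <- c("lon", "lat")
  out
}

# Planar shoelace area; positive for counter-clockwise rings.
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Polygon area in square metres
#'
#' Area of a lon/lat polygon computed by the shoelace formula in a local
#' azimuthal-equidistant frame centered on the polygon's vertex centroid.
#'
#' @param polygon unclosed two-column `lon`/`lat` matrix.
#' @return area in m^2 (non-negative).
#' @export
polygon_area_m2 <- function(polygon) {
  center <- colMeans(polygon[, 1:2, drop = FALSE])
  abs(shoelace_area(project_local(polygon[, 1], polygon[, 2], center)))
}

#' Buffer a polygon outward by a metric distance
#'
#' Computes the Minkowski sum of the polygon's convex hull with a disc of
#' radius `distance_m`, in a local azimuthal-equidistant frame centered on
#' the polygon centroid, then reprojects to WGS84. Exact (up to the
#' circular-arc discretization) for convex polygons; non-convex footprints
#' are buffered via their convex hull. `distance_m = 0` returns the
#' footprint unchanged.
#'
#' @param polygon unclosed two-column `lon`/`lat` matrix with >= 3 vertices.
#' @param distance_m outward buffer distance in metres (>= 0).
#' @param n_arc number of discretization points per full circle (default 72).
#' @return unclosed two-column `lon`/`lat` matrix containing `polygon`.
#' @export
buffer_polygon <- function(polygon, distance_m, n_arc = 72) {
  if (!is.matrix(polygon) || nrow(polygon) < 3) {
    stop("polygon must be a matrix with at least 3 vertices", call. = FALSE)
  }
  if (anyNA(polygon)) stop("polygon has missing coordinates", call. = FALSE)
  if (distance_m < 0) stop("distance_m must be >= 0", call. = FALSE)
  if (distance_m == 0) return(polygon)
  center <- colMeans(polygon[, 1:2, drop = FALSE])
  xy <- project_local(polygon[, 1], polygon[, 2], center)
  theta <- seq(0, 2 * pi, length.out = n_arc + 1)[-(n_arc + 1)]
  ring <- cbind(distance_m * cos(theta), distance_m * sin(theta))
  # all vertex-translates of the disc, then the convex hull
  pts <- cbind(rep(xy[, 1], each = n_arc) + ring[, 1],
               rep(xy[, 2], each = n_arc) + ring[, 2])
  hull <- grDevices::chull(pts)
  unproject_local(pts[hull, , drop = FALSE], center)
}

# axis-aligned rectangle polygon (lon/lat), helper shared by synth and tests
rect_polygon <- function(lon_min, lat_min, lon_max, lat_max) {
  cbind(lon = c(lon_min, lon_max, lon_max, lon_min),
        lat = c(lat_min, lat_min, lat_max, lat_max))
}
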