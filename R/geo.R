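# Spherical geometry and polygon primitives. Distances use the mean Earth
# radius 6,371,000 m; at city scale the relative error vs an ellipsoid is
# far below the metre precision reported anywhere in this pipeline.

EARTH_RADIUS_M <- 6371000

#' Great-circle (haversine) distance in metres
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84,
#'   lon/lat order). Vectorized and recycled.
#' @return Distance(s) in metres on a sphere of radius 6,371,000 m.
#' @export
#' @examples
#' haversine_distance_m(0, 0, 0, 1) # one degree of latitude, ~111.2 km
haversine_distance_m <- function(lon1, lat1, lon2, lat2) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dp <- (lat2 - lat1) * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

#' Initial great-circle bearing in degrees
#'
#' The compass direction, clockwise from true north in \[0, 360), of the
#' great-circle path from the first point towards the second at its start.
#'
#' @param lon1,lat1 Origin in decimal degrees.
#' @param lon2,lat2 Destination in decimal degrees; must differ from the
#'   origin (the bearing between coincident points is undefined).
#' @return Bearing(s) in degrees in \[0, 360).
#' @export
initial_bearing_deg <- function(lon1, lat1, lon2, lat2) {
  if (any(lon1 == lon2 & lat1 == lat2)) {
    rlang::abort("bearing undefined for coincident points")
  }
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  y <- sin(dl) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
  (atan2(y, x) * 180 / pi) %% 360
}

# ---- polygons -------------------------------------------------------------

#' Construct a study-area polygon
#'
#' A polygon is stored as a list of rings; each ring is a two-column
#' (lon, lat) matrix. The first ring is the outer boundary, further rings are
#' holes; point-in-polygon uses the even-odd rule so holes need no special
#' orientation. `as_polygon()` accepts a two-column matrix/data.frame (one
#' ring), a list of such rings, or an already-built `gv_polygon`.
#'
#' @param x Ring(s) as described above.
#' @return A `gv_polygon` object.
#' @export
as_polygon <- function(x) {
  if (inherits(x, "gv_polygon")) {
    return(x)
  }
  rings <- if (is.matrix(x) || is.data.frame(x)) list(x) else x
  rings <- lapply(rings, function(r) {
    m <- as.matrix(as.data.frame(r)[, 1:2])
    storage.mode(m) <- "double"
    colnames(m) <- c("lon", "lat")
    # drop an explicit closing vertex; rings are treated as implicitly closed
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    if (nrow(m) < 3) rlang::abort("polygon ring needs at least 3 distinct vertices")
    if (any(abs(m[, "lon"]) > 180) || any(abs(m[, "lat"]) > 90)) {
      rlang::abort("polygon coordinates outside lon [-180,180] / lat [-90,90]")
    }
    m
  })
  structure(list(rings = rings), class = "gv_polygon")
}

#' Axis-aligned rectangular polygon
#'
#' @param lon_min,lon_max,lat_min,lat_max Bounds in decimal degrees.
#' @return A `gv_polygon`.
#' @export
polygon_rect <- function(lon_min, lon_max, lat_min, lat_max) {
  stopifnot(lon_max > lon_min, lat_max > lat_min)
  as_polygon(cbind(
    lon = c(lon_min, lon_max, lon_max, lon_min),
    lat = c(lat_min, lat_min, lat_max, lat_max)
  ))
}

#' Read a GeoJSON Polygon or MultiPolygon
#'
#' Reads the first feature (or a bare geometry) of a WGS84 GeoJSON file.
#' MultiPolygon parts and interior rings are all carried as rings under the
#' even-odd rule.
#'
#' @param path GeoJSON file path.
#' @return A `gv_polygon`.
#' @export
read_polygon_geojson <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("polygon file not found: %s", path))
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- switch(gj$type %||% "",
    "FeatureCollection" = gj$features[[1]]$geometry,
    "Feature" = gj$geometry,
    "Polygon" = gj,
    "MultiPolygon" = gj,
    rlang::abort(sprintf("unsupported GeoJSON type in %s", path))
  )
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  }
  rings <- switch(geom$type,
    "Polygon" = lapply(geom$coordinates, ring_mat),
    "MultiPolygon" = unlist(lapply(geom$coordinates, function(poly) {
      lapply(poly, ring_mat)
    }), recursive = FALSE),
    rlang::abort("geometry must be Polygon or MultiPolygon")
  )
  as_polygon(rings)
}

#' Write a polygon as GeoJSON
#'
#' @param polygon A `gv_polygon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygon_geojson <- function(polygon, path) {
  polygon <- as_polygon(polygon)
  coords <- lapply(polygon$rings, function(m) {
    m <- rbind(m, m[1, ]) # close the ring
    lapply(seq_len(nrow(m)), function(i) c(m[i, "lon"], m[i, "lat"]))
  })
  gj <- list(type = "Polygon", coordinates = coords)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Point-in-polygon test (even-odd rule)
#'
#' Ray-casting with the standard half-open edge convention: points on the
#' west/south boundary of an axis-aligned ring test inside, points on its
#' east/north boundary outside. Vectorized over points.
#'
#' @param polygon A `gv_polygon` (or anything [as_polygon()] accepts).
#' @param lon,lat Point coordinates in decimal degrees.
#' @return Logical vector.
#' @export
point_in_polygon <- function(polygon, lon, lat) {
  polygon <- as_polygon(polygon)
  inside <- rep(FALSE, length(lon))
  for (ring in polygon$rings) {
    xs <- ring[, "lon"]
    ys <- ring[, "lat"]
    n <- length(xs)
    j <- c(n, seq_len(n - 1))
    for (k in seq_len(n)) {
      xi <- xs[k]; yi <- ys[k]; xj <- xs[j[k]]; yj <- ys[j[k]]
      crosses <- ((yi > lat) != (yj > lat)) &
        (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
  }
  inside
}

#' Planar polygon area in squared degrees
#'
#' Shoelace area treating lon/lat as planar coordinates (holes subtract under
#' the even-odd convention). Useful for grid-density expectations, which live
#' in degree units.
#'
#' @param polygon A `gv_polygon`.
#' @return Area in deg^2.
#' @export
polygon_area_deg2 <- function(polygon) {
  polygon <- as_polygon(polygon)
  shoelace <- function(m) {
    x <- m[, "lon"]; y <- m[, "lat"]
    j <- c(seq_len(nrow(m))[-1], 1)
    abs(sum(x * y[j] - x[j] * y)) / 2
  }
  areas <- vapply(polygon$rings, shoelace, numeric(1))
  # first ring outer; any ring nested in it is a hole under even-odd
  if (length(areas) == 1) areas else max(areas) - sum(areas[-which.max(areas)])
}

#' Approximate polygon area in square kilometres
#'
#' Scales the planar degree area by the metric size of one degree at the
#' polygon's mean latitude (equirectangular approximation — adequate at city
#' scale).
#'
#' @param polygon A `gv_polygon`.
#' @return Area in km^2.
#' @export
polygon_area_km2 <- function(polygon) {
  polygon <- as_polygon(polygon)
  lat0 <- mean(range(unlist(lapply(polygon$rings, function(m) m[, "lat"]))))
  deg_m <- EARTH_RADIUS_M * pi / 180
  polygon_area_deg2(polygon) * deg_m * (deg_m * cos(lat0 * pi / 180)) / 1e6
}

polygon_bbox <- function(polygon) {
  polygon <- as_polygon(polygon)
  lon <- unlist(lapply(polygon$rings, function(m) m[, "lon"]))
  lat <- unlist(lapply(polygon$rings, function(m) m[, "lat"]))
  c(lon_min = min(lon), lon_max = max(lon), lat_min = min(lat), lat_max = max(lat))
}
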