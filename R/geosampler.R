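#' Pseudo-random sample points over a study polygon
#'
#' Lays a regular lon/lat grid at `spacing_deg` over the polygon's bounding
#' box, starting at the south-west corner with the west/south edges inclusive
#' and the east/north edges exclusive, keeps the nodes falling inside the
#' polygon, and jitters each kept node by an independent uniform offset in
#' (-spacing/2, +spacing/2) per axis. Offsets are redrawn (up to
#' `max_attempts` times) until the jittered point lies inside the polygon, so
#' the sample keeps the grid's approximately even density while being
#' pseudo-random. Reproducible for a fixed `seed`.
#'
#' @param polygon A `gv_polygon` (or anything [as_polygon()] accepts).
#' @param spacing_deg Grid spacing in decimal degrees (> 0). The study design
#'   this mirrors used 0.005.
#' @param seed Integer seed controlling the offsets.
#' @param max_attempts Redraws allowed per point before falling back to the
#'   (in-polygon) grid node itself.
#' @return Tibble with `point_id`, `lon`, `lat` (jittered location) and
#'   `grid_lon`, `grid_lat` (the pre-offset node).
#' @export
generate_sample_points <- function(polygon, spacing_deg = 0.005, seed = 1L,
                                   max_attempts = 100L) {
  stopifnot(spacing_deg > 0)
  polygon <- as_polygon(polygon)
  bb <- polygon_bbox(polygon)
  eps <- spacing_deg * 1e-9
  nx <- max(0L, ceiling(((bb["lon_max"] - bb["lon_min"]) - eps) / spacing_deg))
  ny <- max(0L, ceiling(((bb["lat_max"] - bb["lat_min"]) - eps) / spacing_deg))
  if (nx == 0 || ny == 0) rlang::abort("no sample points: polygon is degenerate")
  gx <- unname(bb["lon_min"] + spacing_deg * (seq_len(nx) - 1))
  gy <- unname(bb["lat_min"] + spacing_deg * (seq_len(ny) - 1))
  nodes <- expand.grid(grid_lon = gx, grid_lat = gy, KEEP.OUT.ATTRS = FALSE)
  keep <- point_in_polygon(polygon, nodes$grid_lon, nodes$grid_lat)
  nodes <- nodes[keep, , drop = FALSE]
  if (nrow(nodes) == 0) rlang::abort("no sample points: grid does not intersect polygon")
  half <- spacing_deg / 2
  withr::with_seed(seed, {
    lon <- numeric(nrow(nodes))
    lat <- numeric(nrow(nodes))
    ok <- logical(nrow(nodes))
    for (i in seq_len(nrow(nodes))) {
      for (attempt in seq_len(max_attempts)) {
        cand_lon <- nodes$grid_lon[i] + stats::runif(1, -half, half)
        cand_lat <- nodes$grid_lat[i] + stats::runif(1, -half, half)
        if (point_in_polygon(polygon, cand_lon, cand_lat)) {
          lon[i] <- cand_lon
          lat[i] <- cand_lat
          ok[i] <- TRUE
          break
        }
      }
      if (!ok[i]) {
        # boundary cell whose jitters all escaped: keep the node itself
        lon[i] <- nodes$grid_lon[i]
        lat[i] <- nodes$grid_lat[i]
        ok[i] <- TRUE
      }
    }
  })
  tibble::tibble(
    point_id = sprintf("pt%04d", seq_len(nrow(nodes))),
    lon = lon, lat = lat,
    grid_lon = nodes$grid_lon, grid_lat = nodes$grid_lat
  )
}

#' Match sample points to their nearest panoramas
#'
#' Straight-line (great-circle) nearest matching of each sample point against
#' a finite panorama table, as an offline stand-in for a nearest-panorama web
#' service. Exact distance ties are broken towards the lexicographically
#' smallest `pano_id`. Each match records the distance and the initial bearing
#' from the panorama towards the sample point — the heading a virtual camera
#' at the panorama needs to look at the point.
#'
#' @param points Tibble with `point_id`, `lon`, `lat`.
#' @param panos Tibble with `pano_id`, `lon`, `lat` (the panorama network; a
#'   synthetic world's `$panos`, or a table read from file).
#' @return Tibble with `point_id`, `pano_id`, `pano_lon`, `pano_lat`,
#'   `distance_m`, `bearing_deg`. A coincident point/panorama pair gets
#'   bearing 0 by convention.
#' @export
match_panoramas <- function(points, panos) {
  stopifnot(
    is.data.frame(points), all(c("point_id", "lon", "lat") %in% names(points)),
    is.data.frame(panos), all(c("pano_id", "lon", "lat") %in% names(panos))
  )
  if (nrow(panos) == 0) rlang::abort("panorama table is empty")
  panos <- dplyr::arrange(tibble::as_tibble(panos), .data$pano_id)
  # grid-bucket nearest search: find any candidate by ring expansion, then
  # widen the window to the full great-circle radius it implies and take the
  # exact haversine minimum; ties go to the lexicographically first pano_id
  # (panos are sorted, and which.min picks the first index among equals)
  deg_m <- EARTH_RADIUS_M * pi / 180
  cell <- 0.005
  pix <- floor(panos$lon / cell)
  piy <- floor(panos$lat / cell)
  buckets <- split(seq_len(nrow(panos)), paste(pix, piy))
  coslat_min <- min(cos(range(panos$lat, points$lat) * pi / 180))
  gather <- function(ix0, iy0, rx, ry) {
    keys <- as.vector(outer(
      seq(ix0 - rx, ix0 + rx), seq(iy0 - ry, iy0 + ry), paste
    ))
    sort(unlist(buckets[keys], use.names = FALSE))
  }
  idx <- integer(nrow(points))
  dist <- numeric(nrow(points))
  max_ring <- max(
    abs(range(pix) - floor(range(points$lon) / cell)),
    abs(range(piy) - floor(range(points$lat) / cell))
  ) + 1L
  for (i in seq_len(nrow(points))) {
    ix0 <- floor(points$lon[i] / cell)
    iy0 <- floor(points$lat[i] / cell)
    cand <- integer(0)
    r <- 1L
    while (length(cand) == 0 && r <= max_ring) {
      cand <- gather(ix0, iy0, r, r)
      r <- r + 1L
    }
    d <- haversine_distance_m(
      points$lon[i], points$lat[i], panos$lon[cand], panos$lat[cand]
    )
    dmin <- min(d)
    rx <- ceiling(dmin / (deg_m * coslat_min) / cell) + 1L
    ry <- ceiling(dmin / deg_m / cell) + 1L
    if (rx > r - 1L || ry > r - 1L) {
      cand <- gather(ix0, iy0, max(rx, r - 1L), max(ry, r - 1L))
      d <- haversine_distance_m(
        points$lon[i], points$lat[i], panos$lon[cand], panos$lat[cand]
      )
    }
    best <- which.min(d)
    idx[i] <- cand[best]
    dist[i] <- d[best]
  }
  plon <- panos$lon[idx]
  plat <- panos$lat[idx]
  coincident <- plon == points$lon & plat == points$lat
  bearing <- numeric(nrow(points))
  if (any(!coincident)) {
    bearing[!coincident] <- initial_bearing_deg(
      plon[!coincident], plat[!coincident],
      points$lon[!coincident], points$lat[!coincident]
    )
  }
  tibble::tibble(
    point_id = points$point_id,
    pano_id = panos$pano_id[idx],
    pano_lon = plon, pano_lat = plat,
    distance_m = dist,
    bearing_deg = bearing
  )
}

#' Virtual-camera requests from panorama matches
#'
#' Builds the specification of the rectilinear view to extract from each
#' matched panorama: the camera stands at the panorama and faces the sample
#' point, so the heading is exactly the pano-to-point initial bearing. The
#' defaults (90 degree field of view, 640 x 640 pixels) mirror the standard
#' static street-view image request.
#'
#' @param matches Tibble from [match_panoramas()].
#' @param fov_deg Field of view in degrees, in (0, 120\].
#' @param width_px,height_px Positive integer pixel dimensions.
#' @return Tibble with `point_id`, `pano_id`, `heading_deg`, `fov_deg`,
#'   `width_px`, `height_px`.
#' @export
build_image_request <- function(matches, fov_deg = 90, width_px = 640L,
                                height_px = 640L) {
  stopifnot(
    fov_deg > 0, fov_deg <= 120,
    width_px >= 1, height_px >= 1,
    width_px == as.integer(width_px), height_px == as.integer(height_px)
  )
  tibble::tibble(
    point_id = matches$point_id,
    pano_id = matches$pano_id,
    heading_deg = matches$bearing_deg %% 360,
    fov_deg = fov_deg,
    width_px = as.integer(width_px),
    height_px = as.integer(height_px)
  )
}

#' Read a panorama table (offline provider)
#'
#' CSV with header `pano_id,lon,lat`: a fixed panorama network against which
#' [match_panoramas()] performs offline nearest matching.
#'
#' @param path CSV path.
#' @return Tibble with `pano_id`, `lon`, `lat`.
#' @export
read_panoramas <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("panorama file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("pano_id", "lon", "lat") %in% names(df))) {
    rlang::abort(sprintf("panorama file %s needs columns pano_id,lon,lat", path))
  }
  df$pano_id <- as.character(df$pano_id)
  df
}

#' Summary of point-to-panorama offsets
#'
#' @param matches Tibble from [match_panoramas()].
#' @return One-row tibble: `n`, `mean_distance_m`, `sd_distance_m`,
#'   `max_distance_m`, `n_shared_panoramas` (panoramas serving more than one
#'   sample point).
#' @export
summarize_matches <- function(matches) {
  tibble::tibble(
    n = nrow(matches),
    mean_distance_m = mean(matches$distance_m),
    sd_distance_m = stats::sd(matches$distance_m),
    max_distance_m = max(matches$distance_m),
    n_shared_panoramas = sum(table(matches$pano_id) > 1)
  )
}
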