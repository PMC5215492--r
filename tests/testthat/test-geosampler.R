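test_that("grid node rule gives the enumerated count on an aligned square", {
  # 0.02 x 0.02 square at 0.005 spacing: west/south inclusive, east/north
  # exclusive -> 4 x 4 nodes
  sq <- polygon_rect(0, 0.02, 0, 0.02)
  pts <- generate_sample_points(sq, 0.005, seed = 1)
  expect_equal(nrow(pts), 16)
  expect_equal(
    sort(unique(pts$grid_lon)), c(0, 0.005, 0.01, 0.015),
    tolerance = 1e-12
  )
})

test_that("sample points stay inside the polygon and are reproducible", {
  poly <- polygon_rect(-3.2, -3.15, 55.9, 55.93)
  a <- generate_sample_points(poly, 0.005, seed = 5)
  b <- generate_sample_points(poly, 0.005, seed = 5)
  expect_identical(a, b)
  c <- generate_sample_points(poly, 0.005, seed = 6)
  expect_false(identical(a$lon, c$lon))
  expect_true(all(point_in_polygon(poly, a$lon, a$lat)))
  # offsets bounded by half the spacing
  expect_true(all(abs(a$lon - a$grid_lon) <= 0.0025))
  expect_true(all(abs(a$lat - a$grid_lat) <= 0.0025))
})

test_that("degenerate polygons yield a clear error", {
  line <- cbind(lon = c(0, 1, 2), lat = c(0, 0, 0))
  expect_error(generate_sample_points(line, 0.005, seed = 1), "no sample points|degenerate")
})

test_that("grid density approximates area / spacing^2", {
  # irregular pentagon, large relative to the spacing
  pent <- as_polygon(cbind(
    lon = c(0, 0.4, 0.5, 0.25, -0.05),
    lat = c(0, -0.05, 0.3, 0.45, 0.3)
  ))
  pts <- generate_sample_points(pent, 0.01, seed = 3)
  expected <- polygon_area_deg2(pent) / 0.01^2
  expect_lt(abs(nrow(pts) - expected) / expected, 0.1)
})

test_that("match_panoramas finds the brute-force nearest with deterministic ties", {
  withr::with_seed(11, {
    pts <- tibble::tibble(
      point_id = sprintf("p%02d", 1:40),
      lon = runif(40, -3.3, -3.1), lat = runif(40, 55.9, 55.96)
    )
    panos <- tibble::tibble(
      pano_id = sprintf("g%03d", sample(300)),
      lon = runif(300, -3.3, -3.1), lat = runif(300, 55.9, 55.96)
    )
  })
  m <- match_panoramas(pts, panos)
  # brute-force all-pairs oracle
  pp <- panos[order(panos$pano_id), ]
  for (i in seq_len(nrow(pts))) {
    d <- haversine_distance_m(pts$lon[i], pts$lat[i], pp$lon, pp$lat)
    expect_equal(m$pano_id[i], pp$pano_id[which.min(d)])
    expect_equal(m$distance_m[i], min(d))
    expect_equal(
      m$bearing_deg[i],
      initial_bearing_deg(m$pano_lon[i], m$pano_lat[i], pts$lon[i], pts$lat[i])
    )
  }

  # a single panorama catches every point; duplicates tie-break by id
  single <- tibble::tibble(pano_id = "only", lon = -3.2, lat = 55.93)
  expect_true(all(match_panoramas(pts, single)$pano_id == "only"))
  dup <- tibble::tibble(
    pano_id = c("b", "a"), lon = c(-3.2, -3.2), lat = c(55.93, 55.93)
  )
  expect_true(all(match_panoramas(pts, dup)$pano_id == "a"))
})

test_that("nearby points can share a panorama but keep their own bearings", {
  pts <- tibble::tibble(
    point_id = c("east", "west"),
    lon = c(0.001, -0.001), lat = c(0, 0)
  )
  panos <- tibble::tibble(pano_id = "mid", lon = 0, lat = 0)
  m <- match_panoramas(pts, panos)
  expect_equal(m$pano_id, c("mid", "mid"))
  expect_equal(m$bearing_deg, c(90, 270), tolerance = 1e-6)
})

test_that("image requests pass the bearing through as heading", {
  m <- tibble::tibble(
    point_id = "p", pano_id = "g", pano_lon = 0, pano_lat = 0,
    distance_m = 10, bearing_deg = 123.4
  )
  req <- build_image_request(m)
  expect_equal(req$heading_deg, 123.4)
  expect_equal(req$fov_deg, 90)
  expect_equal(req$width_px, 640L)
  expect_equal(req$height_px, 640L)
  expect_equal(build_image_request(m, fov_deg = 60)$fov_deg, 60)
  m$bearing_deg <- 0
  expect_equal(build_image_request(m)$heading_deg, 0)
  expect_error(build_image_request(m, fov_deg = 150))
})

test_that("panorama tables round-trip through CSV", {
  panos <- tibble::tibble(pano_id = c("a", "b"), lon = c(0, 1), lat = c(2, 3))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(panos, f)
  expect_equal(read_panoramas(f), panos)
})
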