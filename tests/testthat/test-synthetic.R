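test_that("worlds are reproducible by seed and distinct across seeds", {
  cfg <- tiny_world_config(seed = 3L)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$panos, w2$panos)
  expect_identical(
    w1$u(c(-3.17, -3.15), c(55.91, 55.93)),
    w2$u(c(-3.17, -3.15), c(55.91, 55.93))
  )
  w3 <- generate_world(tiny_world_config(seed = 4L))
  expect_false(identical(w1$panos, w3$panos))
  # u respects its bounds everywhere
  withr::with_seed(1, {
    lon <- runif(500, -3.2, -3.14)
    lat <- runif(500, 55.9, 55.94)
  })
  u <- w1$u(lon, lat)
  expect_true(all(u >= 0 & u <= 1))
  vig <- w1$vigintile(lon, lat)
  expect_true(all(vig %in% 1:20))
})

test_that("halving the panorama spacing about doubles the panorama count", {
  n1 <- nrow(generate_world(tiny_world_config(seed = 2L))$panos)
  n2 <- nrow(generate_world(tiny_world_config(seed = 2L, pano_spacing_m = 12.5))$panos)
  expect_lt(abs(n2 / n1 - 2), 0.15 * 2)
})

test_that("degenerate world polygons error out", {
  cfg <- world_config(polygon = cbind(lon = c(0, 1e-9, 0), lat = c(0, 0, 1e-9)))
  expect_error(generate_world(cfg), "degenerate|too small")
})

test_that("classifier emissions track the naturalness extremes", {
  all_nat <- function(u) cbind(rep(1, length(u)), rep(0, length(u)), rep(0, length(u)))
  w <- generate_world(tiny_world_config(seed = 5L, class_mix = all_nat))
  req <- tibble::tibble(pano_id = w$panos$pano_id[1:20])
  labs <- mock_classifier(w, req)
  scores <- score_images(labs, w$taxonomy)
  expect_true(all(scores$csn == 1))

  all_art <- function(u) cbind(rep(0, length(u)), rep(1, length(u)), rep(0, length(u)))
  w2 <- generate_world(tiny_world_config(seed = 5L, class_mix = all_art))
  scores2 <- score_images(mock_classifier(w2, req), w2$taxonomy)
  expect_true(all(scores2$csn == -1))

  expect_error(mock_classifier(w, tibble::tibble(pano_id = "nope")), "unknown pano_id")
})

test_that("classifier label counts match the configured moments", {
  w <- generate_world(tiny_world_config(seed = 9L))
  corp <- simulate_image_corpus(w, 10000, seed = 77L)
  counts <- dplyr::count(corp$labels, image_id)
  expect_true(all(counts$n >= 1 & counts$n <= 18))
  expect_lt(abs(mean(counts$n) - 8.17), 0.1)
  expect_lt(abs(sd(counts$n) - 3.55), 0.15)
})

test_that("classifier emissions are deterministic per image id", {
  w <- generate_world(tiny_world_config(seed = 5L))
  req <- tibble::tibble(pano_id = w$panos$pano_id[1:5])
  expect_identical(mock_classifier(w, req), mock_classifier(w, req))
})

test_that("the mock panel is exact when noiseless and calibrated when noisy", {
  w <- generate_world(tiny_world_config(seed = 6L, rater_noise_sd = 0))
  imgs <- tibble::tibble(image_id = c("m", "n"), lon = -3.17, lat = 55.92)
  w$u <- function(lon, lat) rep(0.5, length(lon))
  r <- mock_panel(w, imgs)
  expect_true(all(r$rating == 4L)) # 1 + 6 * 0.5
  w$u <- function(lon, lat) rep(1, length(lon))
  expect_true(all(mock_panel(w, imgs)$rating == 7L))

  # noisy defaults: mean per-image rater sd near the configured 1.15
  wn <- generate_world(tiny_world_config(seed = 6L))
  corp <- simulate_image_corpus(wn, 100)
  pn <- aggregate_pn(mock_panel(wn, corp$images))
  expect_lt(abs(mean(pn$rater_sd) - 1.15), 0.15)
})

test_that("deprivation lookup respects coverage exactly", {
  w <- generate_world(tiny_world_config(seed = 8L))
  pts <- generate_sample_points(w$config$polygon, 0.005, seed = 2L)
  full <- mock_deprivation(w, pts, coverage = 1)
  expect_equal(nrow(full), nrow(pts))
  part <- mock_deprivation(w, pts, coverage = 756 / 768)
  expect_equal(nrow(pts) - nrow(part), round(nrow(pts) * 12 / 768))
  expect_true(all(part$vigintile %in% 1:20))
  expect_identical(part, mock_deprivation(w, pts, coverage = 756 / 768))
})

test_that("coupling deprivation to the field flips the null result", {
  w <- generate_world(tiny_world_config(seed = 13L))
  pts <- generate_sample_points(w$config$polygon, 0.005, seed = 14L)
  # vigintile made a decreasing function of u plus noise
  u <- w$u(pts$lon, pts$lat)
  withr::with_seed(15, {
    vig <- pmin(pmax(round(21 - 20 * u + rnorm(length(u), 0, 2)), 1), 20)
  })
  lookup <- tibble::tibble(point_id = pts$point_id, vigintile = as.integer(vig))
  m <- match_panoramas(pts, w$panos)
  labs <- mock_classifier(w, tibble::tibble(point_id = m$point_id, pano_id = m$pano_id))
  scores <- dplyr::rename(score_images(labs, w$taxonomy), point_id = "image_id")
  linked <- join_deprivation(scores, lookup)
  r <- pearson_with_ci(linked$csn, linked$vigintile)
  expect_lt(r$r, -0.3)
  expect_lt(r$p_value, 0.01)
})

test_that("simulate_study writes a complete consumable file set", {
  dir <- withr::local_tempdir()
  files <- simulate_study(tiny_world_config(seed = 20L), dir, per_stratum = 5L)
  expect_true(all(file.exists(files)))
  tax <- load_taxonomy(files[["taxonomy"]])
  labels <- read_labels(files[["labels"]])
  ratings <- read_ratings(files[["ratings"]])
  lookup <- read_deprivation_lookup(files[["lookup"]])
  rep <- run_experiment2(
    points = files[["points"]], labels = labels, taxonomy = tax,
    matches = files[["matches"]], ratings = ratings, lookup = lookup
  )
  expect_s3_class(rep, "gv_report")
  expect_equal(rep$panel$n_images, 25)
})
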