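# Synthetic world: a street network, a smooth ground-truth naturalness field
# u(lon, lat) in [0, 1], a mock image classifier whose label emissions are
# coupled to u, a mock rating panel, and a mock deprivation lookup that is
# spatially structured but independent of u by default. Together these stand
# in for the street-imagery and vision services so the full pipeline runs
# offline and reproducibly.

# deterministic small hash of an id string, for per-image sub-seeds
str_seed <- function(id, base_seed, draw_index = 0L) {
  h <- 0
  for (code in utf8ToInt(as.character(id))) h <- (h * 31 + code) %% 1000000007
  as.integer((h + base_seed * 7919 + draw_index) %% .Machine$integer.max)
}

#' Configuration of a synthetic study world
#'
#' Bundles every tunable of the synthetic world. The defaults emulate the
#' statistical structure of a city-scale street-imagery study: a roughly
#' 133 km^2 rectangular study area at Edinburgh's latitude whose 0.005-degree
#' sampling grid holds exactly 768 nodes; label counts per image distributed
#' as a rounded normal with mean 8.17 and sd 3.55 clipped to \[1, 18\];
#' rater noise with sd 1.15 on the 7-point scale; deprivation linkage
#' covering 756 of 768 points; and a street network dense enough that
#' nearest-panorama offsets average about 68 m.
#'
#' @param polygon Study-area polygon (default: the rectangle above).
#' @param street_segment_count Number of straight street segments.
#' @param segment_length_m Length of each street segment in metres.
#' @param pano_spacing_m Spacing of panoramas along a street in metres.
#' @param n_bumps,bump_width_deg Number and width (degrees) of the random
#'   signed radial bumps summed into the naturalness field.
#' @param field_gain,field_amplitude Shaping of the field: the bump sum is
#'   standardized to zero mean and unit sd over the polygon, then mapped to
#'   u = 0.5 + field_amplitude * tanh(field_gain * z), so u stays inside
#'   \[0.5 - amplitude, 0.5 + amplitude\]. The default amplitude 0.32 keeps
#'   panel latent scores away from the 1/7 clip boundaries (preserving the
#'   configured inter-rater sd) while giving the field enough contrast that
#'   CSN tracks it.
#' @param label_count_mean,label_count_sd,label_count_range Moments and
#'   support of the per-image label-count distribution.
#' @param class_mix Function mapping ground-truth naturalness u in \[0, 1\] to
#'   a length-3 probability vector (natural, artificial, ambiguous). The
#'   default interpolates linearly: p_nat = 0.1 + 0.7 u,
#'   p_art = 0.8 - 0.7 u, p_amb = 0.1, so extreme u gives clearly separated
#'   scores while mid-range images mix classes.
#' @param taxonomy Vocabulary source: a `gv_taxonomy` whose labels per class
#'   form the emission pools (default [default_taxonomy()]).
#' @param rater_count Panel size.
#' @param rater_noise_sd Sd of the Gaussian noise added to a rater's latent
#'   score before rounding to the 7-point grid.
#' @param linkage_coverage Fraction of sample points present in the
#'   deprivation lookup (applied as an exact fixed-count subset).
#' @param deprivation_block_deg Side of the square spatial blocks sharing a
#'   deprivation vigintile.
#' @param seed Master seed for world generation.
#' @return A `gv_world_config` list.
#' @export
world_config <- function(polygon = polygon_rect(-3.32, -3.08, 55.89, 55.97),
                         street_segment_count = 750L,
                         segment_length_m = 1200,
                         pano_spacing_m = 12,
                         n_bumps = 12L,
                         bump_width_deg = 0.03,
                         field_gain = 1.5,
                         field_amplitude = 0.32,
                         label_count_mean = 8.17,
                         label_count_sd = 3.55,
                         label_count_range = c(1L, 18L),
                         class_mix = NULL,
                         taxonomy = NULL,
                         rater_count = 15L,
                         rater_noise_sd = 1.15,
                         linkage_coverage = 756 / 768,
                         deprivation_block_deg = 0.01,
                         seed = 1L) {
  if (is.null(class_mix)) {
    class_mix <- function(u) {
      cbind(0.1 + 0.7 * u, 0.8 - 0.7 * u, rep(0.1, length(u)))
    }
  }
  probs <- class_mix(c(0, 0.5, 1))
  if (any(abs(rowSums(probs) - 1) > 1e-8) || any(probs < -1e-12)) {
    rlang::abort("class_mix must return non-negative probabilities summing to 1")
  }
  structure(list(
    polygon = as_polygon(polygon),
    street_segment_count = street_segment_count,
    segment_length_m = segment_length_m,
    pano_spacing_m = pano_spacing_m,
    n_bumps = n_bumps,
    bump_width_deg = bump_width_deg,
    field_gain = field_gain,
    field_amplitude = field_amplitude,
    label_count_mean = label_count_mean,
    label_count_sd = label_count_sd,
    label_count_range = as.integer(label_count_range),
    class_mix = class_mix,
    taxonomy = taxonomy,
    rater_count = as.integer(rater_count),
    rater_noise_sd = rater_noise_sd,
    linkage_coverage = linkage_coverage,
    deprivation_block_deg = deprivation_block_deg,
    seed = as.integer(seed)
  ), class = "gv_world_config")
}

#' Generate a synthetic world
#'
#' Realises a [world_config()]: drops randomly placed, randomly oriented
#' street segments across the polygon and lays panoramas along them at the
#' configured spacing; draws the random radial bumps of the smooth
#' ground-truth naturalness field; and assigns each spatial block a
#' deprivation vigintile independent of the field. Identical seeds give
#' identical worlds.
#'
#' @param config A `gv_world_config`.
#' @return A `gv_world` list: `$config`, `$panos` (tibble `pano_id,lon,lat`),
#'   `$u` (function lon,lat -> naturalness in \[0,1\]), `$vigintile`
#'   (function lon,lat -> integer 1-20), `$taxonomy`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "gv_world_config"))
  polygon <- config$polygon
  bb <- polygon_bbox(polygon)
  lat0 <- (bb["lat_min"] + bb["lat_max"]) / 2
  deg_m <- EARTH_RADIUS_M * pi / 180 # metres per degree latitude
  coslat <- cos(lat0 * pi / 180)
  diag_m <- haversine_distance_m(
    bb["lon_min"], bb["lat_min"], bb["lon_max"], bb["lat_max"]
  )
  if (diag_m < config$segment_length_m) {
    rlang::abort("polygon too small to place street segments")
  }
  taxonomy <- config$taxonomy %||% default_taxonomy()

  withr::with_seed(config$seed, {
    # random in-polygon segment midpoints by rejection sampling
    mids_lon <- numeric(0)
    mids_lat <- numeric(0)
    tries <- 0L
    while (length(mids_lon) < config$street_segment_count) {
      need <- config$street_segment_count - length(mids_lon)
      cl <- stats::runif(4 * need, bb["lon_min"], bb["lon_max"])
      ct <- stats::runif(4 * need, bb["lat_min"], bb["lat_max"])
      keep <- point_in_polygon(polygon, cl, ct)
      mids_lon <- c(mids_lon, cl[keep])
      mids_lat <- c(mids_lat, ct[keep])
      tries <- tries + 1L
      if (tries > 200L) {
        rlang::abort("polygon too small/degenerate to place street segments")
      }
    }
    mids_lon <- mids_lon[seq_len(config$street_segment_count)]
    mids_lat <- mids_lat[seq_len(config$street_segment_count)]
    theta <- stats::runif(config$street_segment_count, 0, pi)

    n_per_seg <- max(2L, floor(config$segment_length_m / config$pano_spacing_m) + 1L)
    offs <- seq(-config$segment_length_m / 2, config$segment_length_m / 2,
      length.out = n_per_seg
    )
    pano_lon <- as.vector(vapply(seq_along(mids_lon), function(i) {
      mids_lon[i] + offs * cos(theta[i]) / (deg_m * coslat)
    }, numeric(n_per_seg)))
    pano_lat <- as.vector(vapply(seq_along(mids_lat), function(i) {
      mids_lat[i] + offs * sin(theta[i]) / deg_m
    }, numeric(n_per_seg)))

    # naturalness field: signed radial bumps, standardized over the polygon
    # so every seed realises the same field contrast, then squashed into
    # [0.5 - amp, 0.5 + amp] through tanh
    bump_lon <- stats::runif(config$n_bumps, bb["lon_min"], bb["lon_max"])
    bump_lat <- stats::runif(config$n_bumps, bb["lat_min"], bb["lat_max"])
    bump_amp <- stats::runif(config$n_bumps, 0.5, 1.5) *
      sample(c(-1, 1), config$n_bumps, replace = TRUE)
    ref_lon <- stats::runif(2000, bb["lon_min"], bb["lon_max"])
    ref_lat <- stats::runif(2000, bb["lat_min"], bb["lat_max"])

    # deprivation vigintiles on square spatial blocks
    nbx <- max(1L, ceiling((bb["lon_max"] - bb["lon_min"]) / config$deprivation_block_deg))
    nby <- max(1L, ceiling((bb["lat_max"] - bb["lat_min"]) / config$deprivation_block_deg))
    vig_blocks <- matrix(
      sample.int(20L, nbx * nby, replace = TRUE),
      nrow = nbx, ncol = nby
    )
  })

  w <- config$bump_width_deg
  bump_sum <- function(lon, lat) {
    s <- rep(0, length(lon))
    for (i in seq_along(bump_lon)) {
      d2 <- ((lon - bump_lon[i]) * coslat)^2 + (lat - bump_lat[i])^2
      s <- s + bump_amp[i] * exp(-d2 / (2 * w^2))
    }
    s
  }
  ref <- bump_sum(ref_lon, ref_lat)
  s_center <- mean(ref)
  s_scale <- stats::sd(ref)
  if (s_scale == 0) s_scale <- 1 # pathological flat field; u is then 0.5
  gain <- config$field_gain
  amp <- config$field_amplitude
  u_fun <- function(lon, lat) {
    0.5 + amp * tanh(gain * (bump_sum(lon, lat) - s_center) / s_scale)
  }
  block_deg <- config$deprivation_block_deg
  vig_fun <- function(lon, lat) {
    ix <- pmin(pmax(1L, 1L + floor((lon - bb["lon_min"]) / block_deg)), nrow(vig_blocks))
    iy <- pmin(pmax(1L, 1L + floor((lat - bb["lat_min"]) / block_deg)), ncol(vig_blocks))
    vig_blocks[cbind(as.integer(ix), as.integer(iy))]
  }

  structure(list(
    config = config,
    panos = tibble::tibble(
      pano_id = sprintf("pano%05d", seq_along(pano_lon)),
      lon = pano_lon, lat = pano_lat
    ),
    u = u_fun,
    vigintile = vig_fun,
    taxonomy = taxonomy
  ), class = "gv_world")
}

# emit one image's label list given ground-truth naturalness u
emit_labels <- function(world, image_id, u, draw_index = 0L) {
  cfg <- world$config
  vocab <- split(world$taxonomy$label, world$taxonomy$class)
  withr::with_seed(str_seed(image_id, cfg$seed, draw_index), {
    t_raw <- round(stats::rnorm(1, cfg$label_count_mean, cfg$label_count_sd))
    n_tot <- min(max(t_raw, cfg$label_count_range[1]), cfg$label_count_range[2])
    probs <- as.numeric(cfg$class_mix(u))
    counts <- stats::rmultinom(1, n_tot, probs)[, 1]
    labs <- c(
      sample(vocab$natural, min(counts[1], length(vocab$natural))),
      sample(vocab$artificial, min(counts[2], length(vocab$artificial))),
      sample(vocab$ambiguous, min(counts[3], length(vocab$ambiguous)))
    )
    labs
  })
}

#' Mock image classifier
#'
#' Emulates the statistical structure of a label-detection service: for each
#' requested view it draws a label count from the configured rounded clipped
#' normal, splits it across semantic classes by `class_mix(u)` evaluated at
#' the panorama location, and draws label strings uniformly without
#' replacement from each class's vocabulary pool. Emissions are deterministic
#' given the world seed and the image id.
#'
#' @param world A `gv_world`.
#' @param requests Tibble with `pano_id` (must exist in the world) and
#'   optionally `point_id`; the image id is `point_id` when present, else
#'   `pano_id`.
#' @return Tibble with `image_id`, `label`, one row per label occurrence.
#' @export
mock_classifier <- function(world, requests) {
  stopifnot(inherits(world, "gv_world"), is.data.frame(requests))
  if (!"pano_id" %in% names(requests)) rlang::abort("requests need a pano_id column")
  m <- match(requests$pano_id, world$panos$pano_id)
  if (anyNA(m)) {
    rlang::abort(sprintf(
      "unknown pano_id: %s",
      paste(utils::head(unique(requests$pano_id[is.na(m)]), 5), collapse = ", ")
    ))
  }
  ids <- if ("point_id" %in% names(requests)) requests$point_id else requests$pano_id
  u <- world$u(world$panos$lon[m], world$panos$lat[m])
  purrr::map2_dfr(seq_along(ids), u, function(i, ui) {
    tibble::tibble(image_id = ids[i], label = emit_labels(world, ids[i], ui, i))
  })
}

#' Mock rating panel
#'
#' Each rater's score for an image is `round(clip(1 + 6 u + e, 1, 7))` with
#' independent Gaussian noise e (sd `rater_noise_sd`), mimicking a 7-button
#' Likert interface driven by the ground-truth naturalness at the image's
#' location. Clipping at the scale ends attenuates the realised inter-rater
#' sd slightly below the configured value.
#'
#' @param world A `gv_world`.
#' @param images Tibble with `image_id`, `lon`, `lat`.
#' @param seed Seed (default: derived from the world seed).
#' @return Tibble with `rater_id`, `image_id`, `rating`.
#' @export
mock_panel <- function(world, images, seed = NULL) {
  stopifnot(inherits(world, "gv_world"), is.data.frame(images))
  stopifnot(all(c("image_id", "lon", "lat") %in% names(images)))
  cfg <- world$config
  seed <- seed %||% str_seed("panel", cfg$seed)
  u <- world$u(images$lon, images$lat)
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      rater_id = sprintf("rater%02d", seq_len(cfg$rater_count)),
      i = seq_len(nrow(images))
    )
    latent <- 1 + 6 * u[grid$i] +
      stats::rnorm(nrow(grid), 0, cfg$rater_noise_sd)
    tibble::tibble(
      rater_id = grid$rater_id,
      image_id = images$image_id[grid$i],
      rating = as.integer(round(pmin(pmax(latent, 1), 7)))
    )
  })
}

#' Mock deprivation lookup
#'
#' Assigns each point the vigintile of its spatial block (independent of the
#' naturalness field, so the default world embodies the null hypothesis of no
#' CSN-deprivation association) and then drops an exact fixed-count subset of
#' points to emulate incomplete reverse-geocoding coverage.
#'
#' @param world A `gv_world`.
#' @param points Tibble with `point_id`, `lon`, `lat`.
#' @param coverage Fraction linked (default from the world config). The
#'   number of unlinked points is `round(n * (1 - coverage))`, drawn at
#'   random but reproducibly.
#' @param seed Seed (default derived from the world seed).
#' @return Lookup tibble `point_id`, `vigintile` containing only the linked
#'   points.
#' @export
mock_deprivation <- function(world, points, coverage = NULL, seed = NULL) {
  stopifnot(inherits(world, "gv_world"), is.data.frame(points))
  stopifnot(all(c("point_id", "lon", "lat") %in% names(points)))
  coverage <- coverage %||% world$config$linkage_coverage
  stopifnot(coverage >= 0, coverage <= 1)
  seed <- seed %||% str_seed("deprivation", world$config$seed)
  n_unlink <- round(nrow(points) * (1 - coverage))
  lookup <- tibble::tibble(
    point_id = points$point_id,
    vigintile = as.integer(world$vigintile(points$lon, points$lat))
  )
  if (n_unlink > 0) {
    withr::with_seed(seed, {
      drop <- sample(nrow(lookup), n_unlink)
    })
    lookup <- lookup[-drop, , drop = FALSE]
  }
  lookup
}

#' Simulate a composed-image corpus
#'
#' Generates a corpus of images at random in-polygon locations (so their
#' ground-truth naturalness spans the field), with labels from the mock
#' classifier — the synthetic analogue of a curated photograph set scored for
#' perceived naturalness.
#'
#' @param world A `gv_world`.
#' @param n_images Corpus size.
#' @param seed Seed for the image locations.
#' @return List with `images` (tibble `image_id,lon,lat,u`) and `labels`
#'   (tibble `image_id,label`).
#' @export
simulate_image_corpus <- function(world, n_images = 307L, seed = NULL) {
  stopifnot(inherits(world, "gv_world"))
  seed <- seed %||% str_seed("corpus", world$config$seed)
  bb <- polygon_bbox(world$config$polygon)
  withr::with_seed(seed, {
    lon <- numeric(0)
    lat <- numeric(0)
    while (length(lon) < n_images) {
      cl <- stats::runif(2 * n_images, bb["lon_min"], bb["lon_max"])
      ct <- stats::runif(2 * n_images, bb["lat_min"], bb["lat_max"])
      keep <- point_in_polygon(world$config$polygon, cl, ct)
      lon <- c(lon, cl[keep])
      lat <- c(lat, ct[keep])
    }
    lon <- lon[seq_len(n_images)]
    lat <- lat[seq_len(n_images)]
  })
  images <- tibble::tibble(
    image_id = sprintf("img%04d", seq_len(n_images)),
    lon = lon, lat = lat, u = world$u(lon, lat)
  )
  # corpus images are not tied to panoramas; emit directly from their u
  labels <- purrr::map2_dfr(images$image_id, images$u, function(id, ui) {
    tibble::tibble(image_id = id, label = emit_labels(world, id, ui))
  })
  list(images = images, labels = labels)
}

#' Write a full set of synthetic study inputs
#'
#' Generates a world and writes every input table the pipeline consumes —
#' taxonomy, sample points, panorama matches, per-image labels, panel ratings
#' for the quintile-stratified subsample, and the deprivation lookup — as
#' CSVs byte-compatible with the package's readers.
#'
#' @param config A `gv_world_config`.
#' @param out_dir Output directory (created if missing).
#' @param per_stratum Panel subsample size per CSN quintile.
#' @return Named character vector of the files written, invisibly.
#' @export
simulate_study <- function(config = world_config(), out_dir, per_stratum = 20L) {
  world <- generate_world(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  points <- generate_sample_points(config$polygon,
    spacing_deg = 0.005,
    seed = str_seed("points", config$seed)
  )
  matches <- match_panoramas(points, world$panos)
  requests <- build_image_request(matches)
  labels <- mock_classifier(world, dplyr::select(requests, "point_id", "pano_id"))
  scores <- score_images(labels, world$taxonomy)
  sub_ids <- stratified_quintile_subsample(scores,
    per_stratum = per_stratum,
    seed = str_seed("subsample", config$seed)
  )
  sub_points <- points[match(sub_ids, points$point_id), ]
  ratings <- mock_panel(world, tibble::tibble(
    image_id = sub_points$point_id, lon = sub_points$lon, lat = sub_points$lat
  ))
  lookup <- mock_deprivation(world, points)
  files <- c(
    taxonomy = file.path(out_dir, "taxonomy.csv"),
    points = file.path(out_dir, "points.csv"),
    matches = file.path(out_dir, "matches.csv"),
    labels = file.path(out_dir, "labels.csv"),
    ratings = file.path(out_dir, "ratings.csv"),
    lookup = file.path(out_dir, "lookup.csv")
  )
  save_taxonomy(world$taxonomy, files["taxonomy"])
  readr::write_csv(points, files["points"], progress = FALSE)
  readr::write_csv(matches, files["matches"], progress = FALSE)
  readr::write_csv(labels, files["labels"], progress = FALSE)
  readr::write_csv(ratings, files["ratings"], progress = FALSE)
  readr::write_csv(lookup, files["lookup"], progress = FALSE)
  invisible(files)
}
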