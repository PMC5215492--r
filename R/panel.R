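#' Aggregate Likert ratings into Perceived Naturalness
#'
#' Perceived Naturalness (PN) of an image is the arithmetic mean of the
#' 1-7 Likert ratings its panel gave it (1 = not natural, 7 = natural).
#' Incomplete panels are tolerated: each image is averaged over the raters who
#' actually rated it. The per-image rater standard deviation uses the sample
#' (n - 1) denominator and is reported as 0 with `sd_undefined = TRUE` when a
#' single rater rated the image.
#'
#' @param ratings Data frame with columns `rater_id`, `image_id`, `rating`
#'   (integers 1-7; each (rater, image) pair at most once).
#' @return Tibble with `image_id`, `pn`, `n_raters`, `rater_sd`,
#'   `sd_undefined`, one row per distinct image.
#' @export
#' @examples
#' aggregate_pn(data.frame(
#'   rater_id = c("a", "b"), image_id = "img1", rating = c(1L, 7L)
#' ))
aggregate_pn <- function(ratings) {
  stopifnot(is.data.frame(ratings))
  if (!all(c("rater_id", "image_id", "rating") %in% names(ratings))) {
    rlang::abort("ratings need columns rater_id, image_id, rating")
  }
  if (nrow(ratings) == 0) rlang::abort("no ratings to aggregate")
  bad <- !(ratings$rating %in% 1:7)
  if (any(bad)) {
    i <- which(bad)[1]
    rlang::abort(sprintf(
      "rating out of 1-7 range: rater '%s', image '%s', value %s",
      ratings$rater_id[i], ratings$image_id[i], ratings$rating[i]
    ))
  }
  dup <- duplicated(ratings[c("rater_id", "image_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    rlang::abort(sprintf(
      "duplicate rating: rater '%s' rated image '%s' more than once",
      ratings$rater_id[i], ratings$image_id[i]
    ))
  }
  tibble::as_tibble(ratings) |>
    dplyr::summarise(
      pn = mean(.data$rating),
      n_raters = dplyr::n(),
      rater_sd = ifelse(dplyr::n() > 1, stats::sd(.data$rating), 0),
      .by = "image_id"
    ) |>
    dplyr::mutate(sd_undefined = .data$n_raters == 1)
}

#' Distributional diagnostics of panel PN scores
#'
#' Moments of the PN values across images: sample mean and sd, plus skewness
#' and kurtosis computed from population central moments. Kurtosis is on the
#' non-excess (Pearson) convention — a normal distribution has kurtosis 3, a
#' uniform one 1.8, and no distribution can fall below 1.
#'
#' @param pn_scores Tibble from [aggregate_pn()] (needs `pn`; `rater_sd` used
#'   for `mean_rater_sd` if present). At least 4 images are required for the
#'   kurtosis to be meaningful.
#' @return One-row tibble: `n_images`, `mean`, `sd`, `skewness`, `kurtosis`,
#'   `mean_rater_sd`.
#' @export
panel_distribution <- function(pn_scores) {
  stopifnot(is.data.frame(pn_scores), "pn" %in% names(pn_scores))
  x <- pn_scores$pn
  if (length(x) < 4) rlang::abort("need at least 4 images for panel moments")
  m <- x - mean(x)
  m2 <- mean(m^2)
  if (m2 == 0) rlang::abort("all PN values identical; moments undefined")
  tibble::tibble(
    n_images = length(x),
    mean = mean(x),
    sd = stats::sd(x),
    skewness = mean(m^3) / m2^1.5,
    kurtosis = mean(m^4) / m2^2,
    mean_rater_sd = if ("rater_sd" %in% names(pn_scores)) {
      mean(pn_scores$rater_sd)
    } else {
      NA_real_
    }
  )
}

#' Quintile-stratified subsample of scored images
#'
#' Splits the CSN scores into five strata at the empirical 20/40/60/80
#' percentiles (ties at a boundary go to the lower stratum) and draws
#' `per_stratum` image ids uniformly without replacement from each stratum —
#' the design used to pick a representative image subset for panel rating.
#' Reproducible for a fixed seed.
#'
#' @param scores Tibble with `image_id` and `csn` (e.g. from
#'   [score_images()]).
#' @param per_stratum Number of images drawn per stratum (>= 1).
#' @param seed Integer seed.
#' @return Character vector of `5 * per_stratum` image ids.
#' @export
stratified_quintile_subsample <- function(scores, per_stratum = 20L, seed = 1L) {
  stopifnot(is.data.frame(scores), all(c("image_id", "csn") %in% names(scores)))
  stopifnot(per_stratum >= 1)
  q <- stats::quantile(scores$csn, probs = c(.2, .4, .6, .8), names = FALSE)
  stratum <- 1L + (scores$csn > q[1]) + (scores$csn > q[2]) +
    (scores$csn > q[3]) + (scores$csn > q[4])
  sizes <- tabulate(stratum, nbins = 5L)
  short <- which(sizes < per_stratum)
  if (length(short) > 0) {
    rlang::abort(sprintf(
      "stratum %d has only %d image(s); %d requested per stratum",
      short[1], sizes[short[1]], per_stratum
    ))
  }
  withr::with_seed(seed, {
    unlist(lapply(1:5, function(s) {
      ids <- scores$image_id[stratum == s]
      sample(ids, per_stratum)
    }))
  })
}

#' Read a panel ratings table
#'
#' CSV with header `rater_id,image_id,rating`.
#'
#' @param path CSV path.
#' @return Tibble with character ids and integer ratings.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("ratings file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("rater_id", "image_id", "rating") %in% names(df))) {
    rlang::abort(sprintf("ratings file %s needs columns rater_id,image_id,rating", path))
  }
  df$rater_id <- as.character(df$rater_id)
  df$image_id <- as.character(df$image_id)
  df$rating <- as.integer(df$rating)
  df
}
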