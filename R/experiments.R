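# End-to-end runners. Each accepts data frames or CSV paths (paths are read
# through the package's readers) and returns a gv_report whose every number
# is recomputable from the paired table it carries.

maybe_read <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else tibble::as_tibble(x)
}

new_report <- function(parts) {
  structure(parts, class = "gv_report")
}

#' Run the composed-image experiment
#'
#' Scores every image in a label table against the taxonomy, joins the CSN
#' scores to the images' Perceived Naturalness, and reports the CSN-PN
#' Pearson correlation with its Fisher-z confidence interval alongside corpus
#' summaries. Images present in only one of the two tables are reported as
#' dropped, never silently discarded.
#'
#' @param labels Label table (`image_id,label[,confidence]`) or CSV path.
#' @param pn PN table (`image_id,pn`, e.g. from [aggregate_pn()]) or CSV
#'   path; a `rating` column triggers aggregation via [aggregate_pn()] first.
#' @param taxonomy A `gv_taxonomy` or CSV path.
#' @param unknown Unknown-label policy for scoring.
#' @param alpha Significance level for the correlation CI.
#' @return A `gv_report` with elements `paired` (image_id, csn, pn),
#'   `correlation` (`gv_correlation`), `csn_summary`, `taxonomy_counts`,
#'   `dropped` (ids found in only one input) and `provenance`.
#' @export
run_experiment1 <- function(labels, pn, taxonomy, unknown = "strict",
                            alpha = 0.05) {
  labels <- maybe_read(labels, read_labels)
  taxonomy <- if (is.character(taxonomy)) load_taxonomy(taxonomy) else taxonomy
  pn <- maybe_read(pn, function(p) readr::read_csv(p, show_col_types = FALSE))
  if ("rating" %in% names(pn) && !"pn" %in% names(pn)) pn <- aggregate_pn(pn)
  if (!all(c("image_id", "pn") %in% names(pn))) {
    rlang::abort("pn table needs columns image_id, pn")
  }
  pn$image_id <- as.character(pn$image_id)
  scores <- score_images(labels, taxonomy, unknown = unknown)
  paired <- dplyr::inner_join(
    scores[c("image_id", "csn")], pn[c("image_id", "pn")],
    by = "image_id"
  )
  if (nrow(paired) == 0) rlang::abort("empty join: no image ids shared between labels and PN")
  dropped <- c(
    setdiff(scores$image_id, paired$image_id),
    setdiff(pn$image_id, paired$image_id)
  )
  new_report(list(
    experiment = "composed-image corpus",
    paired = paired,
    correlation = pearson_with_ci(paired$csn, paired$pn, alpha = alpha),
    csn_summary = summarize_scores(scores, labels),
    scores = scores,
    taxonomy_counts = count_by_class(taxonomy),
    dropped = dropped,
    provenance = list(
      alpha = alpha, unknown = unknown,
      config_hash = rlang::hash(list(unknown, alpha))
    )
  ))
}

#' Run the sampled-city experiment
#'
#' The full street-sampling pipeline on already-materialised tables: scores
#' the per-point label lists, summarises the CSN sign partition and label
#' counts, summarises point-to-panorama offsets, and then — depending on
#' which optional inputs are present — either draws the quintile-stratified
#' panel subsample (no ratings yet) or joins the panel's PN and reports the
#' CSN-PN correlation plus panel distribution, and joins the deprivation
#' lookup to report the CSN-vigintile correlation over linked points.
#'
#' @param points Sample-point table (`point_id,lon,lat,...`) or CSV path.
#' @param matches Panorama-match table or CSV path (optional, for the offset
#'   summary).
#' @param labels Label table keyed by `image_id == point_id`, or CSV path.
#' @param taxonomy A `gv_taxonomy` or CSV path.
#' @param ratings Optional ratings table (`rater_id,image_id,rating`) or
#'   path; when absent the report contains the stratified subsample instead
#'   of a PN block.
#' @param lookup Optional deprivation lookup (`point_id,vigintile`) or path.
#' @param per_stratum,subsample_seed Subsample design when `ratings` is
#'   absent.
#' @param unknown,alpha As in [run_experiment1()].
#' @return A `gv_report`; elements `pn_correlation`, `panel`,
#'   `deprivation_correlation`, `linked`, `subsample` are present according
#'   to the optional inputs.
#' @export
run_experiment2 <- function(points, labels, taxonomy, matches = NULL,
                            ratings = NULL, lookup = NULL,
                            per_stratum = 20L, subsample_seed = 1L,
                            unknown = "strict", alpha = 0.05) {
  points <- maybe_read(points, function(p) readr::read_csv(p, show_col_types = FALSE))
  labels <- maybe_read(labels, read_labels)
  taxonomy <- if (is.character(taxonomy)) load_taxonomy(taxonomy) else taxonomy
  scores <- score_images(labels, taxonomy, unknown = unknown)
  scores <- dplyr::rename(scores, point_id = "image_id")
  rep <- list(
    experiment = "sampled-city pipeline",
    scores = scores,
    csn_summary = summarize_scores(
      dplyr::rename(scores, image_id = "point_id"), labels
    ),
    taxonomy_counts = count_by_class(taxonomy),
    provenance = list(
      alpha = alpha, unknown = unknown,
      per_stratum = per_stratum, subsample_seed = subsample_seed,
      config_hash = rlang::hash(list(unknown, alpha, per_stratum, subsample_seed))
    )
  )
  if (!is.null(matches)) {
    matches <- maybe_read(matches, function(p) readr::read_csv(p, show_col_types = FALSE))
    rep$match_summary <- summarize_matches(matches)
  }
  if (is.null(ratings)) {
    rep$subsample <- stratified_quintile_subsample(
      dplyr::rename(scores, image_id = "point_id"),
      per_stratum = per_stratum, seed = subsample_seed
    )
  } else {
    ratings <- maybe_read(ratings, read_ratings)
    pn <- aggregate_pn(ratings)
    paired <- dplyr::inner_join(
      scores[c("point_id", "csn")],
      dplyr::rename(pn, point_id = "image_id"),
      by = "point_id"
    )
    if (nrow(paired) == 0) rlang::abort("empty join: ratings share no ids with scores")
    rep$paired <- paired
    rep$panel <- panel_distribution(paired)
    rep$pn_correlation <- pearson_with_ci(paired$csn, paired$pn, alpha = alpha)
  }
  if (!is.null(lookup)) {
    lookup <- maybe_read(lookup, read_deprivation_lookup)
    linked <- join_deprivation(scores, lookup)
    rep$linked <- linked
    ok <- linked[linked$linked, ]
    if (nrow(ok) >= 4) {
      rep$deprivation_correlation <- pearson_with_ci(ok$csn, ok$vigintile, alpha = alpha)
    }
  }
  new_report(rep)
}

#' Simulate and run the sampled-city experiment end to end
#'
#' Generates a synthetic world from `config`, samples points over its polygon
#' at the given spacing, matches panoramas, classifies the requested views,
#' rates the quintile-stratified subsample with the mock panel, builds the
#' deprivation lookup, and hands everything to [run_experiment2()].
#'
#' @param config A [world_config()].
#' @param spacing_deg Sampling grid spacing in decimal degrees.
#' @param per_stratum Panel subsample size per CSN quintile.
#' @return A `gv_report` (with the generated tables attached under
#'   `$inputs`).
#' @export
simulate_experiment2 <- function(config = world_config(), spacing_deg = 0.005,
                                 per_stratum = 20L) {
  world <- generate_world(config)
  points <- generate_sample_points(config$polygon,
    spacing_deg = spacing_deg,
    seed = str_seed("points", config$seed)
  )
  matches <- match_panoramas(points, world$panos)
  requests <- build_image_request(matches)
  labels <- mock_classifier(world, requests[c("point_id", "pano_id")])
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
  rep <- run_experiment2(
    points = points, labels = labels, taxonomy = world$taxonomy,
    matches = matches, ratings = ratings, lookup = lookup
  )
  rep$inputs <- list(
    points = points, matches = matches, labels = labels,
    ratings = ratings, lookup = lookup, world = world
  )
  rep
}

#' @export
print.gv_report <- function(x, ...) {
  cat(sprintf("<gv_report: %s>\n", x$experiment))
  s <- x$csn_summary
  cat(sprintf(
    "  images: %d  (CSN < 0: %d, = 0: %d, > 0: %d)\n",
    s$n_images, s$n_below_zero, s$n_zero, s$n_above_zero
  ))
  cat(sprintf(
    "  labels/image: mean %.2f sd %.2f range [%d, %d]\n",
    s$mean_labels_per_image, s$sd_labels_per_image, s$min_labels, s$max_labels
  ))
  for (nm in c("correlation", "pn_correlation", "deprivation_correlation")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %s: ", sub("_", " ", nm)))
      print(x[[nm]])
    }
  }
  if (!is.null(x$match_summary)) {
    cat(sprintf(
      "  pano offsets: mean %.0f m, sd %.0f, max %.0f\n",
      x$match_summary$mean_distance_m, x$match_summary$sd_distance_m,
      x$match_summary$max_distance_m
    ))
  }
  invisible(x)
}

#' Tidy an experiment report
#'
#' One row per correlation the report contains.
#'
#' @param x A `gv_report`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `conf.low`, `conf.high`,
#'   `p.value`, `n`.
#' @method tidy gv_report
#' @export
tidy.gv_report <- function(x, ...) {
  parts <- list(
    csn_pn = x$correlation %||% x$pn_correlation,
    csn_deprivation = x$deprivation_correlation
  )
  purrr::imap_dfr(purrr::compact(parts), function(cr, nm) {
    dplyr::mutate(tidy(cr), term = nm, .before = 1)
  })
}

#' One-row summary of an experiment report
#'
#' @param x A `gv_report`.
#' @param ... Unused.
#' @return One-row tibble combining the CSN summary with the headline
#'   correlation.
#' @importFrom generics glance
#' @method glance gv_report
#' @export
glance.gv_report <- function(x, ...) {
  cr <- x$correlation %||% x$pn_correlation
  out <- x$csn_summary
  if (!is.null(cr)) {
    out$r_csn_pn <- cr$r
    out$p_csn_pn <- cr$p_value
  }
  if (!is.null(x$deprivation_correlation)) {
    out$r_csn_deprivation <- x$deprivation_correlation$r
  }
  out
}

#' @export
generics::glance

#' Serialise a report to JSON
#'
#' Writes the report's numeric content (summaries, correlations, provenance,
#' and optionally the paired table) as a JSON document.
#'
#' @param report A `gv_report`.
#' @param path Output path.
#' @param include_paired Also embed the paired table.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, include_paired = TRUE) {
  keep <- list(
    experiment = report$experiment,
    csn_summary = report$csn_summary,
    taxonomy_counts = report$taxonomy_counts,
    correlations = tidy(report),
    match_summary = report$match_summary,
    panel = report$panel,
    provenance = report$provenance[setdiff(names(report$provenance), "config_hash")]
  )
  if (include_paired && !is.null(report$paired)) keep$paired <- report$paired
  jsonlite::write_json(purrr::compact(keep), path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
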