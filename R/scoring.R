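#' Calculated Semantic Naturalness of a single label list
#'
#' CSN summarises a classifier's label list for one image on a scale from -1
#' (every label names something artificial) to +1 (every label names something
#' natural):
#'
#'   CSN = N/T - A/T
#'
#' where N is the number of natural labels, A the number of artificial labels
#' and T the total number of labels. Ambiguous labels count only towards T,
#' pulling the score towards 0 without changing its sign. Each occurrence of a
#' duplicated label counts.
#'
#' @param labels Character vector of labels for one image (length >= 1).
#' @param taxonomy A `gv_taxonomy` tibble.
#' @param unknown Unknown-label policy passed to [classify_label()].
#' @return A one-row tibble with columns `csn`, `n_natural`, `n_artificial`,
#'   `n_ambiguous`, `n_total`.
#' @export
#' @examples
#' tax <- as_taxonomy(data.frame(
#'   label = c("tree", "grass", "road", "area"),
#'   class = c("natural", "natural", "artificial", "ambiguous")
#' ))
#' csn(c("tree", "grass", "road"), tax) # (2 - 1) / 3
csn <- function(labels, taxonomy, unknown = c("strict", "ambiguous")) {
  if (length(labels) < 1) rlang::abort("cannot score an image with no labels")
  cls <- classify_label(taxonomy, labels, unknown = match.arg(unknown))
  n_nat <- sum(cls == "natural")
  n_art <- sum(cls == "artificial")
  n_amb <- sum(cls == "ambiguous")
  n_tot <- length(cls)
  tibble::tibble(
    csn = (n_nat - n_art) / n_tot,
    n_natural = n_nat, n_artificial = n_art,
    n_ambiguous = n_amb, n_total = n_tot
  )
}

#' Score a batch of images
#'
#' Takes a long table with one row per (image, label) occurrence and returns
#' one CSN score row per image, in first-appearance order of `image_id`.
#' Confidence scores, if present, are ignored by the statistic; an optional
#' minimum-confidence filter is available for sensitivity analysis.
#'
#' @param labels_df Data frame with columns `image_id`, `label` and optionally
#'   `confidence` in \[0, 1\].
#' @param taxonomy A `gv_taxonomy` tibble.
#' @param unknown Unknown-label policy; under `"strict"` an unknown label
#'   aborts the batch naming the image, under `"ambiguous"` it is routed to
#'   the ambiguous class.
#' @param min_confidence If non-`NULL`, label rows with confidence below this
#'   threshold are dropped before scoring (default: no filtering). Images left
#'   with zero labels by the filter are an error.
#' @return Tibble with columns `image_id`, `csn`, `n_natural`, `n_artificial`,
#'   `n_ambiguous`, `n_total`.
#' @export
score_images <- function(labels_df, taxonomy, unknown = c("strict", "ambiguous"),
                         min_confidence = NULL) {
  stopifnot(is.data.frame(labels_df))
  unknown <- match.arg(unknown)
  if (!all(c("image_id", "label") %in% names(labels_df))) {
    rlang::abort("labels need columns `image_id` and `label`")
  }
  if (nrow(labels_df) == 0) rlang::abort("empty label table")
  df <- tibble::as_tibble(labels_df)
  ids <- unique(df$image_id)
  if (!is.null(min_confidence)) {
    if (!"confidence" %in% names(df)) {
      rlang::abort("min_confidence given but no `confidence` column present")
    }
    df <- dplyr::filter(df, .data$confidence >= min_confidence)
    gone <- setdiff(ids, unique(df$image_id))
    if (length(gone) > 0) {
      rlang::abort(sprintf(
        "confidence filter left image(s) with no labels: %s",
        paste(utils::head(gone, 5), collapse = ", ")
      ))
    }
  }
  if (any(is.na(df$label) | !nzchar(as.character(df$label)))) {
    bad <- unique(df$image_id[is.na(df$label) | !nzchar(as.character(df$label))])
    rlang::abort(sprintf(
      "empty/missing label for image(s): %s", paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  if (unknown == "strict") {
    key <- normalize_label(df$label)
    miss <- unique(df$image_id[!key %in% taxonomy$label])
    if (length(miss) > 0) {
      rlang::abort(sprintf(
        "unknown label(s) under strict policy in image(s): %s",
        paste(utils::head(miss, 5), collapse = ", ")
      ))
    }
  }
  cls <- classify_label(taxonomy, df$label, unknown = unknown)
  out <- df |>
    dplyr::mutate(.class = cls) |>
    dplyr::summarise(
      n_natural = sum(.data$.class == "natural"),
      n_artificial = sum(.data$.class == "artificial"),
      n_ambiguous = sum(.data$.class == "ambiguous"),
      n_total = dplyr::n(),
      .by = "image_id"
    ) |>
    dplyr::mutate(
      csn = (.data$n_natural - .data$n_artificial) / .data$n_total
    ) |>
    dplyr::select(
      "image_id", "csn", "n_natural", "n_artificial", "n_ambiguous", "n_total"
    )
  out[match(ids, out$image_id), , drop = FALSE]
}

#' Corpus-level summary of CSN scores
#'
#' Partitions images exactly by the sign of CSN (the zero class is decided on
#' the integer counts, `n_natural == n_artificial`, never by floating-point
#' comparison) and summarises the per-image label counts. The label-count
#' standard deviation uses the sample (n - 1) denominator and is reported as 0
#' with `sd_undefined = TRUE` when only one image is present.
#'
#' @param scores Tibble from [score_images()] (needs `csn`, `n_natural`,
#'   `n_artificial`, `n_total`).
#' @param labels_df Optional original label table; if supplied the number of
#'   distinct (normalized) label strings is reported.
#' @return One-row tibble: `n_images`, `n_below_zero`, `n_zero`,
#'   `n_above_zero`, `mean_labels_per_image`, `sd_labels_per_image`,
#'   `min_labels`, `max_labels`, `n_distinct_labels`, `sd_undefined`.
#' @export
summarize_scores <- function(scores, labels_df = NULL) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1)
  n <- nrow(scores)
  diff <- scores$n_natural - scores$n_artificial
  sd_lab <- if (n > 1) stats::sd(scores$n_total) else 0
  tibble::tibble(
    n_images = n,
    n_below_zero = sum(diff < 0),
    n_zero = sum(diff == 0),
    n_above_zero = sum(diff > 0),
    mean_labels_per_image = mean(scores$n_total),
    sd_labels_per_image = sd_lab,
    min_labels = min(scores$n_total),
    max_labels = max(scores$n_total),
    n_distinct_labels = if (is.null(labels_df)) {
      NA_integer_
    } else {
      length(unique(normalize_label(labels_df$label)))
    },
    sd_undefined = n == 1
  )
}

#' Read a per-image label table
#'
#' CSV with header `image_id,label[,confidence]`, one row per (image, label)
#' occurrence.
#'
#' @param path CSV path.
#' @return Tibble with `image_id`, `label` and `confidence` if present.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("labels file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("image_id", "label") %in% names(df))) {
    rlang::abort(sprintf("labels file %s needs columns image_id,label", path))
  }
  df$image_id <- as.character(df$image_id)
  df
}

#' Write CSN scores to CSV
#'
#' @param scores Tibble from [score_images()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(scores, path, progress = FALSE)
  invisible(path)
}
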