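#' Semantic classes for classifier labels
#'
#' Every label a classifier can emit is curated by a human into exactly one of
#' three broad semantic classes: `"natural"`, `"artificial"` or `"ambiguous"`.
#' There is no "unknown" class; a label absent from a taxonomy is an error
#' condition handled by the unknown-label policy of the scoring functions.
#'
#' @return Character vector of the three admissible class tokens.
#' @export
semantic_classes <- function() c("natural", "artificial", "ambiguous")

#' Normalize a label string
#'
#' Lowercases, trims leading/trailing whitespace and collapses internal runs of
#' whitespace to a single space, so that e.g. `"Residential  Area "` and
#' `"residential area"` denote the same taxonomy entry.
#'
#' @param x Character vector of labels.
#' @return Character vector of normalized labels.
#' @export
normalize_label <- function(x) {
  stringr::str_squish(stringr::str_to_lower(x))
}

new_taxonomy <- function(df, provenance = NA_character_) {
  out <- tibble::new_tibble(df, class = "gv_taxonomy")
  attr(out, "provenance") <- provenance
  out
}

#' Build a label taxonomy from a data frame
#'
#' The taxonomy is the registry mapping each classifier label to its semantic
#' class. Labels are normalized (see [normalize_label()]); duplicate rows that
#' agree on the class are collapsed, while a label mapped to two different
#' classes is an error.
#'
#' @param df Data frame with columns `label` and `class` (class tokens are
#'   matched case-insensitively against [semantic_classes()]).
#' @param provenance Free-text note on where the table came from.
#' @return A `gv_taxonomy` tibble with columns `label`, `class`.
#' @export
#' @examples
#' as_taxonomy(data.frame(
#'   label = c("tree", "road", "area"),
#'   class = c("natural", "artificial", "ambiguous")
#' ))
as_taxonomy <- function(df, provenance = NA_character_) {
  stopifnot(is.data.frame(df))
  if (!all(c("label", "class") %in% names(df))) {
    rlang::abort("taxonomy needs columns `label` and `class`")
  }
  tab <- tibble::as_tibble(df) |>
    dplyr::transmute(
      label = normalize_label(.data$label),
      class = stringr::str_to_lower(stringr::str_trim(.data$class))
    )
  bad <- which(!tab$class %in% semantic_classes())
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "unrecognized class token '%s' in row %d (label '%s')",
      tab$class[bad[1]], bad[1], tab$label[bad[1]]
    ))
  }
  if (any(tab$label == "")) rlang::abort("empty label string in taxonomy")
  tab <- dplyr::distinct(tab)
  dup <- tab$label[duplicated(tab$label)]
  if (length(dup) > 0) {
    rlang::abort(sprintf(
      "label(s) mapped to conflicting classes: %s",
      paste(unique(dup), collapse = ", ")
    ))
  }
  if (nrow(tab) == 0) rlang::abort("empty taxonomy is not allowed")
  new_taxonomy(tab, provenance)
}

#' Load a label taxonomy from a CSV file
#'
#' Reads a two-column CSV (header `label,class`) mapping classifier labels to
#' semantic classes. Other column names can be mapped via `label_col` /
#' `class_col` to tolerate supplementary-file dialects.
#'
#' @param path Path to the CSV file.
#' @param label_col,class_col Column names holding the label and class if they
#'   differ from `label` / `class`.
#' @return A `gv_taxonomy` tibble.
#' @export
load_taxonomy <- function(path, label_col = "label", class_col = "class") {
  if (!file.exists(path)) rlang::abort(sprintf("taxonomy file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c(label_col, class_col) %in% names(raw))) {
    rlang::abort(sprintf(
      "taxonomy file %s lacks columns '%s'/'%s' (has: %s)",
      path, label_col, class_col, paste(names(raw), collapse = ", ")
    ))
  }
  df <- tibble::tibble(label = raw[[label_col]], class = raw[[class_col]])
  as_taxonomy(df, provenance = path)
}

#' Write a taxonomy to CSV
#'
#' Inverse of [load_taxonomy()]: `load_taxonomy(save_taxonomy(tax, f))` yields
#' a taxonomy identical to `tax`.
#'
#' @param taxonomy A `gv_taxonomy` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_taxonomy <- function(taxonomy, path) {
  stopifnot(inherits(taxonomy, "gv_taxonomy"))
  readr::write_csv(taxonomy[c("label", "class")], path, progress = FALSE)
  invisible(path)
}

#' Look up the semantic class of labels
#'
#' @param taxonomy A `gv_taxonomy` tibble.
#' @param label Character vector of labels (normalized before lookup).
#' @param unknown Policy for labels absent from the taxonomy: `"strict"`
#'   (default) raises an error naming the offending labels;
#'   `"ambiguous"` routes them to the ambiguous class with a warning.
#' @return Character vector of classes, same length as `label`.
#' @export
#' @examples
#' tax <- as_taxonomy(data.frame(label = "tree", class = "natural"))
#' classify_label(tax, "Tree")
classify_label <- function(taxonomy, label, unknown = c("strict", "ambiguous")) {
  stopifnot(inherits(taxonomy, "gv_taxonomy"))
  unknown <- match.arg(unknown)
  key <- normalize_label(label)
  if (any(!nzchar(key))) rlang::abort("empty label cannot be classified")
  cls <- taxonomy$class[match(key, taxonomy$label)]
  miss <- is.na(cls)
  if (any(miss)) {
    missing_labels <- unique(key[miss])
    if (unknown == "strict") {
      rlang::abort(sprintf(
        "label(s) not in taxonomy: %s",
        paste(utils::head(missing_labels, 10), collapse = ", ")
      ))
    }
    rlang::warn(sprintf(
      "%d unknown label(s) treated as ambiguous (e.g. %s)",
      length(missing_labels), paste(utils::head(missing_labels, 3), collapse = ", ")
    ))
    cls[miss] <- "ambiguous"
  }
  cls
}

#' Count taxonomy entries per semantic class
#'
#' @param taxonomy A `gv_taxonomy` tibble.
#' @return One-row tibble with columns `natural`, `artificial`, `ambiguous`
#'   and `total`; the three class counts always sum to `total`.
#' @export
count_by_class <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "gv_taxonomy"))
  counts <- table(factor(taxonomy$class, levels = semantic_classes()))
  tibble::tibble(
    natural = as.integer(counts[["natural"]]),
    artificial = as.integer(counts[["artificial"]]),
    ambiguous = as.integer(counts[["ambiguous"]]),
    total = nrow(taxonomy)
  )
}

#' Bundled taxonomy of frequent street-scene labels
#'
#' A small curated registry covering the 60 most frequent street-scene labels
#' (20 per semantic class) that urban imagery classifiers commonly return,
#' e.g. "tree", "grass" and "waterway" (natural); "residential area", "road"
#' and "vehicle" (artificial); "area", "horizon" and "lane" (ambiguous). This
#' is also the default vocabulary pool of the synthetic-world generator, so
#' synthetic label files always resolve under it.
#'
#' @return A `gv_taxonomy` tibble with 60 entries.
#' @export
default_taxonomy <- function() {
  load_taxonomy(system.file("extdata", "street_label_taxonomy.csv",
    package = "greenview", mustWork = TRUE
  ))
}
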