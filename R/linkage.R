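#' Join CSN scores to deprivation vigintiles
#'
#' Links each scored sample point to its small-area deprivation vigintile
#' (a 20-quantile band, 1 = most deprived through 20 = least deprived, or the
#' reverse — the statistic is agnostic) through a deterministic lookup table,
#' the offline stand-in for reverse geocoding a point to a postcode and then
#' to a deprivation data zone. Every input point is emitted: points absent
#' from the lookup are carried through with `linked = FALSE` and an `NA`
#' vigintile, never silently dropped.
#'
#' @param scores Tibble keyed by `point_id` with a `csn` column.
#' @param lookup Tibble with `point_id` and `vigintile` (integers 1-20;
#'   optional `postcode`/`datazone` pass-through columns are ignored here).
#' @return Tibble `point_id`, `csn`, `vigintile`, `linked` with attributes
#'   `n_linked` / `n_unlinked` (also recomputable from the `linked` column).
#' @export
join_deprivation <- function(scores, lookup) {
  stopifnot(
    is.data.frame(scores), all(c("point_id", "csn") %in% names(scores)),
    is.data.frame(lookup)
  )
  if (!all(c("point_id", "vigintile") %in% names(lookup))) {
    rlang::abort("lookup needs columns point_id, vigintile")
  }
  if (nrow(lookup) > 0) {
    bad <- !(lookup$vigintile %in% 1:20)
    if (any(bad)) {
      rlang::abort(sprintf(
        "vigintile out of 1-20 range for point '%s' (value %s)",
        lookup$point_id[which(bad)[1]], lookup$vigintile[which(bad)[1]]
      ))
    }
    if (anyDuplicated(lookup$point_id)) {
      rlang::abort("lookup maps some point_id more than once")
    }
  }
  out <- tibble::as_tibble(scores)[c("point_id", "csn")] |>
    dplyr::left_join(
      tibble::as_tibble(lookup)[c("point_id", "vigintile")],
      by = "point_id"
    ) |>
    dplyr::mutate(linked = !is.na(.data$vigintile))
  attr(out, "n_linked") <- sum(out$linked)
  attr(out, "n_unlinked") <- sum(!out$linked)
  out
}

#' Read a deprivation lookup table
#'
#' CSV with header `point_id,vigintile` plus optional `postcode` and
#' `datazone` pass-through columns.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_deprivation_lookup <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("lookup file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("point_id", "vigintile") %in% names(df))) {
    rlang::abort(sprintf("lookup file %s needs columns point_id,vigintile", path))
  }
  df$point_id <- as.character(df$point_id)
  df$vigintile <- as.integer(df$vigintile)
  df
}
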