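# Shared fixtures, all built in code.

# minimal taxonomy used by the toy scoring tests
toy_taxonomy <- function() {
  as_taxonomy(data.frame(
    label = c("tree", "grass", "cloud", "road", "vehicle", "horizon", "area"),
    class = c(
      "natural", "natural", "natural", "artificial", "artificial",
      "ambiguous", "ambiguous"
    )
  ))
}

# a small world (eighth of the default area, thinner street net) so unit
# tests stay fast; statistical parameters keep their defaults
tiny_world_config <- function(seed = 1L, pano_spacing_m = 25, ...) {
  world_config(
    polygon = polygon_rect(-3.20, -3.14, 55.90, 55.94),
    street_segment_count = 90L,
    pano_spacing_m = pano_spacing_m,
    seed = seed,
    ...
  )
}

# independent brute-force CSN: per-label lookup loop and integer counting,
# sharing no code with csn()/score_images()
oracle_csn <- function(labels, tax_df) {
  n <- 0L; a <- 0L
  for (lb in labels) {
    key <- tolower(trimws(gsub("\\s+", " ", lb)))
    cls <- tax_df$class[tax_df$label == key]
    if (cls == "natural") n <- n + 1L
    if (cls == "artificial") a <- a + 1L
  }
  (n - a) / length(labels)
}

# independent two-pass Pearson correlation oracle
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random label multisets over the toy taxonomy
random_label_multiset <- function(max_len = 12L) {
  pool <- c("tree", "grass", "cloud", "road", "vehicle", "horizon", "area")
  sample(pool, sample.int(max_len, 1), replace = TRUE)
}
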