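test_that("csn reproduces direct formula substitutions", {
  tax <- toy_taxonomy()
  expect_equal(csn(c("tree", "grass", "cloud"), tax)$csn, 1)
  expect_equal(csn(c("road", "vehicle"), tax)$csn, -1)
  # 5 natural, 2 artificial, 1 ambiguous out of 8
  labs <- c("tree", "tree", "grass", "cloud", "grass", "road", "vehicle", "area")
  out <- csn(labs, tax)
  expect_equal(out$csn, 0.375)
  expect_equal(out$n_total, 8L)
  expect_equal(out$n_natural + out$n_artificial + out$n_ambiguous, out$n_total)
  expect_equal(csn(c("tree", "road"), tax)$csn, 0)
  expect_error(csn(character(), tax), "no labels")
})

test_that("csn is bounded, permutation-invariant and matches the brute-force oracle", {
  tax <- toy_taxonomy()
  tax_df <- as.data.frame(tax)
  withr::with_seed(42, {
    for (i in 1:200) {
      labs <- random_label_multiset()
      got <- csn(labs, tax)$csn
      expect_gte(got, -1)
      expect_lte(got, 1)
      expect_identical(got, csn(sample(labs), tax)$csn)
      expect_identical(got, oracle_csn(labs, tax_df))
    }
  })
})

test_that("appending labels moves csn in the expected direction", {
  tax <- toy_taxonomy()
  withr::with_seed(7, {
    for (i in 1:50) {
      labs <- random_label_multiset()
      base <- csn(labs, tax)$csn
      up <- csn(c(labs, "tree"), tax)$csn
      down <- csn(c(labs, "road"), tax)$csn
      mid <- csn(c(labs, "area"), tax)$csn
      if (base < 1) expect_gt(up, base)
      if (base > -1) expect_lt(down, base)
      if (base != 0) {
        expect_lt(abs(mid), abs(base))
        expect_equal(sign(mid), sign(base))
      } else {
        expect_equal(mid, 0)
      }
    }
  })
})

test_that("score_images preserves order, reports context and respects policy", {
  tax <- toy_taxonomy()
  labels <- tibble::tibble(
    image_id = c("c", "c", "a", "b"),
    label = c("tree", "road", "vehicle", "area")
  )
  out <- score_images(labels, tax)
  expect_equal(out$image_id, c("c", "a", "b")) # first-appearance order
  expect_equal(out$csn, c(0, -1, 0))

  bad <- tibble::tibble(image_id = "x", label = "spaceship")
  expect_error(score_images(bad, tax), "x")
  expect_warning(out2 <- score_images(bad, tax, unknown = "ambiguous"))
  expect_equal(out2$csn, 0)
  expect_error(score_images(labels[0, ], tax), "empty")
})

test_that("confidence filtering is optional and guarded", {
  tax <- toy_taxonomy()
  labels <- tibble::tibble(
    image_id = c("a", "a", "b"),
    label = c("tree", "road", "road"),
    confidence = c(0.9, 0.3, 0.2)
  )
  # default: confidences ignored entirely
  expect_equal(score_images(labels, tax)$csn, c(0, -1))
  out <- score_images(labels[labels$image_id == "a", ], tax, min_confidence = 0.5)
  expect_equal(out$csn, 1)
  # an image losing all labels to the filter is an error, not a silent drop
  expect_error(score_images(labels, tax, min_confidence = 0.5), "b")
  expect_error(
    score_images(labels[, c("image_id", "label")], tax, min_confidence = 0.5),
    "confidence"
  )
})

test_that("summarize_scores partitions by exact integer sign", {
  tax <- toy_taxonomy()
  labels <- tibble::tibble(
    image_id = rep(c("a", "b", "c"), c(2, 2, 4)),
    label = c(
      "road", "tree", # a: 0
      "tree", "grass", # b: +1
      "road", "road", "vehicle", "tree" # c: -0.5
    )
  )
  s <- summarize_scores(score_images(labels, tax), labels)
  expect_equal(s$n_below_zero, 1)
  expect_equal(s$n_zero, 1)
  expect_equal(s$n_above_zero, 1)
  expect_equal(s$n_below_zero + s$n_zero + s$n_above_zero, s$n_images)
  expect_equal(s$min_labels, 2)
  expect_equal(s$max_labels, 4)
  expect_equal(s$n_distinct_labels, 4)
  expect_true(s$min_labels <= s$mean_labels_per_image)
  expect_true(s$mean_labels_per_image <= s$max_labels)

  one <- summarize_scores(score_images(labels[1:2, ], tax))
  expect_equal(one$sd_labels_per_image, 0)
  expect_true(one$sd_undefined)
})

test_that("scores round-trip through CSV", {
  tax <- toy_taxonomy()
  labels <- tibble::tibble(image_id = c("a", "a"), label = c("tree", "road"))
  scores <- score_images(labels, tax)
  f <- withr::local_tempfile(fileext = ".csv")
  write_scores(scores, f)
  lf <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(labels, lf)
  expect_equal(read_labels(lf)$label, labels$label)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$csn, scores$csn)
})
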