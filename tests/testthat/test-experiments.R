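make_toy_exp1 <- function() {
  tax <- toy_taxonomy()
  # 10 images with graded naturalness
  labels <- purrr::map_dfr(1:10, function(i) {
    n_nat <- i - 1
    n_art <- 10 - i
    tibble::tibble(
      image_id = sprintf("im%02d", i),
      label = c(rep("tree", n_nat), rep("road", n_art), "area")
    )
  })
  pn <- tibble::tibble(
    image_id = sprintf("im%02d", 1:10),
    pn = c(1.2, 1.8, 2.1, 3.0, 3.3, 4.1, 4.9, 5.6, 6.2, 6.8)
  )
  list(tax = tax, labels = labels, pn = pn)
}

test_that("the composed-image runner reports a hand-checkable correlation", {
  fx <- make_toy_exp1()
  rep <- run_experiment1(fx$labels, fx$pn, fx$tax)
  expect_s3_class(rep, "gv_report")
  expect_equal(nrow(rep$paired), 10)
  # r recomputable by the independent oracle from the paired table
  expect_equal(rep$correlation$r, oracle_pearson(rep$paired$csn, rep$paired$pn),
    tolerance = 1e-12
  )
  expect_gt(rep$correlation$r, 0.9) # graded design is near-linear
  expect_equal(rep$csn_summary$n_images, 10)
  expect_length(rep$dropped, 0)
  g <- glance(rep)
  expect_equal(g$r_csn_pn, rep$correlation$r)
})

test_that("the runner reports one-sided ids and rejects empty joins", {
  fx <- make_toy_exp1()
  pn_extra <- dplyr::bind_rows(fx$pn, tibble::tibble(image_id = "ghost", pn = 4))
  rep <- run_experiment1(fx$labels, pn_extra, fx$tax)
  expect_equal(rep$dropped, "ghost")
  pn_disjoint <- tibble::tibble(image_id = c("x1", "x2"), pn = c(1, 2))
  expect_error(run_experiment1(fx$labels, pn_disjoint, fx$tax), "empty join")
})

test_that("runners accept file inputs through the same readers", {
  fx <- make_toy_exp1()
  lf <- withr::local_tempfile(fileext = ".csv")
  pf <- withr::local_tempfile(fileext = ".csv")
  tf <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(fx$labels, lf)
  readr::write_csv(fx$pn, pf)
  save_taxonomy(fx$tax, tf)
  rep <- run_experiment1(lf, pf, tf)
  expect_equal(rep$correlation$r, run_experiment1(fx$labels, fx$pn, fx$tax)$correlation$r)
})

test_that("the sampled-city runner handles optional blocks by contract", {
  rep <- simulate_experiment2(tiny_world_config(seed = 31L), per_stratum = 5L)
  # with ratings: PN join present, subsample absent
  expect_false(is.null(rep$pn_correlation))
  expect_null(rep$subsample)
  expect_equal(nrow(rep$paired), 25)
  expect_gt(rep$pn_correlation$r, 0)
  expect_false(is.null(rep$deprivation_correlation))
  # linked + unlinked partition the points
  expect_equal(
    attr(rep$linked, "n_linked") + attr(rep$linked, "n_unlinked"),
    nrow(rep$scores)
  )

  # without ratings: subsample present, PN block absent
  inp <- rep$inputs
  rep2 <- run_experiment2(
    points = inp$points, labels = inp$labels,
    taxonomy = inp$world$taxonomy, matches = inp$matches,
    per_stratum = 5L, subsample_seed = 2L
  )
  expect_null(rep2$pn_correlation)
  expect_length(rep2$subsample, 25)
  expect_false(is.null(rep2$csn_summary))
})

test_that("experiment runs are pure functions of inputs and seeds", {
  a <- simulate_experiment2(tiny_world_config(seed = 33L), per_stratum = 5L)
  b <- simulate_experiment2(tiny_world_config(seed = 33L), per_stratum = 5L)
  a$inputs <- NULL
  b$inputs <- NULL
  expect_identical(unclass(a)[sort(names(a))], unclass(b)[sort(names(b))])
})

test_that("reports serialize to JSON with their numbers intact", {
  fx <- make_toy_exp1()
  rep <- run_experiment1(fx$labels, fx$pn, fx$tax)
  f <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$correlations$estimate, rep$correlation$r, tolerance = 1e-12)
  expect_equal(nrow(back$paired), 10)
})

test_that("plots build and write deterministic files", {
  rep <- simulate_experiment2(tiny_world_config(seed = 35L), per_stratum = 5L)
  p1 <- plot_pn_vs_csn(rep$paired)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
  pts <- dplyr::inner_join(rep$inputs$points, rep$scores, by = "point_id")
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  plot_map(pts, rep$inputs$matches, rep$linked, out_path = f1)
  plot_map(pts, rep$inputs$matches, rep$linked, out_path = f2)
  expect_gt(file.size(f1), 0)
  expect_identical(
    readBin(f1, "raw", file.size(f1)),
    readBin(f2, "raw", file.size(f2))
  )
  # layers degrade gracefully without linkage/matches
  expect_s3_class(plot_map(pts), "ggplot")
})
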