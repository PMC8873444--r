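# Masked Otsu thresholding, reference biasing and area-ratio PI.

test_that("Otsu separates a bimodal masked histogram", {
  set.seed(1)
  ch <- matrix(sample(c(0.1, 0.9), 400, replace = TRUE), 20, 20)
  mask <- matrix(TRUE, 20, 20)
  t <- as.numeric(otsu_in_mask(ch, mask))
  expect_gt(t, 0.1)
  expect_lt(t, 0.9)
})

test_that("masking changes the threshold when it excludes a mode", {
  ch <- matrix(0.05, 30, 30)
  ch[, 16:30] <- 0.95
  ch[, 1:15] <- ch[, 1:15] + seq(0, 0.02, length.out = 15)[col(ch[, 1:15])]
  full_t <- as.numeric(otsu_in_mask(ch, matrix(TRUE, 30, 30)))
  low_mask <- matrix(FALSE, 30, 30); low_mask[, 1:15] <- TRUE
  low_t <- as.numeric(otsu_in_mask(ch, low_mask))
  # masked threshold falls inside the low mode; the full-image threshold
  # separates the two modes (foreground rule is value > t)
  expect_lt(low_t, 0.07)
  expect_gt(full_t, max(ch[low_mask]))
  expect_lt(full_t, 0.95)
  expect_false(isTRUE(all.equal(full_t, low_t)))
})

test_that("Otsu agrees with exhaustive between-class-variance search", {
  set.seed(23)
  for (rep in 1:20) {
    vals <- c(rnorm(150, 0.2, 0.05), rnorm(80, 0.7, 0.08))
    vals <- pmax(vals, 0)
    ch <- matrix(vals, 23, 10)
    t_impl <- as.numeric(otsu_in_mask(ch, matrix(TRUE, 23, 10)))
    t_oracle <- brute_otsu(vals)
    expect_equal(t_impl, t_oracle, tolerance = 1e-9)
  }
})

test_that("degenerate Otsu inputs raise explicit errors", {
  ch <- matrix(0.5, 10, 10)
  expect_error(otsu_in_mask(ch, matrix(FALSE, 10, 10)), "empty mask")
  expect_error(otsu_in_mask(ch, matrix(TRUE, 10, 10)), "degenerate histogram")
})

test_that("reference thresholds average per-slide masked Otsu", {
  slides <- lapply(c(31L, 32L), function(sd) {
    generate_slide(small_config(seed = sd, target_pi = 0.3))
  })
  imgs <- lapply(slides, `[[`, "image")
  rois <- lapply(slides, `[[`, "roi_truth")
  ref <- reference_thresholds(imgs, rois)
  expect_equal(ref$provenance, "reference")
  per <- attr(ref, "per_slide")
  expect_equal(nrow(per), 2L)
  expect_equal(ref$t_dab, mean(per$t_dab))
  one <- reference_thresholds(imgs[1], rois[1])
  expect_equal(one$t_dab, per$t_dab[1])
  # empty ground-truth ROI slides are skipped with a warning
  empty <- roi_mask(matrix(FALSE, img_height(imgs[[1]]), img_width(imgs[[1]])))
  expect_warning(
    both <- reference_thresholds(imgs, list(rois[[1]], empty)),
    "empty ground-truth ROI"
  )
  expect_equal(both$t_dab, per$t_dab[1])
  expect_error(
    suppressWarnings(reference_thresholds(imgs[1], list(empty))),
    "no usable training slides"
  )
})

test_that("threshold combination is a per-channel convex blend", {
  own <- stain_thresholds(0.2, 0.3, "otsu")
  ref <- stain_thresholds(0.4, 0.5, "reference")
  expect_equal(combine_thresholds(own, ref, 0)$t_dab, 0.2)
  expect_equal(combine_thresholds(own, ref, 1)$t_dab, 0.4)
  mid <- combine_thresholds(own, ref, 0.5)
  expect_equal(mid$t_dab, 0.3)
  expect_equal(mid$t_hema, 0.4)
  expect_equal(mid$provenance, "biased")
})

test_that("degenerate PI compositions segment to the extremes", {
  all_dab <- generate_slide(small_config(seed = 41L, target_pi = 1))
  est1 <- segment_and_estimate(all_dab$image, all_dab$roi_truth)
  expect_gte(est1$pi, 0.97)
  no_dab <- generate_slide(small_config(seed = 42L, target_pi = 0))
  est0 <- segment_and_estimate(no_dab$image, no_dab$roi_truth)
  expect_lte(est0$pi, 0.03)
})

test_that("PI estimates respect their structural invariants", {
  s <- generate_slide(small_config(seed = 43L, target_pi = 0.35))
  est <- segment_and_estimate(s$image, s$roi_truth)
  expect_lte(est$dab_area, est$relevant_area)
  expect_gte(est$pi, 0)
  expect_lte(est$pi, 1)
  expect_false(est$roi_fallback)
  expect_equal(est$method, "roi")
})

test_that("an empty ROI falls back to whole-image segmentation", {
  s <- generate_slide(small_config(seed = 44L, target_pi = 0.3))
  empty <- roi_mask(matrix(FALSE, img_height(s$image), img_width(s$image)))
  est <- segment_and_estimate(s$image, empty)
  expect_true(est$roi_fallback)
  full <- segment_and_estimate(s$image, roi = NULL, method = "roi")
  expect_equal(est$pi, full$pi)
})

test_that("a fully blank image yields the no-cells error", {
  expect_error(
    segment_and_estimate(flat_slide(255L),
                         thresholds = stain_thresholds(0.5, 0.5, "reference")),
    "no cells segmented"
  )
})

test_that("DAB blobs outside the ROI cannot move the ROI-restricted PI", {
  cfg0 <- small_config(seed = 45L, target_pi = 0.3, artifact_count = 0L)
  cfga <- small_config(seed = 45L, target_pi = 0.3, artifact_count = 2L,
                       artifact_stain = "dab")
  s0 <- generate_slide(cfg0)
  sa <- generate_slide(cfga)
  # same seed: nuclei identical, artifacts appended outside the ROI truth
  e0 <- segment_and_estimate(s0$image, s0$roi_truth)
  ea <- segment_and_estimate(sa$image, sa$roi_truth)
  expect_lt(abs(ea$pi - e0$pi), 0.005)
  b0 <- segment_and_estimate(s0$image)
  ba <- segment_and_estimate(sa$image)
  expect_gt(abs(ba$pi - b0$pi), 0.01)   # base method is measurably biased
})

test_that("estimates serialize to JSON sidecars", {
  dir <- withr::local_tempdir()
  s <- generate_slide(small_config(seed = 46L, target_pi = 0.2))
  est <- segment_and_estimate(s$image, s$roi_truth)
  p <- file.path(dir, "est.json")
  write_estimate_json(est, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$pi, est$pi)
  expect_equal(back$method, "roi")
  expect_equal(back$thresholds$provenance, "otsu")
})
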