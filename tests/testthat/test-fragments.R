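# Sliding-window tiling and fragment labeling.

test_that("grid origin counts match the closed form", {
  g1 <- build_grid(96, 96, 96, 16)
  expect_equal(nrow(g1$origins), 1L)
  expect_equal(c(g1$origins$row, g1$origins$col), c(0L, 0L))

  g2 <- build_grid(128, 128, 96, 16)
  expect_equal(nrow(g2$origins), 9L)   # (floor(32/16)+1)^2

  g3 <- build_grid(192, 192, 192, 192)
  expect_equal(nrow(g3$origins), 1L)

  expect_error(build_grid(64, 64, 96, 16), "larger than image")
  expect_error(build_grid(64, 64, 32, 0), "stride")
})

test_that("origin count closed form holds over random geometries", {
  set.seed(5)
  for (i in 1:25) {
    h <- sample(20:200, 1); w <- sample(20:200, 1)
    win <- sample(5:min(h, w), 1); s <- sample(1:win, 1)
    g <- build_grid(h, w, win, s)
    expected <- (floor((h - win) / s) + 1) * (floor((w - win) / s) + 1)
    expect_equal(nrow(g$origins), expected)
    # windows fully inside, row-major order
    expect_true(all(g$origins$row + win <= h))
    expect_true(all(g$origins$col + win <= w))
    expect_true(!is.unsorted(g$origins$row))
  }
})

test_that("fragment labels follow at-least-one-relevant-cell membership", {
  g <- build_grid(96, 96, 96, 16)
  center <- annotation_set(data.frame(x = 48, y = 48, label = "dab_positive"))
  expect_equal(label_fragments(g, center), 1L)
  none <- annotation_set(data.frame(x = numeric(), y = numeric(),
                                    label = character()))
  expect_equal(label_fragments(g, none), 0L)
  # either stain class is a relevant cell
  neg <- annotation_set(data.frame(x = 48, y = 48, label = "hematoxylin_only"))
  expect_equal(label_fragments(g, neg), 1L)
})

test_that("boundary nuclei follow half-open window membership (brute force)", {
  g <- build_grid(128, 128, 64, 64)     # 2 x 2 non-overlapping windows
  # nucleus exactly on the shared boundary x = 64
  ann <- annotation_set(data.frame(x = 64, y = 10, label = "dab_positive"))
  labels <- label_fragments(g, ann)
  brute <- vapply(seq_len(nrow(g$origins)), function(i) {
    r <- g$origins$row[i]; cc <- g$origins$col[i]
    as.integer(10 >= r && 10 < r + 64 && 64 >= cc && 64 < cc + 64)
  }, integer(1))
  expect_identical(labels, brute)
  expect_equal(sum(labels), 1L)         # belongs to exactly one window

  set.seed(31)
  g2 <- build_grid(100, 90, 48, 16)
  pts <- data.frame(x = runif(40, 0, 89), y = runif(40, 0, 99),
                    label = "hematoxylin_only")
  ann2 <- annotation_set(pts)
  labels2 <- label_fragments(g2, ann2)
  brute2 <- vapply(seq_len(nrow(g2$origins)), function(i) {
    r <- g2$origins$row[i]; cc <- g2$origins$col[i]
    as.integer(any(pts$y >= r & pts$y < r + 48 & pts$x >= cc & pts$x < cc + 48))
  }, integer(1))
  expect_identical(labels2, brute2)
})

test_that("adding an annotation never flips a label to negative", {
  set.seed(8)
  g <- build_grid(120, 120, 48, 24)
  pts <- data.frame(x = runif(10, 0, 119), y = runif(10, 0, 119),
                    label = "dab_positive")
  base <- label_fragments(g, annotation_set(pts))
  more <- label_fragments(g, annotation_set(rbind(
    pts, data.frame(x = 60, y = 60, label = "hematoxylin_only")
  )))
  expect_true(all(more >= base))
})

test_that("extracted fragments equal direct slices", {
  ramp <- array(rep(seq_len(40 * 40), 3) %% 256, dim = c(40, 40, 3))
  img <- slide_image(ramp, "ramp")
  g <- build_grid(40, 40, 40, 40)
  expect_identical(extract_fragment(img, g, 1L), img$pixels)

  g2 <- build_grid(40, 40, 16, 8)
  f <- extract_fragment(img, g2, 1L)
  expect_identical(f, img$pixels[1:16, 1:16, , drop = FALSE])
  last <- nrow(g2$origins)
  fl <- extract_fragment(img, g2, last)
  expect_identical(fl, img$pixels[25:40, 25:40, , drop = FALSE])
  expect_error(extract_fragment(img, g2, last + 1L), "out of range")
})

test_that("fragment label CSV caching round-trips and validates", {
  dir <- withr::local_tempdir()
  g <- build_grid(64, 64, 32, 16)
  labels <- as.integer(seq_len(nrow(g$origins)) %% 2)
  p <- file.path(dir, "labels.csv")
  write_labels_csv(g, labels, p)
  expect_identical(read_labels_csv(g, p), labels)
  g2 <- build_grid(64, 64, 32, 32)
  expect_error(read_labels_csv(g2, p), "do not match")
})
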