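# Shared fixtures built in code. Small, fast configurations for unit
# tests; the acceptance tests use the generator defaults.

small_config <- function(seed = 1L, ...) {
  args <- list(
    seed = seed,
    image_height = 320L, image_width = 320L,
    n_clusters = 2L, nuclei_per_cluster = c(15L, 25L),
    nucleus_radius = c(4, 7),
    lymphocyte_count = 6L, artifact_count = 1L,
    clearance = 60
  )
  do.call(synthesis_config, modifyList(args, list(...)))
}

# Uniform-color slide (for degenerate segmentation inputs)
flat_slide <- function(value = 255L, h = 64L, w = 64L) {
  slide_image(array(value, dim = c(h, w, 3)), "flat")
}

# A disk mask centered in an h x w raster
disk_mask <- function(h, w, cy, cx, r) {
  yy <- matrix(seq_len(h) - 1, h, w)
  xx <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# Brute-force per-pixel window accumulation: the oracle for accumulate()
brute_accumulate <- function(grid, labels) {
  h <- grid$image_height; w <- grid$image_width; win <- grid$window
  counts <- matrix(0L, h, w); coverage <- matrix(0L, h, w)
  for (i in seq_len(nrow(grid$origins))) {
    r <- grid$origins$row[i]; cc <- grid$origins$col[i]
    rows <- (r + 1):(r + win); cols <- (cc + 1):(cc + win)
    coverage[rows, cols] <- coverage[rows, cols] + 1L
    if (labels[i] == 1L) counts[rows, cols] <- counts[rows, cols] + 1L
  }
  list(counts = counts, coverage = coverage)
}

# Exhaustive-search Otsu oracle: direct between-class variance on raw
# values at every one of the 255 interior bin boundaries.
brute_otsu <- function(vals, n_bins = 256L) {
  lo <- min(vals); hi <- max(vals)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  best <- -Inf; best_t <- NA_real_
  for (k in 1:(n_bins - 1L)) {
    t <- edges[k + 1L]
    g0 <- vals[vals < t]; g1 <- vals[vals >= t]
    if (!length(g0) || !length(g1)) next
    # bin centers, as the histogram method sees them
    width <- (hi - lo) / n_bins
    c0 <- lo + (pmin(floor((g0 - lo) / width), n_bins - 1L) + 0.5) * width
    c1 <- lo + (pmin(floor((g1 - lo) / width), n_bins - 1L) + 0.5) * width
    w0 <- length(g0) / length(vals); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(c0) - mean(c1))^2
    if (sb > best) { best <- sb; best_t <- t }
  }
  best_t
}

# 32 px fragments with an unambiguous class signal: nuclei vs background
make_separable_fragments <- function(n_per_class = 100L, seed = 11L) {
  make_frag <- function(s, positive) {
    ki67roi:::local_seed(s, {
      d <- matrix(0, 32, 32); h <- matrix(0, 32, 32)
      if (positive) {
        for (k in seq_len(sample(1:3, 1))) {
          r <- runif(1, 4, 7)
          if (runif(1) < 0.3) {
            d <- ki67roi:::.draw_ellipse(d, runif(1, 8, 24), runif(1, 8, 24),
                                         r, r * 0.85, runif(1, 0, pi),
                                         runif(1, 0.6, 1), 0.05)
          } else {
            h <- ki67roi:::.draw_ellipse(h, runif(1, 8, 24), runif(1, 8, 24),
                                         r, r * 0.85, runif(1, 0, pi),
                                         runif(1, 0.5, 0.9), 0.05)
          }
        }
      }
      d <- d + abs(rnorm(1024, 0, 0.01))
      h <- h + abs(rnorm(1024, 0, 0.01))
      render_from_stain_densities(d, h)$pixels
    })
  }
  labels <- rep(c(1L, 0L), each = n_per_class)
  fragments <- lapply(seq_along(labels),
                      function(i) make_frag(seed + i * 13L, labels[i] == 1L))
  list(fragments = fragments, labels = labels)
}
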