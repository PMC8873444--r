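#' Maximum per-pixel window overlap
#'
#' The largest number of sliding windows that can cover a single pixel deep
#' in the image interior: when the stride divides the window size this is
#' `(window / stride)^2` (e.g. a 96 px window with 16 px stride gives 6
#' subparts per axis, hence 36); otherwise the exact interior maximum is
#' found by enumerating window origins over one stride period.
#'
#' @param window square window side in pixels.
#' @param stride step in pixels (>= 1, <= window).
#' @return Integer count of overlapping windows.
#' @export
max_overlap <- function(window, stride) {
  window <- as.integer(window); stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  if (window < stride) stop("window must be >= stride")
  if (window %% stride == 0L) return(as.integer((window %/% stride)^2))
  per_axis <- vapply(0:(stride - 1L), function(phase) {
    p <- 10L * window + phase          # deep-interior coordinate
    origins <- seq.int(0L, p, by = stride)
    sum(origins > p - window & origins <= p)
  }, integer(1))
  as.integer(max(per_axis)^2)
}

#' Accumulate overlapping fragment predictions into a membership map
#'
#' For every pixel, sums the binary labels of all windows containing it
#' (positive = 1, negative = 0) and divides by the number of covering
#' windows, yielding a fuzzy tumor-cluster membership in `[0, 1]`. Border
#' pixels are covered by fewer windows than the interior maximum, so the
#' normalization is by the actual per-pixel coverage. Pixels outside every
#' window (right/bottom margins narrower than the window) get membership 0
#' and are flagged uncovered.
#'
#' @param pred a [prediction_map()].
#' @return An object of class `membership_map`: list with integer matrices
#'   `counts` and `coverage`, double matrix `mu`, and logical matrix
#'   `uncovered`.
#' @export
accumulate <- function(pred) {
  stopifnot(inherits(pred, "prediction_map"))
  grid <- pred$grid
  h <- grid$image_height; w <- grid$image_width; win <- grid$window
  rect_sum <- function(rows0, cols0) {
    d <- matrix(0L, h + 1L, w + 1L)
    if (length(rows0)) {
      add <- function(r, cc, v) d[cbind(r, cc)] <<- d[cbind(r, cc)] + v
      add(rows0 + 1L, cols0 + 1L, 1L)
      add(rows0 + 1L, cols0 + win + 1L, -1L)
      add(rows0 + win + 1L, cols0 + 1L, -1L)
      add(rows0 + win + 1L, cols0 + win + 1L, 1L)
    }
    cum <- apply(d, 2, cumsum)
    cum <- t(apply(cum, 1, cumsum))
    cum[seq_len(h), seq_len(w), drop = FALSE]
  }
  pos <- pred$labels == 1L
  counts <- rect_sum(grid$origins$row[pos], grid$origins$col[pos])
  coverage <- rect_sum(grid$origins$row, grid$origins$col)
  uncovered <- coverage == 0L
  mu <- counts / pmax(coverage, 1L)
  mu[uncovered] <- 0
  structure(
    list(counts = counts, coverage = coverage, mu = mu, uncovered = uncovered),
    class = "membership_map"
  )
}

#' @export
print.membership_map <- function(x, ...) {
  cat(sprintf(
    "<membership_map> %d x %d px, max count %d, max coverage %d\n",
    nrow(x$mu), ncol(x$mu), max(x$counts), max(x$coverage)))
  invisible(x)
}

#' Defuzzify a membership map into a binary ROI mask
#'
#' Assigns each pixel to the most suitable class. With linear membership
#' functions mu_tumor = counts/coverage and mu_irrelevant = 1 - mu_tumor,
#' the argmax assignment equals thresholding mu_tumor at 0.5. Ties at
#' exactly the cutoff resolve to background, favoring rejection of stain
#' artifacts.
#'
#' @param membership a [accumulate()] result.
#' @param cutoff fraction in (0, 1); default 0.5 (the argmax rule).
#' @return An object of class `roi_mask`: list with logical matrix `mask`
#'   and flag `empty`.
#' @export
defuzzify <- function(membership, cutoff = 0.5) {
  stopifnot(inherits(membership, "membership_map"),
            cutoff > 0, cutoff < 1)
  mask <- membership$mu > cutoff
  roi_mask(mask)
}

#' Construct an ROI mask
#'
#' @param mask logical matrix (`TRUE` = tumor-cluster ROI).
#' @return An object of class `roi_mask` with `mask` and `empty`.
#' @export
roi_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(list(mask = mask, empty = !any(mask)), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d px, %d ROI pixels%s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              if (x$empty) " (empty)" else ""))
  invisible(x)
}

#' Overlay an ROI mask on a slide image
#'
#' Renders the ROI boundary and a translucent fill for visual verification
#' of the defuzzification stage.
#'
#' @param image a [slide_image()].
#' @param roi an [roi_mask()] of the same size.
#' @param color RGB triplet in 0..255 for the overlay.
#' @param alpha fill opacity in `[0, 1]`.
#' @return A [slide_image()] with the overlay burnt in.
#' @export
overlay_roi <- function(image, roi, color = c(255L, 255L, 0L), alpha = 0.25) {
  stopifnot(inherits(image, "slide_image"), inherits(roi, "roi_mask"))
  if (any(dim(roi$mask) != dim(image$pixels)[1:2])) {
    stop("image and ROI dimensions differ")
  }
  px <- image$pixels
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[roi$mask] <- round((1 - alpha) * plane[roi$mask] + alpha * color[ch])
    px[, , ch] <- plane
  }
  slide_image(px, paste0(image$slide_id, "-roi-overlay"))
}
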