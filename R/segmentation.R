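#' Construct stain thresholds
#'
#' Optical-density cuts for the DAB and hematoxylin channels, with a
#' provenance tag: `"otsu"` (computed on the slide itself), `"reference"`
#' (averaged over training slides) or `"biased"` (a combination).
#'
#' @param t_dab,t_hema finite numeric thresholds (base-10 OD).
#' @param provenance one of `"otsu"`, `"reference"`, `"biased"`.
#' @return An object of class `stain_thresholds`.
#' @export
stain_thresholds <- function(t_dab, t_hema,
                             provenance = c("otsu", "reference", "biased")) {
  structure(
    list(t_dab = t_dab, t_hema = t_hema, provenance = match.arg(provenance)),
    class = "stain_thresholds"
  )
}

#' @export
print.stain_thresholds <- function(x, ...) {
  cat(sprintf("<stain_thresholds> DAB %.4f, hematoxylin %.4f (%s)\n",
              x$t_dab, x$t_hema, x$provenance))
  invisible(x)
}

#' Otsu threshold restricted to a mask
#'
#' Maximizes the between-class variance over a 256-bin histogram of the
#' channel values observed inside the mask only, so that staining
#' artifacts outside the ROI cannot bias the intensity distribution. The
#' returned threshold `t` is a bin edge; foreground is `value > t` (values
#' below the first populated boundary side are background).
#'
#' @param channel numeric matrix (e.g. one stain's optical density).
#' @param mask logical matrix of the same size, or an [roi_mask()].
#' @param n_bins histogram resolution (default 256).
#' @return The threshold, with the bin edges attached as attribute
#'   `"edges"` for reproducibility.
#' @export
otsu_in_mask <- function(channel, mask, n_bins = 256L) {
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  stopifnot(is.matrix(channel), all(dim(channel) == dim(mask)))
  vals <- channel[mask]
  if (length(vals) == 0L) {
    stop("empty mask: no pixels to threshold (apply the ROI fallback first)")
  }
  lo <- min(vals); hi <- max(vals)
  if (hi - lo <= 0) stop("degenerate histogram: channel is constant in mask")
  width <- (hi - lo) / n_bins
  bins <- pmin(floor((vals - lo) / width) + 1L, n_bins)
  counts <- tabulate(bins, n_bins)
  p <- counts / sum(counts)
  centers <- lo + (seq_len(n_bins) - 0.5) * width
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * centers)
  mu_tot <- mu_cum[n_bins]
  k <- seq_len(n_bins - 1L)
  w1 <- 1 - w0[k]
  sigma_b <- ifelse(
    w0[k] > 0 & w1 > 0,
    (mu_tot * w0[k] - mu_cum[k])^2 / (w0[k] * w1),
    -Inf
  )
  kstar <- which.max(sigma_b)
  thr <- lo + kstar * width
  attr(thr, "edges") <- seq(lo, hi, length.out = n_bins + 1L)
  thr
}

#' Average reference thresholds from training slides
#'
#' For each training slide, Otsu thresholds are computed per stain channel
#' inside the slide's ground-truth ROI (from expert annotations); the
#' per-channel arithmetic means become the reference thresholds used to
#' bias evaluation slides of the complementary chunk. Slides with an empty
#' ground-truth ROI are skipped with a warning.
#'
#' @param images list of [slide_image()]s.
#' @param rois list of ground-truth ROI masks ([roi_mask()] or logical
#'   matrices), parallel to `images`.
#' @param min_threshold background OD floor applied to each per-slide
#'   threshold (see [segment_and_estimate()]).
#' @return A [stain_thresholds()] with provenance `"reference"` and the
#'   per-slide thresholds attached as attribute `"per_slide"`.
#' @export
reference_thresholds <- function(images, rois, min_threshold = 0.05) {
  stopifnot(length(images) >= 1L, length(images) == length(rois))
  t_dab <- numeric(); t_hema <- numeric()
  for (i in seq_along(images)) {
    mask <- rois[[i]]
    if (inherits(mask, "roi_mask")) mask <- mask$mask
    if (!any(mask)) {
      warning("slide ", images[[i]]$slide_id,
              " has an empty ground-truth ROI; skipped")
      next
    }
    hed <- rgb_to_hed(images[[i]])
    t_dab <- c(t_dab, max(.otsu_or_inf(hed$dab, mask), min_threshold))
    t_hema <- c(t_hema, max(.otsu_or_inf(hed$hema, mask), min_threshold))
  }
  keep <- is.finite(t_dab) & is.finite(t_hema)
  t_dab <- t_dab[keep]; t_hema <- t_hema[keep]
  if (length(t_dab) == 0L) {
    stop("no usable training slides for reference thresholds")
  }
  out <- stain_thresholds(mean(t_dab), mean(t_hema), "reference")
  attr(out, "per_slide") <- data.frame(t_dab = t_dab, t_hema = t_hema)
  out
}

# Otsu that degrades to +Inf (empty stain mask) on a constant channel.
.otsu_or_inf <- function(channel, mask) {
  tryCatch(as.numeric(otsu_in_mask(channel, mask)),
           error = function(e) Inf)
}

#' Combine own and reference thresholds
#'
#' Per-channel convex combination `weight * reference + (1 - weight) *
#' own`. The default weight 1 replaces the slide's own Otsu thresholds by
#' the reference average (pure biasing); intermediate weights blend.
#'
#' @param own,reference [stain_thresholds()] objects.
#' @param weight fraction in `[0, 1]`.
#' @return A [stain_thresholds()] with provenance `"biased"`.
#' @export
combine_thresholds <- function(own, reference, weight = 1) {
  stopifnot(inherits(own, "stain_thresholds"),
            inherits(reference, "stain_thresholds"),
            weight >= 0, weight <= 1)
  mix <- function(o, r) {
    if (!is.finite(o)) return(r)     # degenerate own channel: use reference
    weight * r + (1 - weight) * o
  }
  stain_thresholds(mix(own$t_dab, reference$t_dab),
                   mix(own$t_hema, reference$t_hema), "biased")
}

.disc_kernel <- function(radius) EBImage::makeBrush(2L * radius + 1L, "disc")

#' Segment stained cells within the ROI and estimate the PI
#'
#' Separates the image into DAB and hematoxylin optical densities, cuts
#' each channel at its threshold restricted to the ROI, cleans both binary
#' masks by closing then dilation with disc structuring elements, and
#' approximates the proliferation index as the ratio of the DAB-positive
#' surface area to the total relevant-cell surface area (the union of the
#' DAB and hematoxylin masks, which makes `dab_area <= relevant_area`
#' structural). If the ROI is empty the negative variant is assumed and
#' segmentation runs on the whole image (flagged `roi_fallback`).
#'
#' @param image a [slide_image()].
#' @param roi an [roi_mask()], or `NULL` to segment the whole image (the
#'   "base" reference method that skips the ROI stage).
#' @param thresholds a [stain_thresholds()] to impose (e.g. reference or
#'   biased), or `NULL` to compute Otsu thresholds inside the ROI.
#' @param closing_radius,dilation_radius disc radii (pixels) of the
#'   morphological cleanup applied to each stain mask before the union;
#'   0 disables the operation.
#' @param min_threshold background OD floor for automatically computed
#'   thresholds: a stain channel with no real signal in the ROI would
#'   otherwise have Otsu split its noise floor and count background as
#'   cells. Imposed `thresholds` are used verbatim.
#' @param method tag recorded in the estimate (`"base"`, `"roi"`,
#'   `"roi_bias"`); default inferred from the arguments.
#' @return An object of class `pi_estimate`: list with `pi`, `dab_area`,
#'   `relevant_area`, `roi_fallback`, `method`, `thresholds`.
#' @export
segment_and_estimate <- function(image, roi = NULL, thresholds = NULL,
                                 closing_radius = 1L, dilation_radius = 1L,
                                 min_threshold = 0.05, method = NULL) {
  stopifnot(inherits(image, "slide_image"))
  h <- img_height(image); w <- img_width(image)
  roi_fallback <- FALSE
  if (is.null(roi)) {
    m <- matrix(TRUE, h, w)
  } else {
    stopifnot(inherits(roi, "roi_mask"))
    if (any(dim(roi$mask) != c(h, w))) stop("image and ROI dimensions differ")
    if (roi$empty) {
      roi_fallback <- TRUE
      m <- matrix(TRUE, h, w)
    } else {
      m <- roi$mask
    }
  }
  if (is.null(method)) {
    method <- if (is.null(roi)) {
      "base"
    } else if (!is.null(thresholds) && thresholds$provenance != "otsu") {
      "roi_bias"
    } else {
      "roi"
    }
  }

  hed <- rgb_to_hed(image)
  if (is.null(thresholds)) {
    thresholds <- stain_thresholds(
      max(.otsu_or_inf(hed$dab, m), min_threshold),
      max(.otsu_or_inf(hed$hema, m), min_threshold),
      "otsu"
    )
  }

  clean <- function(mask) {
    if (!any(mask)) return(mask)
    num <- matrix(as.numeric(mask), h, w)
    if (closing_radius > 0) {
      num <- EBImage::closing(num, .disc_kernel(closing_radius))
    }
    if (dilation_radius > 0) {
      num <- EBImage::dilate(num, .disc_kernel(dilation_radius))
    }
    as.matrix(num) > 0.5
  }

  dab_mask <- clean((hed$dab > thresholds$t_dab) & m)
  hema_mask <- clean((hed$hema > thresholds$t_hema) & m)
  relevant <- dab_mask | hema_mask
  if (!any(relevant)) {
    stop("no cells segmented: both stain masks are empty")
  }
  structure(
    list(
      pi = sum(dab_mask) / sum(relevant),
      dab_area = sum(dab_mask), relevant_area = sum(relevant),
      roi_fallback = roi_fallback, method = method, thresholds = thresholds,
      slide_id = image$slide_id
    ),
    class = "pi_estimate"
  )
}

#' @export
print.pi_estimate <- function(x, ...) {
  cat(sprintf(
    "<pi_estimate '%s'> PI = %.4f (%d / %d px, method %s%s)\n",
    x$slide_id, x$pi, x$dab_area, x$relevant_area, x$method,
    if (x$roi_fallback) ", whole-image fallback" else ""))
  invisible(x)
}

#' Write a PI estimate as a JSON sidecar
#'
#' @param estimate a `pi_estimate`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_estimate_json <- function(estimate, path) {
  jsonlite::write_json(
    list(slide_id = estimate$slide_id, method = estimate$method,
         pi = estimate$pi, dab_area = estimate$dab_area,
         relevant_area = estimate$relevant_area,
         roi_fallback = estimate$roi_fallback,
         thresholds = list(t_dab = estimate$thresholds$t_dab,
                           t_hema = estimate$thresholds$t_hema,
                           provenance = estimate$thresholds$provenance)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
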