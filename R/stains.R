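# Hematoxylin / eosin / DAB absorbance unit vectors (Ruifrok & Johnston),
# rows = stains, columns = RGB. Row-normalized at load.
.hed_rgb_matrix <- local({
  m <- rbind(
    hematoxylin = c(0.65, 0.70, 0.29),
    eosin       = c(0.07, 0.99, 0.11),
    dab         = c(0.27, 0.57, 0.78)
  )
  m / sqrt(rowSums(m^2))
})
.rgb_hed_matrix <- solve(.hed_rgb_matrix)

# Half a quantization step: 8-bit value 0 cannot be distinguished from
# optical densities beyond -log10(0.5/255) ~ 2.7.
.od_eps <- 0.5 / 255

#' Separate DAB and hematoxylin stains by color deconvolution
#'
#' Converts an RGB slide into per-stain optical densities (base-10
#' absorbance) in the hematoxylin-eosin-DAB (HED) space using the standard
#' published stain absorbance vectors. The eosin channel is computed but
#' unused downstream.
#'
#' @param image a [slide_image()].
#' @return A list with matrices `dab`, `hema`, `eosin` (height x width,
#'   non-negative optical densities).
#' @export
rgb_to_hed <- function(image) {
  stopifnot(inherits(image, "slide_image"))
  v <- img_unit(image)
  od <- -log10(pmax(v, .od_eps))
  h <- dim(v)[1]; w <- dim(v)[2]
  flat <- matrix(od, nrow = h * w, ncol = 3)      # columns R, G, B
  dens <- flat %*% .rgb_hed_matrix                # columns H, E, D
  dens[dens < 0] <- 0
  list(
    hema  = matrix(dens[, 1], h, w),
    eosin = matrix(dens[, 2], h, w),
    dab   = matrix(dens[, 3], h, w)
  )
}

#' Render an RGB slide from stain optical densities
#'
#' Inverse of [rgb_to_hed()]: composes per-pixel DAB and hematoxylin
#' optical densities through the HED absorbance matrix and the Beer-Lambert
#' law into an 8-bit RGB raster. Zero density renders near-white. The
#' synthetic slide generator draws in density space and renders through
#' this function, so its colors are consistent with the forward
#' deconvolution used by the segmentation stage.
#'
#' @param dab_density,hema_density non-negative matrices of equal size.
#' @param eosin_density optional matrix (e.g. pale stromal background).
#' @param slide_id identifier for the rendered slide.
#' @return A [slide_image()].
#' @export
render_from_stain_densities <- function(dab_density, hema_density,
                                        eosin_density = NULL,
                                        slide_id = "synthetic") {
  if (!all(dim(dab_density) == dim(hema_density))) {
    stop("dab_density and hema_density dimensions differ")
  }
  if (is.null(eosin_density)) {
    eosin_density <- matrix(0, nrow(dab_density), ncol(dab_density))
  }
  if (!all(dim(eosin_density) == dim(dab_density))) {
    stop("eosin_density dimensions differ from the stain rasters")
  }
  if (min(dab_density) < 0 || min(hema_density) < 0 || min(eosin_density) < 0) {
    stop("stain densities must be non-negative")
  }
  h <- nrow(dab_density); w <- ncol(dab_density)
  dens <- cbind(as.vector(hema_density), as.vector(eosin_density),
                as.vector(dab_density))
  od <- dens %*% .hed_rgb_matrix                  # columns R, G, B
  rgb <- 10^(-od)
  rgb[rgb > 1] <- 1
  slide_image(array(round(rgb * 255), dim = c(h, w, 3)), slide_id)
}
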