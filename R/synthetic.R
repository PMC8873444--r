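#' Configuration for the synthetic IHC slide generator
#'
#' Describes one synthetic pROI: clustered tumor nuclei rendered in DAB
#' brown (Ki-67 positive) and hematoxylin blue (negative) at a controlled
#' positive fraction, scattered isolated lymphocytes outside the clusters,
#' optional high-density stain artifacts, and a pale stromal background.
#' Sizes and densities are in pixels and base-10 optical density (OD).
#'
#' @param seed integer; the single source of all randomness.
#' @param image_height,image_width image size in pixels.
#' @param n_clusters number of tumor-cell clusters.
#' @param nuclei_per_cluster integer range `c(min, max)` of nuclei drawn
#'   per cluster.
#' @param target_pi probability in `[0, 1]` that a tumor nucleus is
#'   DAB-positive; each nucleus is labeled independently and the realized
#'   fraction is the slide's ground truth.
#' @param nucleus_radius pixel range `c(min, max)` of tumor-nucleus radii.
#' @param lymphocyte_count isolated small dark nuclei placed outside every
#'   cluster; they carry no annotation (single cells in the intercellular
#'   space are skipped by the annotation protocol).
#' @param artifact_count high-density irregular stain blobs outside the
#'   clusters; the ROI stage is expected to reject them.
#' @param dab_od,hema_od OD ranges `c(min, max)` for positive nuclei (DAB
#'   channel) and negative nuclei/lymphocytes (hematoxylin channel).
#' @param artifact_od OD range for artifact blobs.
#' @param artifact_stain `"dab"`, `"hema"` or `"both"` (drawn per blob).
#' @param dab_haze maximum OD of a smooth diffuse DAB background field
#'   (default 0 = none); emulates unspecific chromogen deposition that can
#'   mislead per-image Otsu thresholding.
#' @param nucleus_noise_sd,background_noise_sd additive density noise
#'   inside nuclei and over the whole raster.
#' @param clearance minimum pixel distance between isolated objects
#'   (lymphocytes, artifacts) and any cluster footprint, keeping them clear
#'   of windows that mostly overlap a cluster.
#' @param packing target fraction of a cluster footprint covered by nuclei;
#'   sets the cluster radius from the nucleus count and size.
#' @return A `synthesis_config` list, validated.
#' @export
synthesis_config <- function(seed = 1L,
                             image_height = 640L, image_width = 640L,
                             n_clusters = 3L,
                             nuclei_per_cluster = c(40L, 70L),
                             target_pi = 0.2,
                             nucleus_radius = c(5, 9),
                             lymphocyte_count = 20L,
                             artifact_count = 2L,
                             dab_od = c(0.6, 1.0),
                             hema_od = c(0.5, 0.9),
                             artifact_od = c(1.0, 1.4),
                             artifact_stain = c("both", "dab", "hema"),
                             dab_haze = 0,
                             nucleus_noise_sd = 0.05,
                             background_noise_sd = 0.005,
                             clearance = 80,
                             packing = 0.35) {
  cfg <- list(
    seed = as.integer(seed),
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_clusters = as.integer(n_clusters),
    nuclei_per_cluster = as.integer(rep(nuclei_per_cluster, length.out = 2)),
    target_pi = target_pi,
    nucleus_radius = rep(nucleus_radius, length.out = 2),
    lymphocyte_count = as.integer(lymphocyte_count),
    artifact_count = as.integer(artifact_count),
    dab_od = dab_od, hema_od = hema_od, artifact_od = artifact_od,
    artifact_stain = match.arg(artifact_stain),
    dab_haze = dab_haze,
    nucleus_noise_sd = nucleus_noise_sd,
    background_noise_sd = background_noise_sd,
    clearance = clearance, packing = packing
  )
  with(cfg, {
    stopifnot(
      image_height >= 48L, image_width >= 48L,
      n_clusters >= 0L, all(nuclei_per_cluster >= 0L),
      target_pi >= 0, target_pi <= 1,
      all(nucleus_radius > 0), lymphocyte_count >= 0L, artifact_count >= 0L,
      packing > 0, packing < 1
    )
  })
  class(cfg) <- "synthesis_config"
  cfg
}

# Add a filled, mildly eccentric, rotated ellipse to a density raster.
# Overlaps blend by per-pixel maximum so densities stay in stain range.
.draw_ellipse <- function(raster, cx, cy, a, b, theta, density, noise_sd) {
  h <- nrow(raster); w <- ncol(raster)
  r <- max(a, b)
  rows <- max(1L, floor(cy + 1 - r)):min(h, ceiling(cy + 1 + r))
  cols <- max(1L, floor(cx + 1 - r)):min(w, ceiling(cx + 1 + r))
  dy <- (rows - 1) - cy
  dx <- (cols - 1) - cx
  u <- outer(dy, dx, function(yy, xx) (xx * cos(theta) + yy * sin(theta)) / a)
  v <- outer(dy, dx, function(yy, xx) (-xx * sin(theta) + yy * cos(theta)) / b)
  inside <- (u^2 + v^2) <= 1
  if (!any(inside)) return(raster)
  val <- matrix(0, length(rows), length(cols))
  val[inside] <- pmax(0, density + rnorm(sum(inside), 0, noise_sd))
  raster[rows, cols] <- pmax(raster[rows, cols], val)
  raster
}

# Smooth random field in [0, max_od]: coarse uniform grid, bilinear upsample.
.smooth_field <- function(h, w, max_od, grid_n = 8L) {
  coarse <- matrix(runif(grid_n^2, 0, max_od), grid_n, grid_n)
  ry <- seq(1, grid_n, length.out = h)
  rx <- seq(1, grid_n, length.out = w)
  y0 <- pmin(floor(ry), grid_n - 1L); x0 <- pmin(floor(rx), grid_n - 1L)
  wy <- ry - y0; wx <- rx - x0
  a <- coarse[cbind(rep(y0, w), rep(x0, each = h))]
  b <- coarse[cbind(rep(y0, w), rep(x0 + 1L, each = h))]
  cc <- coarse[cbind(rep(y0 + 1L, w), rep(x0, each = h))]
  d <- coarse[cbind(rep(y0 + 1L, w), rep(x0 + 1L, each = h))]
  wyv <- rep(wy, w); wxv <- rep(wx, each = h)
  matrix((1 - wyv) * (1 - wxv) * a + (1 - wyv) * wxv * b +
           wyv * (1 - wxv) * cc + wyv * wxv * d, h, w)
}

#' Generate a synthetic IHC slide with known ground truth
#'
#' Draws tumor nuclei in spatial clusters (each nucleus independently
#' DAB-positive with probability `target_pi`), isolated lymphocytes and
#' stain artifacts outside the clusters, composes everything in stain
#' density space and renders through [render_from_stain_densities()].
#' Deterministic given `config$seed`.
#'
#' @param config a [synthesis_config()].
#' @param slide_id identifier for the emitted slide.
#' @return An object of class `synthetic_slide`: list with `image`
#'   ([slide_image()]), `annotations` ([annotation_set()], tumor nuclei
#'   only), `roi_truth` (list `mask` logical matrix + `empty` flag: union
#'   of cluster footprints), `true_pi` ([ground_truth_pi()]) and `config`.
#' @export
generate_slide <- function(config, slide_id = sprintf("synth-%06d", config$seed)) {
  stopifnot(inherits(config, "synthesis_config"))
  local_seed(config$seed, .generate_slide_impl(config, slide_id))
}

.generate_slide_impl <- function(cfg, slide_id) {
  h <- cfg$image_height; w <- cfg$image_width
  max_r <- max(cfg$nucleus_radius)
  n_mean <- mean(cfg$nuclei_per_cluster)
  mean_r2 <- mean(seq(cfg$nucleus_radius[1], cfg$nucleus_radius[2],
                      length.out = 25)^2)
  cluster_r <- sqrt(max(n_mean, 1) * pi * mean_r2 / (pi * cfg$packing))

  # -- cluster centers: inside the image with margin, pairwise separated
  centers <- matrix(numeric(0), 0, 2)
  margin <- cluster_r + max_r + 2
  if (cfg$n_clusters > 0) {
    if (2 * margin >= min(h, w)) {
      stop("image too small for the requested cluster size/count")
    }
    tries <- 0L
    while (nrow(centers) < cfg$n_clusters) {
      tries <- tries + 1L
      if (tries > 500L) {
        stop("cluster placement failed after bounded retries: ",
             "image too small for ", cfg$n_clusters, " clusters of radius ",
             round(cluster_r))
      }
      cand <- c(runif(1, margin, h - margin), runif(1, margin, w - margin))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums(sweep(centers, 2, cand)^2)) > 2 * cluster_r + 10)) {
        centers <- rbind(centers, cand)
      }
    }
  }

  # -- ROI truth: union of cluster footprint disks
  roi <- matrix(FALSE, h, w)
  if (nrow(centers)) {
    yy <- matrix(seq_len(h) - 1, h, w)
    xx <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
    for (i in seq_len(nrow(centers))) {
      roi <- roi | ((yy - centers[i, 1])^2 + (xx - centers[i, 2])^2 <=
                      cluster_r^2)
    }
  }

  dab <- matrix(0, h, w)
  hema <- matrix(0, h, w)

  # -- tumor nuclei
  ann_x <- numeric(); ann_y <- numeric(); ann_lab <- character()
  place_r <- max(cluster_r - max_r - 1, 1)
  for (i in seq_len(nrow(centers))) {
    n_i <- if (cfg$nuclei_per_cluster[1] == cfg$nuclei_per_cluster[2]) {
      cfg$nuclei_per_cluster[1]
    } else {
      sample(cfg$nuclei_per_cluster[1]:cfg$nuclei_per_cluster[2], 1)
    }
    if (n_i == 0) next
    # Sequential placement with a touching-distance constraint: nuclei in a
    # cluster abut rather than interpenetrate. After bounded retries a
    # candidate is accepted anyway (slight overlap, as in dense tissue).
    ny <- numeric(n_i); nx <- numeric(n_i)
    rad <- runif(n_i, cfg$nucleus_radius[1], cfg$nucleus_radius[2])
    for (j in seq_len(n_i)) {
      for (try in seq_len(40L)) {
        rr <- place_r * sqrt(runif(1))
        th <- runif(1, 0, 2 * pi)
        cy <- centers[i, 1] + rr * sin(th)
        cx <- centers[i, 2] + rr * cos(th)
        if (j == 1L) break
        dd <- sqrt((ny[seq_len(j - 1)] - cy)^2 + (nx[seq_len(j - 1)] - cx)^2)
        if (all(dd >= 0.85 * (rad[seq_len(j - 1)] + rad[j]))) break
      }
      ny[j] <- cy; nx[j] <- cx
    }
    pos <- runif(n_i) < cfg$target_pi
    for (j in seq_len(n_i)) {
      a <- rad[j]
      b <- a * runif(1, 0.7, 1)          # mild eccentricity
      theta <- runif(1, 0, pi)
      if (pos[j]) {
        od <- runif(1, cfg$dab_od[1], cfg$dab_od[2])
        dab <- .draw_ellipse(dab, nx[j], ny[j], a, b, theta, od,
                             cfg$nucleus_noise_sd)
      } else {
        od <- runif(1, cfg$hema_od[1], cfg$hema_od[2])
        hema <- .draw_ellipse(hema, nx[j], ny[j], a, b, theta, od,
                              cfg$nucleus_noise_sd)
      }
    }
    ann_x <- c(ann_x, round(nx))
    ann_y <- c(ann_y, round(ny))
    ann_lab <- c(ann_lab,
                 ifelse(pos, "dab_positive", "hematoxylin_only"))
  }

  # -- isolated objects outside every cluster footprint (plus clearance)
  place_outside <- function(obj_r, min_sep, existing) {
    for (try in seq_len(400L)) {
      cand <- c(runif(1, obj_r + 1, h - obj_r - 2),
                runif(1, obj_r + 1, w - obj_r - 2))
      ok_cluster <- nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >
              cluster_r + cfg$clearance + obj_r)
      ok_sep <- nrow(existing) == 0 ||
        all(sqrt(rowSums(sweep(existing, 2, cand)^2)) > min_sep)
      if (ok_cluster && ok_sep) return(cand)
    }
    stop("placement of isolated objects failed after bounded retries: ",
         "no space outside clusters (image too small or clusters too large)")
  }

  lymph <- matrix(numeric(0), 0, 2)
  for (k in seq_len(cfg$lymphocyte_count)) {
    r <- runif(1, 2, 3.2)
    cand <- place_outside(r, 10, lymph)
    lymph <- rbind(lymph, cand)
    od <- runif(1, cfg$hema_od[2], cfg$hema_od[2] + 0.3)   # darker than tumor
    hema <- .draw_ellipse(hema, cand[2], cand[1], r, r * 0.9, runif(1, 0, pi),
                          od, cfg$nucleus_noise_sd)
  }

  artifacts <- matrix(numeric(0), 0, 2)
  for (k in seq_len(cfg$artifact_count)) {
    blob_r <- runif(1, 8, 12)
    cand <- place_outside(blob_r + 6, 110, artifacts)
    artifacts <- rbind(artifacts, cand)
    stain <- switch(cfg$artifact_stain,
                    both = sample(c("dab", "hema"), 1),
                    cfg$artifact_stain)
    od <- runif(1, cfg$artifact_od[1], cfg$artifact_od[2])
    for (sub in seq_len(6L)) {          # irregular blob = union of disks
      sy <- cand[1] + runif(1, -4, 4)
      sx <- cand[2] + runif(1, -4, 4)
      sr <- blob_r * runif(1, 0.5, 1)
      if (stain == "dab") {
        dab <- .draw_ellipse(dab, sx, sy, sr, sr * runif(1, 0.6, 1),
                             runif(1, 0, pi), od, cfg$nucleus_noise_sd)
      } else {
        hema <- .draw_ellipse(hema, sx, sy, sr, sr * runif(1, 0.6, 1),
                              runif(1, 0, pi), od, cfg$nucleus_noise_sd)
      }
    }
  }

  # -- diffuse fields and noise
  if (cfg$dab_haze > 0) {
    # fine-grained so the haze varies within a single cluster footprint
    dab <- pmax(dab, .smooth_field(h, w, cfg$dab_haze, grid_n = 24L))
  }
  eosin <- .smooth_field(h, w, 0.08)    # pale stromal background
  if (cfg$background_noise_sd > 0) {
    dab <- dab + abs(rnorm(h * w, 0, cfg$background_noise_sd))
    hema <- hema + abs(rnorm(h * w, 0, cfg$background_noise_sd))
  }

  image <- render_from_stain_densities(dab, hema, eosin, slide_id)
  annotations <- annotation_set(
    data.frame(x = ann_x, y = ann_y, label = ann_lab), slide_id
  )
  true_pi <- if (nrow(annotations$points)) ground_truth_pi(annotations) else NULL

  structure(
    list(
      image = image,
      annotations = annotations,
      roi_truth = roi_mask(roi),
      true_pi = true_pi,
      config = cfg
    ),
    class = "synthetic_slide"
  )
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("<synthetic_slide '%s'> %d x %d px, %d nuclei, true PI %s\n",
              x$image$slide_id, img_height(x$image), img_width(x$image),
              nrow(x$annotations$points),
              if (is.null(x$true_pi)) "NA" else sprintf("%.4f", x$true_pi$pi)))
  invisible(x)
}

#' Write a synthetic slide with its sidecars
#'
#' Emits `<id>.png` (image), `<id>_markers.xml` (Cell Counter),
#' `<id>_annotations.csv`, `<id>_roi.png` (binary ROI truth) and
#' `<id>.json` (true PI + config echo) into `dir`.
#'
#' @param slide a `synthetic_slide`.
#' @param dir output directory (created if missing).
#' @return The slide id, invisibly.
#' @export
write_synthetic_slide <- function(slide, dir) {
  stopifnot(inherits(slide, "synthetic_slide"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- slide$image$slide_id
  write_image(slide$image, file.path(dir, paste0(id, ".png")))
  write_cellcounter_xml(slide$annotations,
                        file.path(dir, paste0(id, "_markers.xml")))
  write_annotation_csv(slide$annotations,
                       file.path(dir, paste0(id, "_annotations.csv")))
  write_mask(slide$roi_truth$mask, file.path(dir, paste0(id, "_roi.png")))
  jsonlite::write_json(
    list(
      slide_id = id,
      true_pi = if (is.null(slide$true_pi)) NULL else slide$true_pi$pi,
      n_positive = if (is.null(slide$true_pi)) 0L else slide$true_pi$n_positive,
      n_negative = if (is.null(slide$true_pi)) 0L else slide$true_pi$n_negative,
      config = unclass(slide$config)
    ),
    file.path(dir, paste0(id, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(id)
}
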