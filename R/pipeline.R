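#' Pipeline configuration
#'
#' Fully-populated default configuration mirroring the reference pipeline
#' constants: 96 px window with evaluation stride 16 (training stride =
#' window size), defuzzification cutoff 0.5, disc radius 1 morphology,
#' pure-replacement threshold biasing, chunk sizes 25/25/25/20 and the
#' compact CNN training recipe. Values can be overridden from a YAML file
#' and/or an override list; the resolved configuration can be echoed next
#' to outputs for provenance.
#'
#' @param path optional YAML file with overrides.
#' @param overrides optional named list of overrides (applied after the
#'   file).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    window = 96L, eval_stride = 16L, train_stride = NULL,  # NULL = window
    defuzz_cutoff = 0.5,
    closing_radius = 1L, dilation_radius = 1L,
    min_threshold = 0.05,
    bias_weight = 1.0,
    chunk_sizes = c(25L, 25L, 25L, 20L),
    seed = 1L,
    classifier = "heuristic",           # "heuristic" or "tiny_cnn"
    min_stained_fraction = 0.15, density_cut = 0.2,
    training = list(architecture = "tiny_cnn", learning_rate = 0.001,
                    batch_size = 128L, epochs = 50L, bn_momentum = 0.1,
                    valid_fraction = 0.2)
  )
  if (!is.null(path)) cfg <- modifyList(cfg, yaml::read_yaml(path))
  cfg <- modifyList(cfg, overrides)
  if (is.null(cfg$train_stride)) cfg$train_stride <- cfg$window
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write the resolved configuration echo
#'
#' @param config a [pipeline_config()].
#' @param path YAML path.
#' @return `path`, invisibly.
#' @export
write_config_echo <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` synthetic slides (image, marker XML, annotation CSV, ROI
#' truth mask, JSON sidecar) plus a `manifest.json` listing slide ids and
#' true PIs. Per-slide seeds are derived deterministically from `seed`.
#'
#' @param dir output directory.
#' @param n number of slides.
#' @param seed master seed.
#' @param config_fn function(seed, index) returning a
#'   [synthesis_config()]; the default draws the target PI uniformly from
#'   `pi_range` with the generator defaults.
#' @param pi_range range of target PIs for the default `config_fn`.
#' @return The manifest as a data.frame (`slide_id`, `true_pi`),
#'   invisibly.
#' @export
synth_dataset <- function(dir, n, seed = 1L, config_fn = NULL,
                          pi_range = c(0.05, 0.6)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slide_seeds <- local_seed(seed, sample.int(1e7, n))
  target_pis <- local_seed(seed + 1L, runif(n, pi_range[1], pi_range[2]))
  if (is.null(config_fn)) {
    config_fn <- function(s, i) synthesis_config(seed = s, target_pi = target_pis[i])
  }
  ids <- character(n); pis <- numeric(n)
  for (i in seq_len(n)) {
    slide <- generate_slide(config_fn(slide_seeds[i], i),
                            slide_id = sprintf("synth-%03d", i))
    write_synthetic_slide(slide, dir)
    ids[i] <- slide$image$slide_id
    pis[i] <- if (is.null(slide$true_pi)) NA_real_ else slide$true_pi$pi
  }
  manifest <- data.frame(slide_id = ids, true_pi = pis)
  jsonlite::write_json(
    list(seed = seed, n = n,
         slides = lapply(seq_len(n), function(i) {
           list(slide_id = ids[i], true_pi = pis[i])
         })),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

#' Read back a synthetic slide written by [write_synthetic_slide()]
#'
#' @param dir dataset directory.
#' @param slide_id slide identifier.
#' @return A list with `image`, `annotations`, `roi_truth`, `true_pi`.
#' @export
read_synthetic_slide <- function(dir, slide_id) {
  image <- read_image(file.path(dir, paste0(slide_id, ".png")), slide_id)
  annotations <- read_annotation_csv(
    file.path(dir, paste0(slide_id, "_annotations.csv")), slide_id
  )
  mask <- read_mask(file.path(dir, paste0(slide_id, "_roi.png")))
  list(
    image = image, annotations = annotations,
    roi_truth = roi_mask(mask),
    true_pi = if (nrow(annotations$points)) ground_truth_pi(annotations) else NULL
  )
}

# Resolve the classifier argument into a prediction function.
.as_classifier_fn <- function(classifier, slide_id = NULL) {
  if (is.function(classifier)) return(classifier)
  if (inherits(classifier, "ki67_model")) {
    .check_not_trained_on(classifier, slide_id)
    return(function(image, grid) predict(classifier, image, grid))
  }
  if (is.list(classifier)) {
    if (length(classifier) != 3L ||
          !all(vapply(classifier, inherits, logical(1), "ki67_model"))) {
      stop("an ensemble classifier must be a list of exactly 3 models")
    }
    windows <- vapply(classifier, function(m) m$window, numeric(1))
    if (length(unique(windows)) != 1L) {
      stop("ensemble members must share one window size")
    }
    for (m in classifier) .check_not_trained_on(m, slide_id)
    return(function(image, grid) {
      ensemble_vote(lapply(classifier, function(m) predict(m, image, grid)))
    })
  }
  stop("`classifier` must be a function, a ki67_model, or a list of 3 models")
}

.check_not_trained_on <- function(model, slide_id) {
  if (!is.null(slide_id) && slide_id %in% model$train_slide_ids) {
    stop("slide '", slide_id, "' was in the training chunks of a component ",
         "model; evaluate it with a model that has not seen it")
  }
}

#' Estimate the proliferation index of one slide
#'
#' Runs one of the three estimation variants end to end:
#' \describe{
#'   \item{`base`}{skips the ROI stage and segments the whole image (the
#'     reference method).}
#'   \item{`roi`}{classifies fragments, accumulates the overlapping
#'     predictions into a fuzzy membership map, defuzzifies it into a
#'     binary ROI mask and segments only within it.}
#'   \item{`roi_bias`}{as `roi`, with the slide's own Otsu thresholds
#'     biased by reference thresholds from complementary training slides.}
#' }
#'
#' @param image a [slide_image()].
#' @param method `"roi"`, `"roi_bias"` or `"base"`.
#' @param classifier function `(image, grid) -> prediction_map`, a trained
#'   [train_model()] artifact, or a list of exactly 3 of them (majority
#'   vote). Default: [heuristic_classify()] with the config's parameters.
#' @param reference a [reference_thresholds()] result; required for
#'   `"roi_bias"`.
#' @param config a [pipeline_config()].
#' @return A `pi_estimate` (see [segment_and_estimate()]) with the ROI
#'   mask attached as attribute `"roi"` for the non-base methods.
#' @export
estimate_slide <- function(image, method = c("roi", "roi_bias", "base"),
                           classifier = NULL, reference = NULL,
                           config = pipeline_config()) {
  method <- match.arg(method)
  stopifnot(inherits(image, "slide_image"))
  if (method == "base") {
    return(segment_and_estimate(
      image, roi = NULL,
      closing_radius = config$closing_radius,
      dilation_radius = config$dilation_radius,
      min_threshold = config$min_threshold, method = "base"
    ))
  }
  if (is.null(classifier)) {
    classifier <- function(img, grid) {
      heuristic_classify(img, grid,
                         min_stained_fraction = config$min_stained_fraction,
                         density_cut = config$density_cut)
    }
  }
  cls_fn <- .as_classifier_fn(classifier, image$slide_id)
  grid <- build_grid(img_height(image), img_width(image),
                     config$window, config$eval_stride)
  pred <- cls_fn(image, grid)
  roi <- defuzzify(accumulate(pred), config$defuzz_cutoff)

  thresholds <- NULL
  if (method == "roi_bias") {
    if (is.null(reference)) {
      stop("method 'roi_bias' requires `reference` thresholds ",
           "(see reference_thresholds())")
    }
    hed <- rgb_to_hed(image)
    m <- if (roi$empty) matrix(TRUE, img_height(image), img_width(image)) else roi$mask
    own <- stain_thresholds(
      max(.otsu_or_inf(hed$dab, m), config$min_threshold),
      max(.otsu_or_inf(hed$hema, m), config$min_threshold),
      "otsu"
    )
    thresholds <- combine_thresholds(own, reference, config$bias_weight)
  }
  est <- segment_and_estimate(
    image, roi = roi, thresholds = thresholds,
    closing_radius = config$closing_radius,
    dilation_radius = config$dilation_radius,
    min_threshold = config$min_threshold, method = method
  )
  attr(est, "roi") <- roi
  est
}

#' K-fold training of three fragment classifiers
#'
#' Trains one model per training chunk triple: model *i* is trained on the
#' fragments of the two chunks other than *i* (labels from the
#' annotations, training stride = window size) and holds chunk *i* out for
#' evaluation. Slides of the testing chunk never enter any training pool.
#'
#' @param slides named list of slides; each element a list with `image`
#'   ([slide_image()]) and `annotations` ([annotation_set()]), e.g. a
#'   `synthetic_slide`. Names are slide ids.
#' @param partition a [partition_chunks()] result whose chunks 1..3 are
#'   the training chunks.
#' @param config a [training_config()].
#' @param window,input_size fragment window and network input size.
#' @return List of 3 `ki67_model`s; model `i` has `held_out_chunk = i` and
#'   `train_slide_ids` recording its training slides.
#' @export
train_kfold <- function(slides, partition, config = training_config(),
                        window = 96L, input_size = 32L) {
  stopifnot(inherits(partition, "chunk_partition"))
  if (length(partition$chunk_sizes) < 3L) {
    stop("k-fold training requires at least 3 training chunks")
  }
  ids <- names(slides)
  stopifnot(!is.null(ids), all(ids %in% names(partition$assignment)))
  collect <- function(chunks) {
    use <- ids[partition$assignment[ids] %in% chunks]
    frags <- list(); labs <- integer()
    for (id in use) {
      s <- slides[[id]]
      grid <- build_grid(img_height(s$image), img_width(s$image),
                         window, stride = window)
      lab <- label_fragments(grid, s$annotations)
      frags <- c(frags, lapply(seq_len(nrow(grid$origins)),
                               function(i) extract_fragment(s$image, grid, i)))
      labs <- c(labs, lab)
    }
    list(fragments = frags, labels = labs, slide_ids = use)
  }
  lapply(1:3, function(held_out) {
    train_chunks <- setdiff(1:3, held_out)
    pool <- collect(train_chunks)
    cfg <- config
    cfg$seed <- config$seed + held_out
    model <- train_model(pool$fragments, pool$labels, cfg,
                         window = window, input_size = input_size)
    model$held_out_chunk <- held_out
    model$train_slide_ids <- pool$slide_ids
    model
  })
}
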