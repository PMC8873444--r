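#' Construct a prediction map
#'
#' Per-fragment classifier outputs on a grid: a score in `[0, 1]` per
#' origin and a binary label, by convention `score >= 0.5` unless labels
#' are supplied explicitly (the stain-density heuristic uses its own
#' decision rule with scores scaled so the two agree).
#'
#' @param grid a [build_grid()] result.
#' @param scores numeric vector in `[0, 1]`, one per origin.
#' @param labels optional 0/1 vector; default `scores >= 0.5`.
#' @return An object of class `prediction_map`.
#' @export
prediction_map <- function(grid, scores, labels = NULL) {
  stopifnot(inherits(grid, "fragment_grid"))
  if (length(scores) != nrow(grid$origins)) {
    stop("scores length does not match the grid")
  }
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  if (is.null(labels)) labels <- as.integer(scores >= 0.5)
  labels <- as.integer(labels)
  if (length(labels) != length(scores) || any(!labels %in% c(0L, 1L))) {
    stop("labels must be 0/1 and match the scores")
  }
  structure(list(grid = grid, scores = scores, labels = labels),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  cat(sprintf("<prediction_map> %d fragments, %d positive (%.1f%%)\n",
              length(x$labels), sum(x$labels),
              100 * mean(x$labels)))
  invisible(x)
}

#' Cache a prediction map as CSV
#'
#' @param pred a `prediction_map`.
#' @param path CSV with columns `origin_row, origin_col, score, label`.
#' @param grid grid to validate against on read.
#' @return `path` invisibly (write); a `prediction_map` (read).
#' @export
write_prediction_csv <- function(pred, path) {
  write.csv(
    data.frame(origin_row = pred$grid$origins$row,
               origin_col = pred$grid$origins$col,
               score = pred$scores, label = pred$labels),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_prediction_csv
#' @export
read_prediction_csv <- function(grid, path) {
  df <- read.csv(path)
  if (nrow(df) != nrow(grid$origins) ||
        !all(df$origin_row == grid$origins$row) ||
        !all(df$origin_col == grid$origins$col)) {
    stop("cached predictions do not match the grid")
  }
  prediction_map(grid, df$score, df$label)
}

#' Training configuration for the fragment classifier
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 0.001, binary cross-entropy, batch size 128, 50 epochs, checkpointing
#' only on validation-loss improvement, and a stratified 4:1
#' train/validation split. `tiny_cnn` is a compact 3-conv-block network
#' (32 px input) that trains in seconds on a CPU; `paper_densenet` names
#' the full-scale densely-connected topology, which this package does not
#' train (see `train_model()`).
#'
#' @param architecture `"tiny_cnn"` or `"paper_densenet"`.
#' @param learning_rate Adam step size.
#' @param batch_size samples per gradient step.
#' @param epochs maximum training epochs.
#' @param bn_momentum batch-normalization momentum (echoed for
#'   architectures that use it; `tiny_cnn` has no BN layers).
#' @param valid_fraction held-out fraction for validation (0.2 = 4:1).
#' @param seed integer controlling initialization, split and shuffling.
#' @return A `training_config` list.
#' @export
training_config <- function(architecture = c("tiny_cnn", "paper_densenet"),
                            learning_rate = 0.001, batch_size = 128L,
                            epochs = 50L, bn_momentum = 0.1,
                            valid_fraction = 0.2, seed = 1L) {
  stopifnot(valid_fraction > 0, valid_fraction < 1,
            learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(
    list(architecture = match.arg(architecture),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), bn_momentum = bn_momentum,
         valid_fraction = valid_fraction, seed = as.integer(seed)),
    class = "training_config"
  )
}

# Fragments (list of w x w x 3 arrays, 0..255) -> (n, s, s, 3) in [0, 1]
.fragments_to_tensor <- function(fragments, size) {
  n <- length(fragments)
  x <- array(0, dim = c(n, size, size, 3))
  for (i in seq_len(n)) {
    x[i, , , ] <- resize_rgb(fragments[[i]], size) / 255
  }
  x
}

#' Train the binary fragment classifier
#'
#' Trains on a seeded, label-stratified 4:1 train/validation split with the
#' binary cross-entropy objective and Adam; after every epoch the model is
#' evaluated on the validation subset and the weights are checkpointed only
#' when the validation loss has improved. The returned artifact carries the
#' best-checkpoint weights, the full per-epoch log and a config echo.
#' Deterministic given `config$seed`.
#'
#' @param fragments list of `w x w x 3` pixel arrays (values 0..255), e.g.
#'   from [extract_fragment()] over one or more slides.
#' @param labels 0/1 vector, one per fragment (1 = contains at least one
#'   relevant cell).
#' @param config a [training_config()].
#' @param window fragment window size in pixels (recorded so prediction can
#'   refuse mismatched grids); default taken from the first fragment.
#' @param input_size side of the square network input; fragments are
#'   bilinearly resized to it.
#' @return An object of class `ki67_model` with fields `net` (weights),
#'   `config`, `window`, `input_size`, `log` (data.frame epoch /
#'   train_loss / valid_loss / checkpoint), `best_valid_loss`,
#'   `train_slide_ids` (filled by [train_kfold()]).
#' @export
train_model <- function(fragments, labels, config = training_config(),
                        window = NULL, input_size = 32L) {
  stopifnot(inherits(config, "training_config"))
  if (config$architecture == "paper_densenet") {
    stop("architecture 'paper_densenet' (121-layer densely-connected CNN) ",
         "is not trainable by this package; use architecture 'tiny_cnn'")
  }
  n <- length(fragments)
  if (n == 0L) stop("empty training pool")
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels length does not match fragments")
  if (length(unique(labels)) < 2L) {
    stop("training pool contains a single class; both labels are required")
  }
  window <- window %||% dim(fragments[[1]])[1]
  x <- .fragments_to_tensor(fragments, input_size)

  local_seed(config$seed, {
    # stratified 4:1 split
    valid_idx <- unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(labels == cl)
      k <- max(1L, round(length(idx) * config$valid_fraction))
      sample(idx, k)
    }))
    train_idx <- setdiff(seq_len(n), valid_idx)

    net <- nn_init(input_size = input_size, seed = config$seed)
    state <- adam_init(net$params)
    xv <- x[valid_idx, , , , drop = FALSE]; yv <- labels[valid_idx]
    best <- list(loss = Inf, params = net$params)
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      valid_loss = numeric(), checkpoint = logical())

    for (epoch in seq_len(config$epochs)) {
      ord <- sample(train_idx)
      batch_losses <- numeric()
      for (start in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1, length(ord))]
        xb <- x[bi, , , , drop = FALSE]; yb <- labels[bi]
        fwd <- nn_forward(net, xb, with_cache = TRUE)
        batch_losses <- c(batch_losses, nn_loss(fwd$z, yb))
        grads <- nn_backward(net, fwd, yb)
        upd <- adam_step(net$params, grads, state, lr = config$learning_rate)
        net$params <- upd$params; state <- upd$state
      }
      vloss <- nn_loss(nn_forward(net, xv)$z, yv)
      improved <- vloss < best$loss
      if (improved) best <- list(loss = vloss, params = net$params)
      log <- rbind(log, data.frame(
        epoch = epoch, train_loss = mean(batch_losses),
        valid_loss = vloss, checkpoint = improved
      ))
    }
    net$params <- best$params
    structure(
      list(net = net, config = config, window = window,
           input_size = input_size, log = log, best_valid_loss = best$loss,
           valid_idx = sort(valid_idx), train_slide_ids = character()),
      class = "ki67_model"
    )
  })
}

#' @export
print.ki67_model <- function(x, ...) {
  cat(sprintf(
    "<ki67_model> %s, window %d px, %d epochs trained, best valid loss %.4f\n",
    x$config$architecture, x$window, nrow(x$log), x$best_valid_loss))
  invisible(x)
}

#' Predict fragment labels over a grid
#'
#' Scores every fragment of `grid` with a trained model; labels are scores
#' thresholded at 0.5. The grid window must equal the window the model was
#' trained on.
#'
#' @param object a [train_model()] artifact.
#' @param image a [slide_image()].
#' @param grid a [build_grid()] result with `window == object$window`.
#' @param batch_size fragments scored per forward pass.
#' @param ... unused.
#' @return A [prediction_map()].
#' @export
predict.ki67_model <- function(object, image, grid, batch_size = 256L, ...) {
  stopifnot(inherits(image, "slide_image"), inherits(grid, "fragment_grid"))
  if (grid$window != object$window) {
    stop("grid window (", grid$window, " px) does not match the model's ",
         "training window (", object$window, " px)")
  }
  n <- nrow(grid$origins)
  scores <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    frags <- lapply(idx, function(i) extract_fragment(image, grid, i))
    xb <- .fragments_to_tensor(frags, object$input_size)
    z <- nn_forward(object$net, xb)$z
    scores[idx] <- 1 / (1 + exp(-z))
  }
  prediction_map(grid, scores)
}

#' Deterministic stain-density fragment classifier
#'
#' Reference classifier used to exercise the ROI and segmentation stages
#' without any training: a fragment is positive iff the fraction of its
#' pixels whose HED stain density (either DAB or hematoxylin channel)
#' exceeds `density_cut` is at least `min_stained_fraction`. At the default
#' settings, windows inside a tumor-cell cluster (tens of percent of
#' stained pixels) are accepted while windows holding only an isolated
#' lymphocyte or a compact stain blob (a few percent) are rejected.
#'
#' @param image a [slide_image()].
#' @param grid a [build_grid()] result.
#' @param min_stained_fraction acceptance threshold on the stained-pixel
#'   fraction.
#' @param density_cut optical-density cut defining a "stained" pixel;
#'   above typical background noise and diffuse haze.
#' @return A [prediction_map()]; scores are the stained fractions rescaled
#'   so that the decision boundary maps to 0.5.
#' @export
heuristic_classify <- function(image, grid, min_stained_fraction = 0.15,
                               density_cut = 0.2) {
  stopifnot(inherits(image, "slide_image"), inherits(grid, "fragment_grid"))
  hed <- rgb_to_hed(image)
  stained <- (hed$dab > density_cut) | (hed$hema > density_cut)
  h <- nrow(stained); w <- ncol(stained)
  cs <- matrix(0L, h + 1L, w + 1L)
  cum <- apply(stained, 2, cumsum)
  cs[-1, -1] <- t(apply(cum, 1, cumsum))
  r0 <- grid$origins$row; c0 <- grid$origins$col; win <- grid$window
  total <- cs[cbind(r0 + win + 1L, c0 + win + 1L)] -
    cs[cbind(r0 + 1L, c0 + win + 1L)] -
    cs[cbind(r0 + win + 1L, c0 + 1L)] +
    cs[cbind(r0 + 1L, c0 + 1L)]
  frac <- total / win^2
  scores <- pmin(1, frac / (2 * min_stained_fraction))
  prediction_map(grid, scores, labels = as.integer(frac >= min_stained_fraction))
}

#' Majority vote of three fragment classifiers
#'
#' Combines exactly three prediction maps on one shared grid: each
#' fragment's label is the one established by at least two component
#' models; mean scores are reported alongside but the labels come from the
#' vote.
#'
#' @param maps list of exactly 3 [prediction_map()]s on identical grids.
#' @return A [prediction_map()] with voted labels.
#' @export
ensemble_vote <- function(maps) {
  if (!is.list(maps) || length(maps) != 3L) {
    stop("ensemble_vote requires exactly 3 prediction maps")
  }
  lapply(maps, function(m) stopifnot(inherits(m, "prediction_map")))
  if (!same_grid(maps[[1]]$grid, maps[[2]]$grid) ||
        !same_grid(maps[[1]]$grid, maps[[3]]$grid)) {
    stop("prediction maps are on different grids")
  }
  votes <- maps[[1]]$labels + maps[[2]]$labels + maps[[3]]$labels
  labels <- as.integer(votes >= 2L)
  scores <- (maps[[1]]$scores + maps[[2]]$scores + maps[[3]]$scores) / 3
  prediction_map(maps[[1]]$grid, scores, labels = labels)
}
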