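# Fragment classifiers: CNN engine correctness, training discipline,
# the deterministic heuristic, and majority-vote ensembling.

test_that("network gradients match finite differences", {
  set.seed(1)
  net <- ki67roi:::nn_init(input_size = 8L, channels = c(2L, 3L), seed = 2L)
  x <- array(runif(4 * 8 * 8 * 3), dim = c(4, 8, 8, 3))
  y <- c(1, 0, 1, 0)
  fwd <- ki67roi:::nn_forward(net, x, with_cache = TRUE)
  grads <- ki67roi:::nn_backward(net, fwd, y)
  num_grad <- function(nm, idx, eps = 1e-5) {
    p <- net
    p$params[[nm]][idx] <- p$params[[nm]][idx] + eps
    lp <- ki67roi:::nn_loss(ki67roi:::nn_forward(p, x)$z, y)
    p$params[[nm]][idx] <- p$params[[nm]][idx] - 2 * eps
    lm <- ki67roi:::nn_loss(ki67roi:::nn_forward(p, x)$z, y)
    (lp - lm) / (2 * eps)
  }
  for (nm in names(net$params)) {
    for (k in 1:4) {
      idx <- sample(length(net$params[[nm]]), 1)
      expect_lt(abs(num_grad(nm, idx) - grads[[nm]][idx]), 1e-6)
    }
  }
})

# One shared training run reused by the checks below (seconds, not minutes)
sep <- make_separable_fragments(n_per_class = 60L, seed = 4L)
model <- train_model(sep$fragments, sep$labels,
                     training_config(epochs = 12L, seed = 5L), window = 32L)

test_that("training separates well-separated fragment classes", {
  xv <- ki67roi:::.fragments_to_tensor(sep$fragments[model$valid_idx], 32L)
  z <- ki67roi:::nn_forward(model$net, xv)$z
  acc <- mean((z > 0) == (sep$labels[model$valid_idx] == 1))
  expect_gte(acc, 0.95)
})

test_that("the training log and checkpoints honor the contract", {
  expect_lte(nrow(model$log), 12L)
  expect_lte(sum(model$log$checkpoint), nrow(model$log))
  # reloaded best weights correspond to the minimum logged validation loss
  expect_equal(model$best_valid_loss, min(model$log$valid_loss))
  expect_true(model$log$checkpoint[which.min(model$log$valid_loss)])
})

test_that("training is deterministic per seed from the first epoch", {
  short <- training_config(epochs = 1L, seed = 5L)
  idx <- c(1:20, 61:80)                # both classes present
  m1 <- train_model(sep$fragments[idx], sep$labels[idx], short, window = 32L)
  m2 <- train_model(sep$fragments[idx], sep$labels[idx], short, window = 32L)
  expect_identical(m1$log$train_loss, m2$log$train_loss)
  expect_identical(m1$net$params$Wd, m2$net$params$Wd)
})

test_that("degenerate training pools are rejected", {
  expect_error(train_model(list(), integer(), training_config()), "empty")
  expect_error(
    train_model(sep$fragments[1:10], rep(1L, 10), training_config()),
    "single class"
  )
  expect_error(
    train_model(sep$fragments, sep$labels,
                training_config(architecture = "paper_densenet")),
    "tiny_cnn"
  )
})

test_that("prediction scores a grid and refuses mismatched windows", {
  s <- generate_slide(small_config(seed = 6L, target_pi = 0.5))
  g <- build_grid(img_height(s$image), img_width(s$image), 32L, 32L)
  pred <- predict(model, s$image, g)
  expect_equal(length(pred$scores), nrow(g$origins))
  expect_true(all(pred$scores >= 0 & pred$scores <= 1))
  expect_identical(pred$labels, as.integer(pred$scores >= 0.5))

  g96 <- build_grid(img_height(s$image), img_width(s$image), 96L, 96L)
  expect_error(predict(model, s$image, g96), "window")

  blank <- flat_slide(255L, 96L, 96L)
  gb <- build_grid(96, 96, 32L, 32L)
  pb <- predict(model, blank, gb)
  expect_true(all(pb$labels == 0L))
})

test_that("the heuristic classifier is deterministic and sane", {
  blank <- flat_slide(255L, 96L, 96L)
  g <- build_grid(96, 96, 48, 48)
  expect_true(all(heuristic_classify(blank, g)$labels == 0L))

  dens <- matrix(0.8, 48, 48)
  nucleus <- render_from_stain_densities(dens, matrix(0, 48, 48))
  g1 <- build_grid(48, 48, 48, 48)
  expect_equal(heuristic_classify(nucleus, g1)$labels, 1L)
})

test_that("heuristic labels agree with annotation-derived labels", {
  # at a sensitivity matched to the one-cell labeling rule (one nucleus is
  # about 2% of a 96 px window), the stained-fraction heuristic reproduces
  # the annotation-derived fragment labels on a tumor-cluster slide
  cfg <- synthesis_config(seed = 10L, image_height = 512L, image_width = 512L,
                          n_clusters = 1L, nuclei_per_cluster = c(180L, 180L),
                          target_pi = 0.3, lymphocyte_count = 0L,
                          artifact_count = 0L)
  s <- generate_slide(cfg)
  g <- build_grid(512, 512, 96L, 16L)
  pred <- heuristic_classify(s$image, g, min_stained_fraction = 0.02)
  truth <- label_fragments(g, s$annotations)
  expect_gte(mean(pred$labels == truth), 0.9)
})

test_that("ensemble voting equals the majority function everywhere", {
  g <- build_grid(32, 32, 32, 32)
  mk <- function(lab) prediction_map(g, as.numeric(lab), labels = lab)
  combos <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  for (i in seq_len(nrow(combos))) {
    v <- unlist(combos[i, ])
    out <- ensemble_vote(list(mk(v[1]), mk(v[2]), mk(v[3])))
    expect_equal(out$labels, as.integer(sum(v) >= 2))
  }
})

test_that("ensembles are idempotent, symmetric, and strict about inputs", {
  g <- build_grid(64, 64, 32, 16)
  set.seed(2)
  n <- nrow(g$origins)
  maps <- lapply(1:3, function(i) prediction_map(g, runif(n)))
  same <- ensemble_vote(list(maps[[1]], maps[[1]], maps[[1]]))
  expect_identical(same$labels, maps[[1]]$labels)
  perm <- ensemble_vote(maps[c(3, 1, 2)])
  expect_identical(perm$labels, ensemble_vote(maps)$labels)
  expect_error(ensemble_vote(maps[1:2]), "exactly 3")
  g2 <- build_grid(64, 64, 32, 32)
  bad <- prediction_map(g2, runif(nrow(g2$origins)))
  expect_error(ensemble_vote(list(maps[[1]], maps[[2]], bad)), "different grids")
})

test_that("prediction maps cache to CSV and back", {
  dir <- withr::local_tempdir()
  g <- build_grid(64, 64, 32, 16)
  set.seed(4)
  pred <- prediction_map(g, runif(nrow(g$origins)))
  p <- file.path(dir, "pred.csv")
  write_prediction_csv(pred, p)
  back <- read_prediction_csv(g, p)
  expect_equal(back$scores, pred$scores)
  expect_identical(back$labels, pred$labels)
})
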