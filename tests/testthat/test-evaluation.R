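# Classification metrics, AUROC and PI error reports.

test_that("perfect and balanced confusions give the expected metrics", {
  truth <- c(1, 1, 0, 0, 1, 0)
  m <- classification_metrics(truth, truth)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  m2 <- classification_metrics(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(m2[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 0.5, precision = 0.5, recall = 0.5, f1 = 0.5))
})

test_that("metrics match brute-force confusion counting on random labels", {
  set.seed(3)
  for (rep in 1:5) {
    pred <- sample(0:1, 50, replace = TRUE)
    truth <- sample(0:1, 50, replace = TRUE)
    m <- classification_metrics(pred, truth)
    tp <- sum(pred & truth); tn <- sum(!pred & !truth)
    fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    expect_equal(m$counts, c(tp = tp, tn = tn, fp = fp, fn = fn))
    expect_equal(m$accuracy, (tp + tn) / 50)
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
  }
})

test_that("zero-denominator metrics are flagged undefined, not zero", {
  m <- classification_metrics(c(0, 0, 0), c(0, 0, 0))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$recall))
  expect_true(is.na(m$f1))
  expect_equal(m$accuracy, 1)
  expect_error(classification_metrics(c(0, 1), c(0, 1, 1)), "lengths differ")
})

test_that("AUROC equals the pairwise comparison probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  set.seed(6)
  for (rep in 1:5) {
    scores <- runif(30)
    truth <- sample(0:1, 30, replace = TRUE)
    if (length(unique(truth)) < 2) next
    pos <- scores[truth == 1]; neg <- scores[truth == 0]
    brute <- mean(outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n)))
    expect_equal(roc_auc(scores, truth), brute)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(8)
  scores <- runif(40)
  truth <- sample(0:1, 40, replace = TRUE)
  a <- roc_auc(scores, truth)
  expect_equal(roc_auc(qlogis(scores * 0.98 + 0.01), truth), a)
  expect_equal(roc_auc(scores^3, truth), a)
})

test_that("PI error reports follow the error formulas", {
  perfect <- pi_errors(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$n_invalid, 0L)

  r <- pi_errors(c(0.3, 0.5), c(0.2, 0.2))   # errors 0.1 and 0.3
  expect_equal(r$mae, 0.2)
  expect_equal(r$rmse, sqrt(0.05))
  expect_equal(r$n_invalid, 1L)              # only 0.3 exceeds 0.2 strictly
  exact <- pi_errors(c(0.4), c(0.2))         # error exactly 0.2: valid
  expect_equal(exact$n_invalid, 0L)
})

test_that("MAE never exceeds RMSE and the bootstrap CI brackets the MAE", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    est <- runif(n); tru <- runif(n)
    r <- pi_errors(est, tru, n_boot = 500L, seed = rep)
    expect_lte(r$mae, r$rmse + 1e-12)
    expect_gte(r$mae, r$ci_low - 1e-9)
    expect_lte(r$mae, r$ci_high + 1e-9)
    expect_gte(r$ci_low, 0)
  }
  same <- pi_errors(rep(0.4, 5), rep(0.2, 5))   # equal errors: MAE == RMSE
  expect_equal(same$mae, same$rmse)
})

test_that("bootstrap CIs shrink with the slide count and are seeded", {
  set.seed(11)
  err_small <- runif(10, 0, 0.2)
  err_big <- rep(err_small, 10)
  r10 <- pi_errors(err_small, rep(0, 10), n_boot = 2000L, seed = 1L)
  r100 <- pi_errors(err_big, rep(0, 100), n_boot = 2000L, seed = 1L)
  expect_lt(r100$ci_high - r100$ci_low, r10$ci_high - r10$ci_low)
  again <- pi_errors(err_small, rep(0, 10), n_boot = 2000L, seed = 1L)
  expect_equal(again$ci_low, r10$ci_low)
  expect_equal(again$ci_high, r10$ci_high)
})

test_that("report tables build, serialize and round-trip", {
  dir <- withr::local_tempdir()
  empty <- build_report(list())
  expect_equal(nrow(empty), 0L)
  r <- pi_errors(c(0.3, 0.5), c(0.2, 0.2))
  tab <- build_report(list(
    roi = list(subset = "test", model = "heuristic", window = 96L,
               biased = FALSE, report = r,
               metrics = classification_metrics(c(1, 0), c(1, 0)))
  ))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$mae, 0.2)
  expect_equal(tab$f1, 1)
  p <- file.path(dir, "report.csv")
  write.csv(tab, p, row.names = FALSE)
  back <- read.csv(p)
  expect_equal(back$mae, tab$mae)
  expect_equal(back$rmse, tab$rmse)
  md <- report_to_markdown(tab)
  expect_match(md[1], "mae")
  expect_equal(length(md), 3L)
})
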