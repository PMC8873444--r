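#' Fragment classification metrics
#'
#' Accuracy, precision, recall and F1 from predicted and true binary
#' fragment labels. A metric whose denominator is zero is reported as `NA`
#' (flagged undefined) rather than silently 0, so averaged summaries are
#' not biased.
#'
#' @param pred,truth 0/1 vectors of equal length.
#' @return A list with `accuracy`, `precision`, `recall`, `f1` and the
#'   confusion `counts` (tp, tn, fp, fn).
#' @export
classification_metrics <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) {
    stop("pred and truth lengths differ")
  }
  stopifnot(all(pred %in% 0:1), all(truth %in% 0:1))
  tp <- sum(pred == 1L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(
    accuracy = safe_div(tp + tn, tp + tn + fp + fn),
    precision = precision, recall = recall, f1 = f1,
    counts = c(tp = tp, tn = tn, fp = fp, fn = fn)
  )
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a randomly
#' chosen positive fragment outscores a randomly chosen negative one, with
#' ties counted one half.
#'
#' @param scores numeric classifier scores.
#' @param truth 0/1 vector of the same length.
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  stopifnot(length(scores) == length(truth), all(truth %in% 0:1))
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUROC undefined: both classes must be present")
  }
  r <- rank(scores)                    # midranks handle ties
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-slide proliferation-index error report
#'
#' Mean absolute error and root-mean-square error of estimated versus
#' ground-truth PI over a slide set, a percentile-bootstrap 95% confidence
#' interval of the MAE (lower bound clipped at 0, since the MAE is
#' non-negative), and the count of invalid estimations (slides with
#' absolute error strictly greater than 0.2).
#'
#' @param estimates numeric vector of estimated PIs, or a list of
#'   `pi_estimate` objects.
#' @param truths numeric vector of true PIs, or a list of
#'   [ground_truth_pi()] objects, parallel to `estimates`.
#' @param conf_level confidence level of the bootstrap interval.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed seed for the bootstrap resampling.
#' @param invalid_cutoff absolute-error threshold defining an invalid
#'   estimation (strict inequality).
#' @return An object of class `pi_error_report`: list with `errors`
#'   (per-slide absolute errors), `mae`, `rmse`, `ci_low`, `ci_high`,
#'   `n_invalid`, `n`.
#' @export
pi_errors <- function(estimates, truths, conf_level = 0.95,
                      n_boot = 10000L, seed = 1L, invalid_cutoff = 0.2) {
  if (is.list(estimates)) {
    estimates <- vapply(estimates, function(e) e$pi, numeric(1))
  }
  if (is.list(truths)) {
    truths <- vapply(truths, function(t) t$pi, numeric(1))
  }
  if (length(estimates) != length(truths)) {
    stop("estimate and truth slide sets differ in length")
  }
  n <- length(estimates)
  if (n == 0L) stop("no slides to evaluate")
  errors <- abs(estimates - truths)
  mae <- mean(errors)
  rmse <- sqrt(mean(errors^2))
  boot_mae <- local_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    rowMeans(matrix(errors[idx], nrow = n_boot))
  })
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(boot_mae, c(alpha, 1 - alpha), type = 7))
  structure(
    list(errors = errors, mae = mae, rmse = rmse,
         ci_low = max(0, ci[1]), ci_high = ci[2],
         n_invalid = sum(errors > invalid_cutoff), n = n),
    class = "pi_error_report"
  )
}

#' @export
print.pi_error_report <- function(x, ...) {
  cat(sprintf(
    "<pi_error_report> n = %d, MAE %.4f (95%% CI %.4f-%.4f), RMSE %.4f, %d invalid (> 0.2)\n",
    x$n, x$mae, x$ci_low, x$ci_high, x$rmse, x$n_invalid))
  invisible(x)
}

#' Tabulate per-method evaluation rows
#'
#' Collects named `pi_error_report`s (and optionally classification
#' metrics) into one data.frame shaped like the usual per-subset /
#' per-method comparison tables, writable as CSV or Markdown.
#'
#' @param rows named list; each element a list with fields among `subset`,
#'   `model`, `window`, `biased`, `report` (a `pi_error_report`) and
#'   `metrics` (from [classification_metrics()]).
#' @return A data.frame, one row per method.
#' @export
build_report <- function(rows) {
  if (length(rows) == 0L) {
    return(data.frame(
      method = character(), subset = character(), model = character(),
      window = integer(), biased = logical(), n = integer(),
      mae = numeric(), ci_low = numeric(), ci_high = numeric(),
      rmse = numeric(), n_invalid = integer(),
      accuracy = numeric(), precision = numeric(), recall = numeric(),
      f1 = numeric()
    ))
  }
  do.call(rbind, lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    rep <- r$report
    m <- r$metrics
    data.frame(
      method = nm,
      subset = r$subset %||% NA_character_,
      model = r$model %||% NA_character_,
      window = r$window %||% NA_integer_,
      biased = r$biased %||% NA,
      n = if (is.null(rep)) NA_integer_ else rep$n,
      mae = if (is.null(rep)) NA_real_ else rep$mae,
      ci_low = if (is.null(rep)) NA_real_ else rep$ci_low,
      ci_high = if (is.null(rep)) NA_real_ else rep$ci_high,
      rmse = if (is.null(rep)) NA_real_ else rep$rmse,
      n_invalid = if (is.null(rep)) NA_integer_ else rep$n_invalid,
      accuracy = if (is.null(m)) NA_real_ else m$accuracy,
      precision = if (is.null(m)) NA_real_ else m$precision,
      recall = if (is.null(m)) NA_real_ else m$recall,
      f1 = if (is.null(m)) NA_real_ else m$f1
    )
  }))
}

#' Render a report table as Markdown
#'
#' @param report data.frame from [build_report()].
#' @return Character vector of Markdown lines.
#' @export
report_to_markdown <- function(report) {
  fmt <- function(v) {
    ifelse(is.na(v), "-",
           ifelse(vapply(v, is.numeric, logical(1)),
                  formatC(unlist(v), digits = 4, format = "fg"),
                  as.character(v)))
  }
  header <- paste0("| ", paste(names(report), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(report)), collapse = "|"), "|")
  body <- apply(report, 1, function(row) {
    paste0("| ", paste(fmt(row), collapse = " | "), " |")
  })
  c(header, sep, body)
}
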