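#' Confusion counts for a positive class
#'
#' Counts true/false positives and negatives of predictions against truth,
#' with `positive` taken as the condition-positive class (one-vs-rest for
#' multi-class labels).
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param positive The class treated as positive.
#' @return A `confusion_counts` list: `TP`, `TN`, `FP`, `FN`, `P` (= TP+FN),
#'   `N` (= TN+FP), and `positive`.
#' @export
confusion_counts <- function(y_true, y_pred, positive) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length", call. = FALSE)
  }
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 P = tp + fn, N = tn + fp, positive = positive),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(P+N)`, sensitivity `TP/P`, specificity `TN/N`,
#' precision `TP/(TP+FP)` and F1 `2TP/(2TP+FP+FN)`. Metrics with a zero
#' denominator are reported as `NA` (undefined), never silently 0, so they
#' drop out of averages instead of biasing them.
#'
#' @param cc A `confusion_counts` object.
#' @return A `metrics_report` list with `acc`, `sen`, `spe`, `pre`, `f1`
#'   (proportions in `[0, 1]`, `NA` when undefined).
#' @export
compute_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  tot <- cc$P + cc$N
  if (tot == 0L) stop("no samples: P + N = 0", call. = FALSE)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    acc = (cc$TP + cc$TN) / tot,
    sen = safe(cc$TP, cc$P),
    spe = safe(cc$TN, cc$N),
    pre = safe(cc$TP, cc$TP + cc$FP),
    f1 = safe(2 * cc$TP, 2 * cc$TP + cc$FP + cc$FN)
  ), class = "metrics_report")
}

#' True positive and true negative rates
#'
#' `TPR = TP/P` and `TNR = TN/N` (numerically identical to sensitivity and
#' specificity; reported separately where the two outcome groups are survival
#' strata rather than disease states). Zero denominators give `NA`.
#'
#' @param cc A `confusion_counts` object.
#' @return Named numeric vector `c(tpr, tnr)`.
#' @export
tpr_tnr <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  c(tpr = if (cc$P > 0) cc$TP / cc$P else NA_real_,
    tnr = if (cc$N > 0) cc$TN / cc$N else NA_real_)
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", 100 * v)
  cat("ACC ", pct(x$acc), "  SEN ", pct(x$sen), "  SPE ", pct(x$spe),
      "  PRE ", pct(x$pre), "  F1 ",
      if (is.na(x$f1)) "undefined" else sprintf("%.4f", x$f1), "\n",
      sep = "")
  invisible(x)
}

# stratified fold assignment: within each class, shuffle and deal indices
# round-robin over 1..k, so class fold sizes differ by at most one
stratified_folds <- function(labels, k) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class '", cl, "' has ", length(idx), " samples, fewer than k = ",
           k, "; use a smaller k", call. = FALSE)
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs the full training protocol `runs` times: each run draws a fresh
#' seeded stratified k-fold partition; per fold, the class-modeling training
#' set is built from the training split (all target-class samples plus one
#' replicated donor per other class), a bidirectional LSTM is fitted (with
#' its standardizer learned on that training material), and the held-out fold
#' is scored. Metrics are averaged over folds within a run, then summarized
#' as mean and standard deviation over runs. For two classes the full metric
#' panel (ACC/SEN/SPE/PRE/F1, positive = `target_class`) is reported; with
#' more classes, overall accuracy.
#'
#' @param features List of `feature_sequence` objects.
#' @param labels Class labels, parallel to `features`.
#' @param k Number of folds (e.g. 2, 3 or 10; default 10).
#' @param runs Number of repeated runs (default 10).
#' @param seed Base seed; run `r` uses `seed + r - 1` for its fold draw and
#'   model training, so results are reproducible end to end.
#' @param target_class Class to model (default: first factor level).
#' @param class_modeling Build the class-modeling training set per fold
#'   (default `TRUE`); if `FALSE`, folds train on the raw training split.
#' @param batch_size Minibatch size for the per-fold models (default 16, a
#'   desk-scale setting that keeps the update count useful when training
#'   splits are small; pass 150 for the large-data configuration).
#' @param ... Further arguments to [frp_lstm()] (`hidden_size`, `epochs`,
#'   `learning_rate`, ...).
#' @return A `cv_result`: `folds` (per-run per-fold metric data frame),
#'   `summary` (mean and sd over runs, per metric), `fold_assignments`
#'   (per-run integer vectors), `histories` (per-fold training histories),
#'   `k`, `runs`, `classes`.
#' @export
repeated_kfold_cv <- function(features, labels, k = 10L, runs = 10L,
                              seed = 1L, target_class = NULL,
                              class_modeling = TRUE, batch_size = 16L, ...) {
  labels <- as.factor(labels)
  classes <- levels(labels)
  if (is.null(target_class)) target_class <- classes[1L]
  k <- as.integer(k); runs <- as.integer(runs)
  rows <- list()
  fold_assignments <- vector("list", runs)
  histories <- list()
  for (r in seq_len(runs)) {
    run_seed <- as.integer(seed) + r - 1L
    fold <- withr::with_seed(run_seed, stratified_folds(labels, k))
    fold_assignments[[r]] <- fold
    for (f in seq_len(k)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      train_x <- features[tr]
      train_y <- labels[tr]
      if (class_modeling) {
        cm <- build_class_modeling_set(train_x, train_y, target_class)
        train_x <- cm$features
        train_y <- cm$labels
      }
      fit <- frp_lstm(train_x, train_y, batch_size = batch_size,
                      seed = run_seed, ...)
      pred <- predict(fit, features[te])
      truth <- factor(as.character(labels[te]), levels = fit$classes)
      acc <- mean(pred == truth)
      if (length(classes) == 2L) {
        m <- compute_metrics(confusion_counts(truth, pred, target_class))
        rows[[length(rows) + 1L]] <- data.frame(
          run = r, fold = f, acc = acc, sen = m$sen, spe = m$spe,
          pre = m$pre, f1 = m$f1)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          run = r, fold = f, acc = acc, sen = NA_real_, spe = NA_real_,
          pre = NA_real_, f1 = NA_real_)
      }
      histories[[length(histories) + 1L]] <- cbind(run = r, fold = f,
                                                   fit$history)
    }
  }
  folds_df <- do.call(rbind, rows)
  metrics <- c("acc", "sen", "spe", "pre", "f1")
  run_means <- stats::aggregate(folds_df[metrics],
                                by = list(run = folds_df$run),
                                FUN = mean, na.rm = TRUE)
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(run_means[[m]]), numeric(1L)),
    sd = vapply(metrics, function(m) stats::sd(run_means[[m]]), numeric(1L))
  )
  rownames(summ) <- NULL
  structure(list(folds = folds_df, summary = summ,
                 fold_assignments = fold_assignments,
                 histories = do.call(rbind, histories),
                 k = k, runs = runs, classes = classes,
                 target_class = target_class, seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(x$runs, " run(s) of ", x$k, "-fold stratified cross-validation (",
      length(x$classes), " classes, target '", x$target_class, "')\n",
      sep = "")
  for (i in seq_len(nrow(x$summary))) {
    m <- x$summary[i, ]
    if (is.nan(m$mean) || is.na(m$mean)) next
    if (m$metric == "f1") {
      cat(sprintf("  %-4s %.3f ± %.3f\n", toupper(m$metric), m$mean,
                  if (is.na(m$sd)) 0 else m$sd))
    } else {
      cat(sprintf("  %-4s %.2f ± %.2f %%\n", toupper(m$metric),
                  100 * m$mean, 100 * if (is.na(m$sd)) 0 else m$sd))
    }
  }
  invisible(x)
}

#' Write a cross-validation report
#'
#' Writes the metric summary as JSON and, alongside it, a plain-text table
#' with `mean ± sd` in percent.
#'
#' @param cv A `cv_result`.
#' @param path Output JSON path; the text table goes to `<path>.txt`.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  jsonlite::write_json(list(
    k = cv$k, runs = cv$runs, classes = cv$classes,
    target_class = cv$target_class,
    summary = cv$summary, folds = cv$folds
  ), path, auto_unbox = TRUE, digits = NA)
  txt <- utils::capture.output(print(cv))
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
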