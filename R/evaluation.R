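# Classification metrics, ROC/AUC and the repeated, leakage-safe
# cross-validation protocol.

#' Binary classification metrics at a threshold
#'
#' Confusion counts at `threshold` (a call is positive when probability
#' strictly exceeds it) plus precision, accuracy, recall, F1, Matthews
#' correlation coefficient and trapezoidal ROC AUC. The AUC is computed
#' on the continuous probabilities (rank statistic; ties contribute
#' half), never on binarized calls. Metrics with a zero denominator are
#' reported as 0; a single-class label vector leaves the AUC undefined
#' (`NA` with a warning), while the thresholded metrics are still
#' returned.
#'
#' @param labels Binary vector.
#' @param probabilities Numeric vector, same length.
#' @param threshold Decision threshold, default 0.5.
#' @return A list of class `metrics_report`.
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities),
            all(labels %in% c(0, 1)), !any(is.na(probabilities)))
  labels <- as.integer(labels)
  calls <- as.integer(probabilities > threshold)
  tp <- sum(calls == 1L & labels == 1L)
  fp <- sum(calls == 1L & labels == 0L)
  tn <- sum(calls == 0L & labels == 0L)
  fn <- sum(calls == 0L & labels == 1L)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  accuracy <- safe_div(tp + tn, length(labels))
  f1 <- safe_div(2 * precision * recall, precision + recall)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  auc <- if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined for a single-class label vector", call. = FALSE)
    NA_real_
  } else {
    r <- rank(probabilities)  # average ranks: ties count one half
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(precision = precision, accuracy = accuracy, recall = recall,
                 f1 = f1, mcc = mcc, auc = auc, threshold = threshold,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f  ",
                     "mcc %.4f  auc %s\n"),
              x$accuracy, x$precision, x$recall, x$f1, x$mcc,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  cat(sprintf("counts @%.2f: TP %d FP %d TN %d FN %d\n", x$threshold,
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' ROC curve points
#'
#' False/true positive rates over all score thresholds, suitable for
#' plotting or CSV export.
#'
#' @inheritParams compute_metrics
#' @return Data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(labels, probabilities) {
  ord <- order(probabilities, decreasing = TRUE)
  lab <- as.integer(labels)[ord]
  n1 <- sum(lab == 1L)
  n0 <- sum(lab == 0L)
  thr <- probabilities[ord]
  keep <- !duplicated(thr, fromLast = TRUE)  # one point per distinct score
  data.frame(threshold = c(Inf, thr[keep]),
             fpr = c(0, cumsum(lab == 0L)[keep] / max(n0, 1L)),
             tpr = c(0, cumsum(lab == 1L)[keep] / max(n1, 1L)))
}

#' Label-stratified k-fold assignment
#' @noRd
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

default_cv_trainer <- function(train_records, scheme, config, tables) {
  feats <- encode_dataset(train_records, scheme, tables)
  train_model(build_binding_model(config), feats, train_records$label, config)
}

default_cv_scorer <- function(model, records, tables) {
  predict_prob(model, encode_dataset(records, model$scheme, tables))
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat a fresh label-stratified shuffle assigns records to k
#' folds; each fold is scored by a model trained on the remaining folds.
#' Encoder tables are rebuilt from each training fold only (the AAPP
#' table never sees a held-out record), unless `leakage_safe = FALSE`,
#' which mimics building the table from the whole dataset.
#'
#' @param dataset Pair data.frame with binary `label`.
#' @param scheme Fusion scheme.
#' @param config A [model_config()] used by the default trainer.
#' @param k Number of folds (>= 2).
#' @param repeats Number of repeats.
#' @param seeds Integer vector, one seed per repeat.
#' @param trainer,scorer Pluggable `trainer(train_records, scheme,
#'   config, tables) -> model` and `scorer(model, records, tables) ->
#'   probabilities`. Defaults train and score the convolutional model;
#'   tests substitute cheap scorers to exercise the protocol.
#' @param leakage_safe Rebuild AAPP tables per training fold (default).
#' @param phychem Optional `phychem_table` for phychem-* schemes.
#' @return A list of class `cv_report`: `metrics` (one row per repeat x
#'   fold), `assignments` (fold vector per repeat), `seeds`, and
#'   `aapp_tcr_counts` (per repeat/fold, the repertoire sizes of the
#'   AAPP table actually used, for leakage audits).
#' @export
cross_validate <- function(dataset, scheme = "onehot-aapp",
                           config = model_config(scheme = scheme),
                           k = 5L, repeats = 4L,
                           seeds = config$seed + seq_len(repeats),
                           trainer = default_cv_trainer,
                           scorer = default_cv_scorer,
                           leakage_safe = TRUE,
                           phychem = NULL) {
  k <- as.integer(k)
  repeats <- as.integer(repeats)
  stopifnot(k >= 2L, repeats >= 1L)
  if (nrow(dataset) < k) stop("dataset smaller than k", call. = FALSE)
  if (length(seeds) != repeats) stop("need one seed per repeat", call. = FALSE)
  rows <- list()
  assignments <- vector("list", repeats)
  aapp_counts <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(dataset$label, k, seeds[r])
    assignments[[r]] <- fold
    aapp_counts[[r]] <- vector("list", k)
    for (f in seq_len(k)) {
      train <- dataset[fold != f, , drop = FALSE]
      test <- dataset[fold == f, , drop = FALSE]
      aapp_source <- if (leakage_safe) train else dataset
      tables <- list(aapp = build_aapp_table(
                       aapp_source[aapp_source$label == 1L, , drop = FALSE]),
                     phychem = phychem)
      aapp_counts[[r]][[f]] <- tables$aapp$tcr_counts
      model <- trainer(train, scheme, config, tables)
      prob <- scorer(model, test, tables)
      m <- compute_metrics(test$label, prob)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, fold = f, n_test = nrow(test),
        precision = m$precision, accuracy = m$accuracy, recall = m$recall,
        f1 = m$f1, mcc = m$mcc, auc = m$auc)
    }
  }
  structure(list(metrics = do.call(rbind, rows), assignments = assignments,
                 seeds = seeds, k = k, repeats = repeats,
                 aapp_tcr_counts = aapp_counts),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d-fold x %d repeat(s)>\n", x$k, x$repeats))
  cat(sprintf("mean accuracy %.4f, mean AUC %.4f\n",
              mean(x$metrics$accuracy), mean(x$metrics$auc)))
  invisible(x)
}

#' Write a CV report's per-fold metrics to CSV
#' @param report A `cv_report`.
#' @param path Output path.
#' @export
write_cv_report <- function(report, path) {
  utils::write.csv(report$metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
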