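test_that("compute_metrics matches direct confusion arithmetic", {
  # 8 TP, 2 FN among 10 positives; 9 TN, 1 FP among 10 negatives
  labels <- c(rep(1, 10), rep(0, 10))
  prob <- c(rep(0.9, 8), rep(0.1, 2), rep(0.2, 9), 0.8)
  m <- compute_metrics(labels, prob)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(8, 1, 9, 2))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
  expect_equal(m$mcc, (8 * 9 - 1 * 2) / sqrt(9 * 10 * 10 * 11))
})

test_that("perfect separation and degenerate cases behave", {
  labels <- c(1, 1, 0, 0)
  perfect <- compute_metrics(labels, c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$auc, 1)

  flat <- compute_metrics(labels, rep(0.7, 4))
  expect_equal(flat$auc, 0.5)       # uninformative scores
  expect_equal(flat$precision, 0.5)

  # all-negative calls: zero denominators collapse to 0, not NaN
  none <- compute_metrics(labels, rep(0.1, 4))
  expect_equal(none$precision, 0)
  expect_equal(none$mcc, 0)

  expect_warning(single <- compute_metrics(c(1, 1), c(0.2, 0.9)), "AUC undefined")
  expect_true(is.na(single$auc))
  expect_equal(single$recall, 0.5)  # threshold metrics still computed
})

test_that("AUC equals all-pairs concordance and survives permutation", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    prob <- round(runif(n), 2)  # rounding injects ties
    m <- compute_metrics(labels, prob)
    expect_equal(m$auc, auc_bruteforce(labels, prob))
    perm <- sample(n)
    m2 <- compute_metrics(labels[perm], prob[perm])
    expect_equal(m2$auc, m$auc)
    expect_equal(m2$accuracy, m$accuracy)
    expect_equal(m2$mcc, m$mcc)
  }
})

test_that("roc_points starts at (0,0), ends at (1,1) and is monotone", {
  set.seed(3)
  labels <- rbinom(60, 1, 0.5)
  labels[1:2] <- c(0, 1)
  prob <- round(runif(60), 2)
  roc <- roc_points(labels, prob)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("cross_validate partitions, stratifies and reproduces folds", {
  ds <- tiny_dataset(n_pep = 6, tcrs = 10, seed = 51)
  rep1 <- cross_validate(ds, k = 5, repeats = 2, seeds = c(7, 8),
                         trainer = cheap_trainer, scorer = cheap_scorer)
  expect_s3_class(rep1, "cv_report")
  expect_equal(nrow(rep1$metrics), 10L)
  for (r in 1:2) {
    fold <- rep1$assignments[[r]]
    expect_length(fold, nrow(ds))
    for (cls in 0:1) {
      sizes <- table(fold[ds$label == cls])
      expect_lte(diff(range(sizes)), 1)  # stratified balance
    }
  }
  rep2 <- cross_validate(ds, k = 5, repeats = 2, seeds = c(7, 8),
                         trainer = cheap_trainer, scorer = cheap_scorer)
  expect_identical(rep1$assignments, rep2$assignments)
  expect_identical(rep1$metrics, rep2$metrics)

  expect_error(cross_validate(ds[1:3, ], k = 5, trainer = cheap_trainer,
                              scorer = cheap_scorer), "smaller")
  expect_error(cross_validate(ds, k = 5, repeats = 2, seeds = 1,
                              trainer = cheap_trainer, scorer = cheap_scorer),
               "seed")
})

test_that("per-fold AAPP tables never see held-out records", {
  ds <- tiny_dataset(n_pep = 5, tcrs = 8, seed = 61)
  rep1 <- cross_validate(ds, k = 4, repeats = 1, seeds = 5,
                         trainer = cheap_trainer, scorer = cheap_scorer)
  fold <- rep1$assignments[[1]]
  for (f in 1:4) {
    train_pos <- ds[fold != f & ds$label == 1, ]
    expected <- build_aapp_table(train_pos)$tcr_counts
    expect_identical(rep1$aapp_tcr_counts[[1]][[f]], expected)
  }
  # non-leakage-safe mode uses the whole dataset's positives
  rep2 <- cross_validate(ds, k = 4, repeats = 1, seeds = 5,
                         trainer = cheap_trainer, scorer = cheap_scorer,
                         leakage_safe = FALSE)
  full <- build_aapp_table(ds[ds$label == 1, ])$tcr_counts
  for (f in 1:4) expect_identical(rep2$aapp_tcr_counts[[1]][[f]], full)
})

test_that("the anchor-match scorer recovers planted signal under CV", {
  # sanity that the protocol, not the CNN, is exercised here: with a
  # strong motif the cheap scorer must rank positives above negatives
  ds <- tiny_dataset(n_pep = 6, tcrs = 12, strength = 1, seed = 71)
  rep1 <- cross_validate(ds, k = 3, repeats = 1, seeds = 2,
                         trainer = cheap_trainer, scorer = cheap_scorer)
  expect_gt(mean(rep1$metrics$auc), 0.8)
  f <- tempfile(fileext = ".csv")
  write_cv_report(rep1, f)
  expect_equal(nrow(read.csv(f)), 3L)
})
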