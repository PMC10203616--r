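# Model tests use deliberately tiny datasets and epoch counts; the
# full-scale signal-recovery run lives in test-acceptance.R.

make_tiny_model_bits <- function(seed = 5, n_pep = 3, tcrs = 4) {
  ds <- tiny_dataset(n_pep = n_pep, tcrs = tcrs, seed = seed)
  tables <- list(aapp = build_aapp_table(ds[ds$label == 1, , drop = FALSE]))
  feats <- encode_dataset(ds, "onehot-aapp", tables)
  list(ds = ds, tables = tables, feats = feats)
}

test_that("untrained model emits softmax probabilities", {
  bits <- make_tiny_model_bits()
  model <- build_binding_model(model_config(seed = 1))
  fw <- tcrbinder:::nn_forward(model$net, bits$feats$X1, bits$feats$X2)
  expect_equal(rowSums(fw$prob), rep(1, nrow(bits$ds)), tolerance = 1e-12)
  expect_true(all(fw$prob >= 0 & fw$prob <= 1))
})

test_that("training reduces the loss and records one value per epoch", {
  bits <- make_tiny_model_bits()
  cfg <- model_config(epochs = 3L, seed = 8)
  model <- train_model(build_binding_model(cfg), bits$feats, bits$ds$label, cfg)
  expect_length(model$history, 3L)
  expect_lte(model$history[3], model$history[1])
  expect_true(model$trained)
  expect_error(train_model(build_binding_model(cfg),
                           list(X1 = bits$feats$X1[0, , drop = FALSE],
                                X2 = bits$feats$X2[0, , drop = FALSE]),
                           integer(0), cfg),
               "empty")
})

test_that("a positive and a negative example are memorized", {
  bits <- make_tiny_model_bits(seed = 9)
  two <- rbind(bits$ds[bits$ds$label == 1, ][1, ], bits$ds[bits$ds$label == 0, ][1, ])
  f2 <- encode_dataset(two, "onehot-aapp", bits$tables)
  cfg <- model_config(epochs = 20L, batch_size = 2L, seed = 3)
  m <- train_model(build_binding_model(cfg), f2, two$label, cfg)
  p <- predict_prob(m, f2)
  expect_gt(p[1], 0.5)
  expect_lt(p[2], 0.5)
})

test_that("training is reproducible under a fixed seed", {
  bits <- make_tiny_model_bits()
  cfg <- model_config(epochs = 2L, seed = 21)
  m1 <- train_model(build_binding_model(cfg), bits$feats, bits$ds$label, cfg)
  m2 <- train_model(build_binding_model(cfg), bits$feats, bits$ds$label, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(predict_prob(m1, bits$feats), predict_prob(m2, bits$feats))
})

test_that("batch prediction equals one-by-one prediction", {
  bits <- make_tiny_model_bits()
  model <- build_binding_model(model_config(seed = 2))
  all_at_once <- predict_prob(model, bits$feats)
  one_by_one <- vapply(seq_len(nrow(bits$ds)), function(i) {
    predict_prob(model, list(X1 = bits$feats$X1[i, , drop = FALSE],
                             X2 = bits$feats$X2[i, , drop = FALSE]))
  }, numeric(1))
  expect_equal(all_at_once, one_by_one, tolerance = 1e-12)
})

test_that("assign_binding_level reproduces the published partition", {
  expect_equal(assign_binding_level(c(0.4, 0.6, 0.9, 0.96)),
               c("non-binding", "low", "medium", "high"))
  # boundaries: 0.5 and 0.95 are not strictly above their cuts
  expect_equal(assign_binding_level(c(0.5, 0.8, 0.95)),
               c("non-binding", "medium", "medium"))
  expect_error(assign_binding_level(1.2), "\\[0, 1\\]")
  expect_error(assign_binding_level(c(0.3, NA)), "\\[0, 1\\]")
})

test_that("predict_pairs keeps order, fills levels and isolates bad rows", {
  bits <- make_tiny_model_bits()
  model <- build_binding_model(model_config(seed = 4))
  pairs <- rbind(bits$ds[1:3, c("peptide", "cdr3")],
                 data.frame(peptide = "BADXX", cdr3 = "CASSLGQF"))
  res <- suppressWarnings(predict_pairs(model, pairs, bits$tables))
  expect_equal(res$peptide, pairs$peptide)
  expect_equal(res$cdr3, pairs$cdr3)
  expect_equal(res$interaction[1:3], as.integer(res$probability[1:3] > 0.5))
  expect_equal(res$binding_level[1:3], assign_binding_level(res$probability[1:3]))
  expect_true(is.na(res$probability[4]))
  errs <- attr(res, "errors")
  expect_equal(errs$row, 4L)
  expect_match(errs$reason, "alphabet|length")

  f <- tempfile(fileext = ".csv")
  write_predictions(res, f)
  header <- readLines(f, n = 1)
  expect_equal(header, "peptide,cdr3,probability,interaction,binding_level")
})

test_that("rank_tcrs_for_peptide sorts by probability with lexicographic ties", {
  bits <- make_tiny_model_bits()
  model <- build_binding_model(model_config(seed = 6))
  pep <- bits$ds$peptide[1]
  cands <- unique(bits$ds$cdr3)[1:5]
  ranked <- suppressWarnings(rank_tcrs_for_peptide(model, pep, cands, bits$tables))
  expect_equal(nrow(ranked), 5L)
  expect_true(all(diff(ranked$probability) <= 0))
  plain <- suppressWarnings(predict_pairs(
    model, data.frame(peptide = pep, cdr3 = cands), bits$tables))
  reord <- plain[order(-plain$probability, plain$cdr3), ]
  expect_equal(ranked$cdr3, reord$cdr3)
  expect_equal(nrow(suppressWarnings(
    rank_tcrs_for_peptide(model, pep, cands[1], bits$tables))), 1L)
  expect_error(rank_tcrs_for_peptide(model, pep, character(0), bits$tables),
               "candidate")
})

test_that("save/load round trip preserves predictions bit for bit", {
  bits <- make_tiny_model_bits()
  cfg <- model_config(epochs = 2L, seed = 13)
  model <- train_model(build_binding_model(cfg), bits$feats, bits$ds$label, cfg)
  dir <- tempfile()
  save_binding_model(model, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  back <- load_binding_model(dir)
  expect_identical(predict_prob(back, bits$feats), predict_prob(model, bits$feats))
  expect_equal(back$scheme, model$scheme)
  expect_identical(back$residue_order, model$residue_order)
})
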