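# The dual-input convolutional binding model: configuration, build,
# train, predict, rank, persist.

#' Model and training configuration
#'
#' Defaults reproduce the published architecture and training protocol:
#' module 1 convolutions of 16 filters (3 x 2) and 32 filters (6 x 4),
#' module 2 convolution of 16 filters (1 x 2), max pooling with kernel 2
#' and stride 1, batch normalization after the first module-1
#' convolution and after every pooling layer, per-module dense width 128,
#' fusion dense layers of 256 and 128 units with L2 penalty 0.01,
#' dropout 0.3 before the 2-unit softmax output, Adagrad at learning
#' rate 0.01 minimizing MSE, 60 epochs with batch size 20. All hidden
#' activations are ReLU; convolutions use valid padding.
#'
#' @param scheme Fusion scheme (see [fuse_pair()]); fixes the two input
#'   shapes (640 = 32 x 20 and 400 = 20 x 20 variables for the default
#'   `"onehot-aapp"`).
#' @param epochs,batch_size,learning_rate,l2,dropout Training knobs.
#' @param module_dense Width of each module's terminal dense layer.
#' @param seed Integer seed governing initialization, shuffling and
#'   dropout.
#' @param n_phychem_scales Number of scales in the phychem table (used
#'   only to size the module-1 input for phychem-* schemes).
#' @return A list of class `model_config`.
#' @export
model_config <- function(scheme = "onehot-aapp", epochs = 60L, batch_size = 20L,
                         learning_rate = 0.01, l2 = 0.01, dropout = 0.3,
                         module_dense = 128L, seed = 42L,
                         n_phychem_scales = 21L) {
  if (!scheme %in% FUSION_SCHEMES) {
    stop("unknown fusion scheme '", scheme, "'", call. = FALSE)
  }
  parts <- strsplit(scheme, "-", fixed = TRUE)[[1]]
  input1 <- c(PAIR_ROWS, if (parts[1] == "onehot") length(AA_ALPHABET)
              else as.integer(n_phychem_scales))
  input2 <- if (parts[2] == "aapp") c(length(AAPP_POSITIONS), length(AA_ALPHABET))
            else c(2L, length(AA_ALPHABET))
  stopifnot(dropout >= 0, dropout < 1, module_dense > 0, epochs >= 1, batch_size >= 1)
  structure(list(
    scheme = scheme,
    input1 = as.integer(input1), input2 = as.integer(input2),
    m1_conv1 = list(filters = 16L, kernel = c(3L, 2L)),
    m1_conv2 = list(filters = 32L, kernel = c(6L, 4L)),
    m2_conv = list(filters = 16L, kernel = c(1L, 2L)),
    pool = list(size = 2L, stride = 1L),
    module_dense = as.integer(module_dense),
    fusion_dense = c(256L, 128L),
    l2 = l2, dropout = dropout,
    optimizer = "adagrad", learning_rate = learning_rate, loss = "mse",
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    seed = as.integer(seed)), class = "model_config")
}

#' Build an untrained dual-input binding model
#'
#' Instantiates the network of [model_config()] with seeded Glorot
#' initialization. The module-1 input accepts `prod(config$input1)`
#' scalars and the module-2 input `prod(config$input2)` (640 and 400 for
#' the default scheme).
#'
#' @param config A [model_config()].
#' @return A list of class `binding_model` (untrained).
#' @export
build_binding_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  net <- nn_init(config)
  structure(list(net = net, config = config, scheme = config$scheme,
                 trained = FALSE, history = numeric(),
                 residue_order = AA_ALPHABET, padding = "right",
                 thresholds = c(call = 0.5, medium = 0.8, high = 0.95)),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("<binding_model %s: inputs %d + %d, %s, %d epoch(s) trained>\n",
              x$scheme, prod(x$config$input1), prod(x$config$input2),
              if (x$trained) "trained" else "untrained", length(x$history)))
  invisible(x)
}

#' Encode a pair set into the two model input matrices
#'
#' Rows follow the input record order; each row is the column-major
#' flattening of the pair's module-1 and module-2 feature maps. The
#' module-2 AAPP map is resolved once per unique peptide (with the
#' minimum-edit-distance fallback for unseen peptides).
#'
#' @param records Pair data.frame with `peptide` and `cdr3`.
#' @param scheme Fusion scheme.
#' @param tables List of encoder tables (see [fuse_pair()]).
#' @return List with matrices `X1` (n x prod(input1)) and `X2`
#'   (n x prod(input2)).
#' @export
encode_dataset <- function(records, scheme = "onehot-aapp", tables = list()) {
  n <- nrow(records)
  parts <- strsplit(scheme, "-", fixed = TRUE)[[1]]
  m2_cache <- new.env(parent = emptyenv())
  enc <- lapply(seq_len(n), function(i) {
    pep <- records$peptide[i]
    m1 <- if (parts[1] == "onehot") encode_onehot_pair(pep, records$cdr3[i])
          else encode_phychem_pair(pep, records$cdr3[i], tables$phychem)
    m2 <- if (parts[2] == "aapp") {
      if (!exists(pep, envir = m2_cache, inherits = FALSE)) {
        assign(pep, lookup_aapp(pep, tables$aapp), envir = m2_cache)
      }
      get(pep, envir = m2_cache, inherits = FALSE)
    } else {
      rbind(compute_aac(pep), compute_aac(records$cdr3[i]))
    }
    list(as.vector(unclass(m1)), as.vector(unclass(m2)))
  })
  list(X1 = do.call(rbind, lapply(enc, `[[`, 1)),
       X2 = do.call(rbind, lapply(enc, `[[`, 2)))
}

#' Train a binding model
#'
#' Minimizes the mean squared error between the softmax output and
#' one-hot labels with Adagrad. Shuffling and dropout are driven by
#' `config$seed`, so training is reproducible.
#'
#' @param model An untrained (or partially trained) `binding_model`.
#' @param features List with `X1`/`X2` from [encode_dataset()].
#' @param labels Binary vector (1 = interacting), one per row.
#' @param config Training configuration; defaults to the model's own.
#' @param verbose Print per-epoch loss.
#' @return The trained `binding_model` with `history` holding one
#'   regularized training-loss value per epoch.
#' @export
train_model <- function(model, features, labels, config = model$config,
                        verbose = FALSE) {
  stopifnot(inherits(model, "binding_model"))
  X1 <- features$X1; X2 <- features$X2
  n <- nrow(X1)
  if (is.null(n) || n == 0L) stop("empty training set", call. = FALSE)
  stopifnot(nrow(X2) == n, length(labels) == n, all(labels %in% c(0, 1)))
  Y <- cbind(1 - labels, labels)  # positive class is output column 2
  net <- model$net
  acc <- adagrad_init(net$params)
  lr <- config$learning_rate
  history <- numeric(config$epochs)

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        fw <- nn_forward(net, X1[idx, , drop = FALSE], X2[idx, , drop = FALSE],
                         training = TRUE)
        net$buffers[names(fw$buffers)] <- fw$buffers
        batch_losses <- c(batch_losses, nn_loss(net, fw$prob, Y[idx, , drop = FALSE]))
        grads <- nn_backward(net, fw$cache, Y[idx, , drop = FALSE])
        upd <- adagrad_step(net$params, grads, acc, lr)
        net$params <- upd$params
        acc <- upd$acc
      }
      history[epoch] <- mean(batch_losses)
      if (verbose) message(sprintf("epoch %d/%d loss %.5f", epoch, config$epochs,
                                   history[epoch]))
    }
  })
  model$net <- net
  model$trained <- TRUE
  model$history <- c(model$history, history)
  model
}

#' Positive-class probabilities for encoded features
#'
#' Inference pass (running batch-norm statistics, no dropout), processed
#' in fixed-size chunks; per-sample output is independent of batching.
#'
#' @param model Trained `binding_model`.
#' @param features List with `X1`/`X2`.
#' @param chunk Rows per forward pass.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_prob <- function(model, features, chunk = 64L) {
  n <- nrow(features$X1)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- nn_forward(model$net, features$X1[idx, , drop = FALSE],
                     features$X2[idx, , drop = FALSE], training = FALSE)
    out[idx] <- fw$prob[, 2L]
  }
  out
}

#' Discretize a predicted probability into a binding level
#'
#' Pairs with probability strictly above 0.5 are called interacting;
#' among those, probability below 0.8 is `"low"`, between 0.8 and 0.95
#' (inclusive) `"medium"`, and strictly above 0.95 `"high"`. At or below
#' 0.5 the level is `"non-binding"`.
#'
#' @param probability Numeric vector in [0, 1].
#' @return Character vector of levels.
#' @export
assign_binding_level <- function(probability) {
  if (any(is.na(probability)) || any(probability < 0 | probability > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  ifelse(probability <= 0.5, "non-binding",
         ifelse(probability < 0.8, "low",
                ifelse(probability <= 0.95, "medium", "high")))
}

#' Predict interactions for a table of peptide-CDR3 pairs
#'
#' Encodes, scores and discretizes each pair, preserving input order.
#' Unseen peptides are routed through the minimum-edit-distance fallback
#' when building their AAPP map. Pairs that fail the sequence invariants
#' are not scored: their row carries `NA` results and the reason is
#' collected in the `errors` attribute of the result.
#'
#' @param model Trained `binding_model`.
#' @param pairs Pair data.frame with `peptide` and `cdr3`.
#' @param tables Encoder tables (an `aapp_table` under `$aapp` for the
#'   *-aapp schemes; `$phychem` for phychem-*).
#' @return Data.frame with columns `peptide`, `cdr3`, `probability`,
#'   `interaction`, `binding_level`; attribute `errors` holds a
#'   data.frame (`row`, `reason`) for unscored pairs.
#' @export
predict_pairs <- function(model, pairs, tables = list()) {
  stopifnot(inherits(model, "binding_model"))
  if (!model$trained) warning("scoring with an untrained model", call. = FALSE)
  n <- nrow(pairs)
  reason <- vapply(seq_len(n), function(i) {
    tryCatch({
      assert_sequence(pairs$peptide[i], "peptide")
      assert_sequence(pairs$cdr3[i], "cdr3")
      NA_character_
    }, error = function(e) conditionMessage(e))
  }, character(1))
  ok <- is.na(reason)
  prob <- rep(NA_real_, n)
  if (any(ok)) {
    feats <- encode_dataset(pairs[ok, , drop = FALSE], model$scheme, tables)
    prob[ok] <- predict_prob(model, feats)
  }
  out <- data.frame(
    peptide = pairs$peptide, cdr3 = pairs$cdr3, probability = prob,
    interaction = ifelse(is.na(prob), NA_integer_, as.integer(prob > 0.5)),
    binding_level = ifelse(is.na(prob), NA_character_,
                           assign_binding_level(replace(prob, is.na(prob), 0))),
    stringsAsFactors = FALSE)
  attr(out, "errors") <- data.frame(row = which(!ok), reason = reason[!ok],
                                    stringsAsFactors = FALSE)
  out
}

#' Rank candidate TCRs for a peptide
#'
#' Scores every candidate CDR3 against one peptide and returns the
#' prediction records sorted by probability (descending), ties broken by
#' CDR3 lexicographic order.
#'
#' @param model Trained `binding_model`.
#' @param peptide Query peptide.
#' @param candidate_cdr3s Non-empty character vector of CDR3s.
#' @param tables Encoder tables, as in [predict_pairs()].
#' @return Data.frame of prediction records, best first.
#' @export
rank_tcrs_for_peptide <- function(model, peptide, candidate_cdr3s, tables = list()) {
  if (!length(candidate_cdr3s)) stop("no candidate CDR3s supplied", call. = FALSE)
  pairs <- data.frame(peptide = peptide, cdr3 = as.character(candidate_cdr3s),
                      stringsAsFactors = FALSE)
  res <- predict_pairs(model, pairs, tables)
  res <- res[order(-res$probability, res$cdr3, na.last = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write prediction records to CSV
#'
#' Exactly five columns: peptide, cdr3, probability, interaction,
#' binding_level.
#'
#' @param predictions Output of [predict_pairs()].
#' @param path CSV path.
#' @export
write_predictions <- function(predictions, path) {
  cols <- c("peptide", "cdr3", "probability", "interaction", "binding_level")
  utils::write.csv(predictions[, cols], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Save a binding model to a directory
#'
#' Writes the learned parameters and batch-norm state (`weights.rds`)
#' plus a JSON sidecar recording the configuration, fusion scheme,
#' residue order, padding convention and thresholds, so predictions are
#' reproducible independent of package defaults.
#'
#' @param model A `binding_model`.
#' @param dir Target directory (created if needed).
#' @export
save_binding_model <- function(model, dir) {
  stopifnot(inherits(model, "binding_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(params = model$net$params, buffers = model$net$buffers,
               history = model$history, trained = model$trained),
          file.path(dir, "weights.rds"))
  sidecar <- list(
    package = "tcrbinder", format_version = 1L,
    scheme = model$scheme, residue_order = model$residue_order,
    padding = model$padding, thresholds = as.list(model$thresholds),
    config = unclass(model$config))
  jsonlite::write_json(sidecar, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a binding model saved by [save_binding_model()]
#'
#' @param dir Model directory.
#' @return A `binding_model` whose predictions are bit-identical to the
#'   saved model's.
#' @export
load_binding_model <- function(dir) {
  sidecar_path <- file.path(dir, "model.json")
  if (!file.exists(sidecar_path)) {
    stop("no model found at ", dir, call. = FALSE)
  }
  sidecar <- jsonlite::read_json(sidecar_path)
  cfgl <- sidecar$config
  config <- model_config(
    scheme = cfgl$scheme, epochs = cfgl$epochs, batch_size = cfgl$batch_size,
    learning_rate = cfgl$learning_rate, l2 = cfgl$l2, dropout = cfgl$dropout,
    module_dense = cfgl$module_dense, seed = cfgl$seed,
    n_phychem_scales = cfgl$input1[[2]])
  model <- build_binding_model(config)
  state <- readRDS(file.path(dir, "weights.rds"))
  model$net$params <- state$params
  model$net$buffers <- state$buffers
  model$history <- state$history
  model$trained <- state$trained
  model$residue_order <- unlist(sidecar$residue_order)
  model$padding <- sidecar$padding
  model
}
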