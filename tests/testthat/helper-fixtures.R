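# Shared helpers: small in-code fixtures and independent oracles.

pair_df <- function(peptide, cdr3, label = 1L, source = NA_character_,
                    confidence = NA_real_) {
  data.frame(peptide = peptide, cdr3 = cdr3, label = as.integer(label),
             source = source, confidence = confidence, stringsAsFactors = FALSE)
}

write_pairs_csv <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# A small motif dataset for fast end-to-end paths.
tiny_dataset <- function(n_pep = 6, tcrs = 8, strength = 0.9, neg_ratio = 1,
                         seed = 5) {
  generate_paired_dataset(n_pep, tcrs, motif_spec(strength = strength),
                          neg_ratio = neg_ratio, seed = seed)
}

# Exponential-time reference for the edit-distance recurrence (tiny
# strings only); deliberately independent of the DP implementation.
naive_lev <- function(a, b) {
  if (!nchar(a)) return(nchar(b))
  if (!nchar(b)) return(nchar(a))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(naive_lev(substr(a, 2, nchar(a)), b) + 1L,
      naive_lev(a, substr(b, 2, nchar(b))) + 1L,
      naive_lev(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))) + cost)
}

# All-pairs concordance AUC (the trapezoidal-ROC oracle).
auc_bruteforce <- function(labels, prob) {
  pos <- prob[labels == 1]
  neg <- prob[labels == 0]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

random_pep <- function(n, len = 9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Cheap anchor-match scorer standing in for the CNN when a test targets
# the evaluation protocol rather than the model: probability is the
# fraction of AAPP-preferred residues the CDR3 matches at the motif
# anchors.
cheap_trainer <- function(train_records, scheme, config, tables) {
  structure(list(aapp = tables$aapp), class = "cheap_model")
}

cheap_scorer <- function(model, records, tables) {
  anchors <- c(4L, 5L, 6L)
  vapply(seq_len(nrow(records)), function(i) {
    pep <- records$peptide[i]
    map <- lookup_aapp(pep, model$aapp)
    ch <- strsplit(records$cdr3[i], "")[[1]]
    hit <- vapply(anchors, function(a) {
      if (a > length(ch)) return(0)
      as.numeric(AA_ALPHABET[which.max(map[a - 1L, ])] == ch[a])
    }, numeric(1))
    0.05 + 0.9 * mean(hit)
  }, numeric(1))
}
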