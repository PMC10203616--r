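# tcrbinder

Predicting whether a TCRβ CDR3 sequence recognizes a given MHC class I
peptide, for immunoinformatics work on neoantigen screening: candidate
peptides that pass MHC-presentation filters still need a cognate T cell
receptor to elicit a response, and `tcrbinder` scores that peptide-TCR
side of the problem.

## The method

Every peptide-CDR3 pair is encoded twice and the two maps feed a
dual-input convolutional network fused at the dense layers:

* **Module 1 — single-residue map.** The peptide (8-11 aa) and CDR3
  (8-21 aa) are zero-padded into an 11×20 and a 21×20 block (rows =
  positions, columns = residues in fixed order `ACDEFGHIKLMNPQRSTVWY`)
  and stacked into a 32×20 = 640-entry one-hot map (or a 32×21
  standardized physicochemical map).
* **Module 2 — distribution map.** Either stacked amino-acid
  compositions (AAC, `AAC_i = count_i / N_s`), or the **amino acid
  position preference** (AAPP) matrix of the epitope: for peptide *p*
  with *N_t* cognate CDR3s in the positive training set,

  `AAPP_p(x, i) = count_{x,i} / N_t`, for CDR3 positions `x = 2..21`

  (position 1 is the conserved start cysteine) — a 20×20 = 400-entry
  map of which residues the epitope's repertoire prefers where.

Architecture: conv 16 (3×2) → BN → ReLU → conv 32 (6×4) → maxpool (2,
stride 1) → BN → ReLU → dense 128 for module 1; conv 16 (1×2) →
maxpool → BN → ReLU → dense 128 for module 2; concatenated → dense 256
→ dense 128 (L2 0.01) → dropout 0.3 → softmax(2). Trained with Adagrad
(lr 0.01) on MSE against one-hot labels, 60 epochs, batch size 20.
The whole network — convolutions, batch norm, backprop, Adagrad — is
implemented in this package (R orchestration, C++ kernels); no deep
learning framework is required.

A peptide never seen in training has no AAPP map: it borrows the map of
the nearest training peptide under Levenshtein (minimum edit) distance,
ties broken lexicographically. Predicted probabilities above 0.5 are
called interactions, discretized into binding levels: low (< 0.8),
medium (0.8-0.95), high (> 0.95).

Negative training pairs are sampled by randomly pairing positive-set
peptides with CDR3s from a background (healthy-donor style) repertoire.
A synthetic generator plants position-preference motifs so the whole
pipeline is testable without external data. Evaluation covers the
standard metric suite (accuracy, precision, recall, F1, MCC,
trapezoidal ROC AUC) and repeated label-stratified k-fold CV with
leakage-safe, per-fold AAPP construction.

## Worked example

```r
library(tcrbinder)

# a synthetic world: 12 epitopes x 20 cognate CDR3s, anchors 4-6,
# motif strength 0.9, 1:1 sampled negatives
ds <- generate_paired_dataset(n_peptides = 12, tcrs_per_peptide = 20,
                              motif = motif_spec(strength = 0.9), seed = 42)
set.seed(1)
test_idx <- unlist(lapply(split(seq_len(nrow(ds)), ds$label),
                          function(i) sample(i, length(i) %/% 5)))
train <- ds[-test_idx, ]; test <- ds[test_idx, ]

tables <- list(aapp = build_aapp_table(train[train$label == 1, ]))
cfg <- model_config(epochs = 10, seed = 7)       # quick demo; default is 60
model <- train_model(build_binding_model(cfg),
                     encode_dataset(train, "onehot-aapp", tables),
                     train$label, cfg)
model
#> <binding_model onehot-aapp: inputs 640 + 400, trained, 10 epoch(s) trained>

res <- predict_pairs(model, test[1:2, c("peptide", "cdr3")], tables)
nearest_training_peptide("CGYQKLHA", unique(train$peptide))
#> 'CGYQKLHA' -> 'CGYQKLCA' (edit distance 1)
```

`predict_pairs()` returns the five-column record table (peptide, cdr3,
probability, interaction, binding_level):

```
  peptide             cdr3 probability interaction binding_level
 KQTPGDDI     CYPFYHMFSQEG       0.501           1           low
 CGYQKLCA CMCIACTHCMWCTQQF       0.499           0   non-binding
```

This 480-pair demo is deliberately under-trained (near-chance held-out
AUC) — it illustrates the API, not the model. At the test suite's
desk scale — 40 epitopes × 30 CDR3s (2,400 pairs), motif strength 0.9,
10 epochs, fixed seeds — the held-out metrics printed by the same
pipeline are:

```
accuracy 0.8771  precision 0.9132  recall 0.8333  f1 0.8715  mcc 0.7571  auc 0.9538
counts @0.50: TP 200 FP 19 TN 221 FN 40
```

and the acceptance test asserts AUC ≥ 0.85 there, strictly above the
motif-free (strength 0) control (~0.5).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "tcrbinder", package = "tcrbinder"))')
Rscript $CLI simulate --out sim --n-peptides 12 --tcrs-per-peptide 20 --seed 11
Rscript $CLI train --pairs sim/pairs.csv --out model --epochs 10 --seed 5
Rscript $CLI predict-pairs --model model --pairs sim/pairs.csv --out pred.csv
Rscript $CLI predict-peptide --model model --peptides peps.txt \
        --candidates repertoire.txt --out ranked.csv
Rscript $CLI evaluate --pairs sim/pairs.csv --out cv.csv --k 5 --repeats 4
Rscript $CLI nearest --query NLVPMVATI --candidates peps.txt
```

Every run writes a `manifest.json` (flags, seed, residue order) next to
its outputs so it can be reproduced exactly.

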