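# Synthetic peptide-TCR data with planted positional structure.
#
# The generator emulates the world the positional-preference encoding
# assumes: every synthetic epitope owns a cognate CDR3 repertoire whose
# residues at a few anchor positions prefer a peptide-specific residue,
# on top of a motif-free background. A background repertoire (stand-in
# for healthy-donor sequences) supplies negative pairings. Datasets are
# regenerated bit-identically from (spec, seed) and are never stored.

#' Specification of a planted CDR3 motif
#'
#' @param anchors CDR3 anchor positions (within 2..21) at which cognate
#'   sequences prefer a peptide-specific residue.
#' @param strength Probability in [0, 1] that an anchor position emits
#'   the preferred residue rather than a background draw; 0 reduces to
#'   pure background.
#' @param background Length-20 residue distribution (in [AA_ALPHABET]
#'   order) used away from anchors; default uniform.
#' @param preference_weights Length-20 distribution from which each
#'   peptide's preferred anchor residues are drawn; default uniform.
#' @return A list of class `motif_spec`.
#' @export
motif_spec <- function(anchors = c(4L, 5L, 6L), strength = 0.9,
                       background = rep(1 / 20, 20),
                       preference_weights = rep(1 / 20, 20)) {
  stopifnot(all(anchors %in% AAPP_POSITIONS), strength >= 0, strength <= 1,
            length(background) == 20, length(preference_weights) == 20)
  background <- background / sum(background)
  preference_weights <- preference_weights / sum(preference_weights)
  structure(list(anchors = as.integer(anchors), strength = strength,
                 background = background,
                 preference_weights = preference_weights),
            class = "motif_spec")
}

random_seqs <- function(n, len_range, dist, first_c = FALSE) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  vapply(lens, function(L) {
    body <- sample(AA_ALPHABET, L - first_c, replace = TRUE, prob = dist)
    paste(c(if (first_c) "C", body), collapse = "")
  }, character(1))
}

#' Generate positive peptide-repertoire pairs with planted motifs
#'
#' Draws `n_peptides` distinct synthetic epitopes and, for each, a set
#' of distinct cognate CDR3s starting with the canonical cysteine.
#' Every peptide receives its own preferred residue at each anchor of
#' `motif`; cognate CDR3s emit that residue at the anchor with
#' probability `motif$strength` (positions beyond a CDR3's length are
#' simply absent). All records pass curation. Deterministic per seed.
#'
#' @param n_peptides Number of epitopes.
#' @param tcrs_per_peptide Cognate repertoire size per epitope.
#' @param motif A [motif_spec()].
#' @param peptide_len,cdr3_len Inclusive length ranges; must sit inside
#'   the curation bounds (CDR3 lengths include the leading cysteine).
#' @param seed Integer seed.
#' @return Pair data.frame (`label = 1`,
#'   `source = "synthetic-positive"`), with attribute `motifs`: a named
#'   list of per-peptide preferred residues at the anchors.
#' @export
generate_epitope_repertoire <- function(n_peptides, tcrs_per_peptide,
                                        motif = motif_spec(),
                                        peptide_len = c(8L, 11L),
                                        cdr3_len = c(12L, 16L),
                                        seed = 1L) {
  stopifnot(inherits(motif, "motif_spec"), n_peptides >= 1, tcrs_per_peptide >= 1)
  if (peptide_len[1] < PEPTIDE_LEN_RANGE[1] || peptide_len[2] > PEPTIDE_LEN_RANGE[2] ||
      peptide_len[1] > peptide_len[2] ||
      cdr3_len[1] < CDR3_LEN_RANGE[1] || cdr3_len[2] > CDR3_LEN_RANGE[2] ||
      cdr3_len[1] > cdr3_len[2]) {
    stop("length ranges must sit inside the curation bounds", call. = FALSE)
  }
  with_seed(seed, {
    peptides <- character(0)
    while (length(peptides) < n_peptides) {
      peptides <- unique(c(peptides,
                           random_seqs(n_peptides - length(peptides),
                                       peptide_len, motif$background)))
    }
    motifs <- lapply(peptides, function(p) {
      stats::setNames(sample(AA_ALPHABET, length(motif$anchors), replace = TRUE,
                             prob = motif$preference_weights),
                      paste0("pos", motif$anchors))
    })
    names(motifs) <- peptides
    recs <- lapply(peptides, function(p) {
      pref <- motifs[[p]]
      cdr3s <- character(0)
      while (length(cdr3s) < tcrs_per_peptide) {
        new <- vapply(seq_len(tcrs_per_peptide - length(cdr3s)), function(i) {
          s <- seq_chars(random_seqs(1L, cdr3_len, motif$background,
                                     first_c = TRUE))
          at <- motif$anchors[motif$anchors <= length(s)]
          use <- stats::runif(length(at)) < motif$strength
          s[at[use]] <- pref[paste0("pos", at[use])]
          paste(s, collapse = "")
        }, character(1))
        cdr3s <- unique(c(cdr3s, new))
      }
      data.frame(peptide = p, cdr3 = cdr3s, label = 1L,
                 source = "synthetic-positive", confidence = NA_real_,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    attr(out, "motifs") <- motifs
    out
  })
}

#' Generate a motif-free background CDR3 repertoire
#'
#' Stand-in for a healthy-donor repertoire used as the negative-pairing
#' pool: CDR3s start with cysteine and all remaining residues are drawn
#' from the background distribution. Deterministic per seed.
#'
#' @param n Number of sequences (>= 0).
#' @param cdr3_len Inclusive length range (within curation bounds).
#' @param background Length-20 residue distribution; default uniform.
#' @param seed Integer seed.
#' @return Character vector of distinct CDR3s.
#' @export
generate_background_repertoire <- function(n, cdr3_len = c(12L, 16L),
                                           background = rep(1 / 20, 20),
                                           seed = 1L) {
  stopifnot(n >= 0)
  if (n == 0) return(character(0))
  background <- background / sum(background)
  with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      out <- unique(c(out, random_seqs(n - length(out), cdr3_len, background,
                                       first_c = TRUE)))
    }
    out
  })
}

#' Perturb peptides into an unseen-epitope evaluation set
#'
#' Applies 1-2 random substitutions to each input peptide, producing
#' queries absent from the training set that exercise the
#' minimum-edit-distance fallback (an analogue of a peptide-unique
#' evaluation subset).
#'
#' @param peptides Character vector of training peptides.
#' @param n_edits Integer vector of allowed edit counts (sampled per
#'   peptide).
#' @param seed Integer seed.
#' @return Character vector of perturbed peptides, none equal to any
#'   input peptide.
#' @export
perturb_peptides <- function(peptides, n_edits = 1:2, seed = 1L) {
  with_seed(seed, {
    vapply(peptides, function(p) {
      repeat {
        s <- seq_chars(p)
        for (pos in sample(seq_along(s), sample(n_edits, 1L))) {
          s[pos] <- sample(setdiff(AA_ALPHABET, s[pos]), 1L)
        }
        cand <- paste(s, collapse = "")
        if (!cand %in% peptides) return(cand)
      }
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Generate a complete labelled dataset (positives + sampled negatives)
#'
#' Convenience wrapper: plants motifs with
#' [generate_epitope_repertoire()], draws a background repertoire of
#' `round(neg_ratio * n_pos)` + margin sequences, and samples negatives
#' at `neg_ratio` negatives per positive (1:1 default; 10 for an
#' imbalanced evaluation design).
#'
#' @inheritParams generate_epitope_repertoire
#' @param neg_ratio Negatives per positive.
#' @param background_size Size of the background pool; defaults to the
#'   number of negatives needed.
#' @return Pair data.frame of positives then negatives; attribute
#'   `motifs` as in [generate_epitope_repertoire()].
#' @export
generate_paired_dataset <- function(n_peptides, tcrs_per_peptide,
                                    motif = motif_spec(), neg_ratio = 1,
                                    peptide_len = c(8L, 11L),
                                    cdr3_len = c(12L, 16L),
                                    background_size = NULL, seed = 1L) {
  pos <- generate_epitope_repertoire(n_peptides, tcrs_per_peptide, motif,
                                     peptide_len, cdr3_len, seed = seed)
  n_neg <- as.integer(round(neg_ratio * nrow(pos)))
  if (is.null(background_size)) background_size <- max(n_neg, 1L)
  bg <- generate_background_repertoire(background_size, cdr3_len,
                                       motif$background, seed = seed + 1L)
  neg <- sample_negative_pairs(unique(pos$peptide), bg, n_neg, seed = seed + 2L,
                               positives = pos)
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  attr(out, "motifs") <- attr(pos, "motifs")
  out
}
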