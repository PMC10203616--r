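# Feature encoders. A peptide-CDR3 pair is encoded twice:
#   module 1 (single-residue group): one-hot or physicochemical map of the
#     concatenated, zero-padded pair (peptide rows 1-11, CDR3 rows 12-32);
#   module 2 (distribution group): amino-acid composition (AAC) or the
#     per-epitope Amino Acid Position Preference (AAPP) matrix computed
#     over the epitope's cognate CDR3 repertoire, CDR3 positions 2-21.
# All encoders are pure functions of their inputs.

feature_map <- function(values, kind) {
  structure(values, class = c("feature_map", class(values)), kind = kind)
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map %s: %d x %d>\n", attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

PEPTIDE_BLOCK_ROWS <- 11L  # max peptide length
CDR3_BLOCK_ROWS <- 21L     # max CDR3 length
PAIR_ROWS <- PEPTIDE_BLOCK_ROWS + CDR3_BLOCK_ROWS  # 32

onehot_block <- function(s, n_rows) {
  m <- matrix(0, n_rows, length(AA_ALPHABET),
              dimnames = list(NULL, AA_ALPHABET))
  ch <- seq_chars(s)
  m[cbind(seq_along(ch), aa_index(ch))] <- 1
  m
}

#' One-hot encode a peptide-CDR3 pair
#'
#' The peptide occupies rows 1-11 and the CDR3 rows 12-32 (sequences are
#' right-padded with all-zero rows to their block height), each row
#' holding the 0/1 indicator of the residue at that position over the 20
#' columns of [AA_ALPHABET]. The result is a 32 x 20 map with exactly
#' `nchar(peptide) + nchar(cdr3)` ones.
#'
#' @param peptide Peptide sequence (8-11 residues).
#' @param cdr3 CDR3 sequence (8-21 residues).
#' @return A 32 x 20 `feature_map` of kind `"onehot"`.
#' @export
encode_onehot_pair <- function(peptide, cdr3) {
  assert_sequence(peptide, "peptide")
  assert_sequence(cdr3, "cdr3")
  feature_map(rbind(onehot_block(peptide, PEPTIDE_BLOCK_ROWS),
                    onehot_block(cdr3, CDR3_BLOCK_ROWS)),
              "onehot")
}

#' Load and standardize a physicochemical property table
#'
#' Reads a CSV of per-residue values for named physicochemical scales
#' (rows = the 20 residues, first column `residue`, remaining columns
#' one scale each). Each scale is standardized to mean 0 and (population)
#' variance 1 across the 20 canonical residues; the standardization is a
#' property of the table, computed once, never refit per dataset.
#'
#' The packaged default carries 21 literature scales in the ProtScale
#' style (Kyte-Doolittle hydropathy, Hopp-Woods hydrophilicity,
#' Chou-Fasman propensities, bulkiness, polarity, molecular weight,
#' isoelectric point, ...). It is a documented stand-in scale set and can
#' be replaced by any CSV of the same shape.
#'
#' @param path CSV path; defaults to the packaged 21-scale table.
#' @return A list of class `phychem_table`: `values` (raw 20 x n matrix),
#'   `std` (standardized matrix), `center`, `scale` (per-scale stats).
#' @export
load_phychem_table <- function(path = system.file("extdata", "phychem_scales.csv",
                                                  package = "tcrbinder")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "residue") stop("first column must be 'residue'", call. = FALSE)
  res <- tab$residue
  if (!setequal(res, AA_ALPHABET) || anyDuplicated(res)) {
    stop("phychem table must contain exactly the 20 canonical residues", call. = FALSE)
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- res
  vals <- vals[AA_ALPHABET, , drop = FALSE]
  center <- colMeans(vals)
  scale <- sqrt(colMeans(sweep(vals, 2, center)^2))  # population sd
  if (any(scale == 0)) stop("constant physicochemical scale cannot be standardized",
                            call. = FALSE)
  std <- sweep(sweep(vals, 2, center), 2, scale, "/")
  structure(list(values = vals, std = std, center = center, scale = scale),
            class = "phychem_table")
}

#' Physicochemically encode a peptide-CDR3 pair
#'
#' Same 32-row layout as [encode_onehot_pair()], but each occupied row
#' holds the standardized values of the residue across all scales of
#' `table` (21 columns for the packaged default); padding rows are zero.
#'
#' @inheritParams encode_onehot_pair
#' @param table A `phychem_table` from [load_phychem_table()].
#' @return A 32 x n_scales `feature_map` of kind `"phychem"`.
#' @export
encode_phychem_pair <- function(peptide, cdr3, table = load_phychem_table()) {
  assert_sequence(peptide, "peptide")
  assert_sequence(cdr3, "cdr3")
  stopifnot(inherits(table, "phychem_table"))
  block <- function(s, n_rows) {
    m <- matrix(0, n_rows, ncol(table$std),
                dimnames = list(NULL, colnames(table$std)))
    ch <- seq_chars(s)
    m[seq_along(ch), ] <- table$std[ch, , drop = FALSE]
    m
  }
  feature_map(rbind(block(peptide, PEPTIDE_BLOCK_ROWS),
                    block(cdr3, CDR3_BLOCK_ROWS)),
              "phychem")
}

#' Amino-acid composition of a sequence
#'
#' Frequency of each of the 20 residues: count of residue i divided by
#' sequence length. Entries sum to 1 for any non-empty sequence.
#'
#' @param sequence Non-empty sequence over the 20-letter alphabet.
#' @return Named numeric vector of length 20 in [AA_ALPHABET] order.
#' @export
compute_aac <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.na(sequence) || !nzchar(sequence)) {
    stop("cannot compute composition of an empty sequence", call. = FALSE)
  }
  if (!is_valid_residues(sequence)) {
    stop("sequence contains characters outside the 20-letter alphabet", call. = FALSE)
  }
  ch <- seq_chars(sequence)
  counts <- tabulate(aa_index(ch), nbins = length(AA_ALPHABET))
  stats::setNames(counts / length(ch), AA_ALPHABET)
}

#' Build per-epitope amino-acid position preference (AAPP) matrices
#'
#' For every unique peptide p in a positive pair set with N_t cognate
#' CDR3s, the AAPP matrix holds, for CDR3 position x = 2..21 and residue
#' i, the fraction of cognate CDR3s whose residue at position x is i
#' (count_{x,i} / N_t). Position 1 is excluded: curated CDR3s share the
#' start cysteine, so it carries no preference information. The matrix
#' rows therefore sum, per position, to the fraction of cognate CDR3s
#' long enough to reach that position (exactly 1 at position 2).
#'
#' Counts and repertoire sizes are stored alongside the probabilities so
#' tables serialize exactly.
#'
#' @param positive_records Pair data.frame; all labels must be 1.
#' @return A list of class `aapp_table`: `maps` (named list of 20 x 20
#'   matrices, rows positions 2-21, columns [AA_ALPHABET]), `counts`
#'   (integer matrices of the same shape) and `tcr_counts` (named
#'   integer vector N_t).
#' @export
build_aapp_table <- function(positive_records) {
  if (nrow(positive_records) && any(positive_records$label != 1L)) {
    stop("AAPP tables are built from positive (label 1) records only", call. = FALSE)
  }
  peptides <- unique(positive_records$peptide)
  n_pos <- length(AAPP_POSITIONS)
  dn <- list(paste0("pos", AAPP_POSITIONS), AA_ALPHABET)
  maps <- counts <- stats::setNames(vector("list", length(peptides)), peptides)
  tcr_counts <- stats::setNames(integer(length(peptides)), peptides)
  for (p in peptides) {
    cdr3s <- positive_records$cdr3[positive_records$peptide == p]
    nt <- length(cdr3s)
    cnt <- matrix(0L, n_pos, length(AA_ALPHABET), dimnames = dn)
    for (s in cdr3s) {
      ch <- seq_chars(s)
      x <- AAPP_POSITIONS[AAPP_POSITIONS <= length(ch)]
      cnt[cbind(x - 1L, aa_index(ch[x]))] <- cnt[cbind(x - 1L, aa_index(ch[x]))] + 1L
    }
    counts[[p]] <- cnt
    maps[[p]] <- cnt / nt
    tcr_counts[[p]] <- nt
  }
  structure(list(maps = maps, counts = counts, tcr_counts = tcr_counts),
            class = "aapp_table")
}

#' @export
print.aapp_table <- function(x, ...) {
  cat(sprintf("<aapp_table: %d peptide(s), repertoire sizes %s>\n",
              length(x$maps),
              if (length(x$tcr_counts)) paste(range(x$tcr_counts), collapse = "-")
              else "-"))
  invisible(x)
}

#' Look up (or borrow) the AAPP map for a peptide
#'
#' Returns the peptide's own 20 x 20 AAPP map when the peptide was seen
#' in training. For an unseen peptide, the map of the training peptide
#' at minimum edit distance is returned instead
#' ([nearest_training_peptide()]; ties broken lexicographically).
#'
#' @param peptide Query peptide.
#' @param table An `aapp_table`.
#' @param training_peptides Candidate peptides for the fallback; defaults
#'   to all peptides in `table`.
#' @return A 20 x 20 `feature_map` of kind `"aapp"`, with attributes
#'   `source_peptide` and `distance` recording the fallback.
#' @export
lookup_aapp <- function(peptide, table,
                        training_peptides = names(table$maps)) {
  stopifnot(inherits(table, "aapp_table"))
  if (!length(table$maps)) stop("AAPP table is empty", call. = FALSE)
  if (peptide %in% names(table$maps)) {
    src <- peptide
    dist <- 0L
  } else {
    hit <- nearest_training_peptide(peptide, intersect(training_peptides,
                                                       names(table$maps)))
    src <- hit$match
    dist <- hit$distance
  }
  out <- feature_map(table$maps[[src]], "aapp")
  attr(out, "source_peptide") <- src
  attr(out, "distance") <- dist
  out
}

FUSION_SCHEMES <- c("onehot-aac", "onehot-aapp", "phychem-aac", "phychem-aapp")

#' Fuse a pair into its two model input maps
#'
#' Combines one encoder from the single-residue group (one-hot or
#' phychem) with one from the distribution group (AAC or AAPP) into the
#' two maps consumed by the dual-input model. For AAC, the peptide and
#' CDR3 composition vectors are stacked into a 2 x 20 matrix; the AAPP
#' map depends on the peptide only (it is a repertoire property of the
#' epitope, not of the CDR3 being scored).
#'
#' @inheritParams encode_onehot_pair
#' @param scheme One of `"onehot-aac"`, `"onehot-aapp"`,
#'   `"phychem-aac"`, `"phychem-aapp"`.
#' @param tables List with elements `aapp` (an `aapp_table`; required for
#'   the *-aapp schemes) and `phychem` (a `phychem_table`; required for
#'   the phychem-* schemes).
#' @return A list of class `fused_features`: `module1`, `module2`
#'   (feature maps), `scheme`.
#' @export
fuse_pair <- function(peptide, cdr3, scheme = "onehot-aapp", tables = list()) {
  if (!scheme %in% FUSION_SCHEMES) {
    stop("unknown fusion scheme '", scheme, "'; expected one of ",
         paste(FUSION_SCHEMES, collapse = ", "), call. = FALSE)
  }
  parts <- strsplit(scheme, "-", fixed = TRUE)[[1]]
  module1 <- switch(parts[1],
    onehot = encode_onehot_pair(peptide, cdr3),
    phychem = {
      if (is.null(tables$phychem)) stop("scheme ", scheme, " needs tables$phychem",
                                        call. = FALSE)
      encode_phychem_pair(peptide, cdr3, tables$phychem)
    })
  module2 <- switch(parts[2],
    aac = feature_map(rbind(peptide = compute_aac(peptide),
                            cdr3 = compute_aac(cdr3)), "aac"),
    aapp = {
      if (is.null(tables$aapp)) stop("scheme ", scheme, " needs tables$aapp",
                                     call. = FALSE)
      lookup_aapp(peptide, tables$aapp)
    })
  structure(list(module1 = module1, module2 = module2, scheme = scheme),
            class = "fused_features")
}

#' Serialize an AAPP table to CSV
#'
#' One long-format CSV holding the integer counts (exact round trip) and
#' repertoire sizes: columns `peptide`, `tcr_count`, `position`, then the
#' 20 residue count columns.
#'
#' @param table An `aapp_table`.
#' @param path Output CSV path.
#' @export
write_aapp_table <- function(table, path) {
  stopifnot(inherits(table, "aapp_table"))
  rows <- lapply(names(table$counts), function(p) {
    cnt <- table$counts[[p]]
    data.frame(peptide = p, tcr_count = table$tcr_counts[[p]],
               position = AAPP_POSITIONS, cnt,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an AAPP table written by [write_aapp_table()]
#'
#' @param path CSV path.
#' @return An `aapp_table`; probabilities are reconstructed from the
#'   stored integer counts, so the round trip is exact.
#' @export
read_aapp_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  peptides <- unique(tab$peptide)
  dn <- list(paste0("pos", AAPP_POSITIONS), AA_ALPHABET)
  maps <- counts <- stats::setNames(vector("list", length(peptides)), peptides)
  tcr_counts <- stats::setNames(integer(length(peptides)), peptides)
  for (p in peptides) {
    sub <- tab[tab$peptide == p, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    cnt <- as.matrix(sub[, AA_ALPHABET, drop = FALSE])
    storage.mode(cnt) <- "integer"
    dimnames(cnt) <- dn
    counts[[p]] <- cnt
    tcr_counts[[p]] <- as.integer(sub$tcr_count[1])
    maps[[p]] <- cnt / tcr_counts[[p]]
  }
  structure(list(maps = maps, counts = counts, tcr_counts = tcr_counts),
            class = "aapp_table")
}
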