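#' The 20 canonical amino-acid letters, alphabetical
#'
#' Fixed residue-to-column order used by every encoder in the package.
#' The order is recorded in saved model sidecars so that artifacts remain
#' portable if the default ever changes.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Curation bounds for MHC-I presented peptides and TCRbeta CDR3 loops.
PEPTIDE_LEN_RANGE <- c(8L, 11L)
CDR3_LEN_RANGE <- c(8L, 21L)

# CDR3 positions carried by the positional-preference encoding: 2..21
# (position 1 is the conserved start cysteine and carries no information).
AAPP_POSITIONS <- 2:21

aa_index <- function(chars) match(chars, AA_ALPHABET)

#' Split a sequence string into single residues
#' @noRd
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

is_valid_residues <- function(s) {
  !is.na(s) && nzchar(s) && !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), s)
}

#' Validate a peptide or CDR3 sequence
#'
#' @param s Character scalar.
#' @param role `"peptide"` or `"cdr3"`; selects the permitted length range
#'   (8-11 for peptides, 8-21 for CDR3s).
#' @return `TRUE` invisibly, or stops with an informative error.
#' @export
assert_sequence <- function(s, role = c("peptide", "cdr3")) {
  role <- match.arg(role)
  rng <- if (role == "peptide") PEPTIDE_LEN_RANGE else CDR3_LEN_RANGE
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop(sprintf("%s must be a single character string", role), call. = FALSE)
  }
  if (!is_valid_residues(s)) {
    stop(sprintf("%s '%s' contains characters outside the 20-letter alphabet", role, s),
         call. = FALSE)
  }
  n <- nchar(s)
  if (n < rng[1] || n > rng[2]) {
    stop(sprintf("%s '%s' has length %d, outside [%d, %d]", role, s, n, rng[1], rng[2]),
         call. = FALSE)
  }
  invisible(TRUE)
}
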