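# Reading, curating, splitting and negatively augmenting peptide-CDR3 pair
# tables. Pair sets are plain data.frames with columns
# peptide / cdr3 / label / source / confidence so they compose with the rest
# of the tidy ecosystem; no bespoke container is needed.

#' Run code with a temporary RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

empty_pair_frame <- function() {
  data.frame(peptide = character(), cdr3 = character(), label = integer(),
             source = character(), confidence = numeric(),
             stringsAsFactors = FALSE)
}

#' Read a peptide-CDR3 pair table from CSV/TSV
#'
#' Reads a delimited file of peptide-CDR3 observations under a declared
#' column mapping. No attempt is made to auto-detect database-specific
#' schemas; the caller says which column is which. Sequences are
#' uppercased and stripped of surrounding whitespace. Rows with a missing
#' peptide or CDR3 survive as records with `NA` in that field and are
#' rejected (reason `"missing-field"`) at curation rather than crashing
#' the read.
#'
#' @param path Path to a UTF-8 CSV or TSV file with a header row.
#' @param columns Named character vector mapping record fields to file
#'   columns. Names `peptide` and `cdr3` are required; `label`, `source`
#'   and `confidence` are optional.
#' @param sep Field separator; defaults to `","` unless the file ends in
#'   `.tsv`/`.txt`, then `"\t"`.
#' @return A data.frame with columns `peptide`, `cdr3`, `label`,
#'   `source`, `confidence` (one row per input row).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("peptide,cdr3,label",
#'              "NLVPMVATV,CASSQWSNEKLFF,1"), f)
#' parse_pair_table(f)
#' @export
parse_pair_table <- function(path,
                             columns = c(peptide = "peptide", cdr3 = "cdr3",
                                         label = "label"),
                             sep = NULL) {
  if (!file.exists(path)) stop("cannot read pair table: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  req <- c("peptide", "cdr3")
  if (!all(req %in% names(columns))) {
    stop("column mapping must name 'peptide' and 'cdr3' columns", call. = FALSE)
  }
  missing_cols <- setdiff(unname(columns), names(tab))
  if (length(missing_cols)) {
    stop("mapped column(s) absent from file: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(tab)
  if (n == 0L) return(empty_pair_frame())

  grab <- function(field, default) {
    if (field %in% names(columns)) tab[[columns[[field]]]] else rep(default, n)
  }
  clean_seq <- function(x) {
    x <- toupper(trimws(x))
    x[!nzchar(x)] <- NA_character_
    x
  }
  out <- data.frame(
    peptide = clean_seq(grab("peptide", NA_character_)),
    cdr3 = clean_seq(grab("cdr3", NA_character_)),
    label = suppressWarnings(as.integer(grab("label", "1"))),
    source = as.character(grab("source", NA_character_)),
    confidence = suppressWarnings(as.numeric(grab("confidence", NA_character_))),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Curation rule set for pair tables
#'
#' @param peptide_len,cdr3_len Integer length-2 inclusive bounds.
#' @param confidence_min If non-`NULL`, records whose `confidence` is not
#'   strictly greater than this value are rejected (VDJdb-style scoring:
#'   the default keeps score > 0). Records with `NA` confidence are
#'   never rejected by this rule (other sources carry no score).
#' @param dedup Collapse duplicated (peptide, cdr3) pairs, keeping the
#'   first occurrence in file order.
#' @param warn_start_c Emit one warning listing CDR3s that do not begin
#'   with the canonical cysteine; never a rejection.
#' @return A list of class `curation_rules`.
#' @export
curation_rules <- function(peptide_len = PEPTIDE_LEN_RANGE,
                           cdr3_len = CDR3_LEN_RANGE,
                           confidence_min = NULL,
                           dedup = TRUE,
                           warn_start_c = TRUE) {
  structure(list(peptide_len = as.integer(peptide_len),
                 cdr3_len = as.integer(cdr3_len),
                 confidence_min = confidence_min,
                 dedup = isTRUE(dedup),
                 warn_start_c = isTRUE(warn_start_c)),
            class = "curation_rules")
}

#' Curate a parsed pair table
#'
#' Applies the standard curation pipeline: drop records with missing
#' fields, non-canonical residues, out-of-range lengths (peptides 8-11,
#' CDR3s 8-21), low VDJdb-style confidence, and duplicated
#' (peptide, cdr3) pairs. Every input row is accounted for: it is either
#' kept or appears in the report with a single reason code. Curation is
#' idempotent.
#'
#' @param records A data.frame as returned by [parse_pair_table()].
#' @param rules A [curation_rules()] object.
#' @return A list with elements `records` (the curated data.frame) and
#'   `report` (class `curation_report`: `kept` count and a `rejected`
#'   data.frame with columns `row`, `peptide`, `cdr3`, `reason`).
#' @export
curate_pairs <- function(records, rules = curation_rules()) {
  stopifnot(inherits(rules, "curation_rules"))
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  bad_alpha <- function(x) {
    !is.na(x) & grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), x)
  }
  set_reason <- function(idx, code) {
    idx <- idx & is.na(reason)
    reason[idx] <<- code
  }
  set_reason(is.na(records$peptide) | is.na(records$cdr3), "missing-field")
  set_reason(bad_alpha(records$peptide) | bad_alpha(records$cdr3), "alphabet")
  plen <- nchar(records$peptide)
  clen <- nchar(records$cdr3)
  set_reason(!is.na(plen) & (plen < rules$peptide_len[1] | plen > rules$peptide_len[2]),
             "peptide-length")
  set_reason(!is.na(clen) & (clen < rules$cdr3_len[1] | clen > rules$cdr3_len[2]),
             "cdr3-length")
  if (!is.null(rules$confidence_min)) {
    set_reason(!is.na(records$confidence) & records$confidence <= rules$confidence_min,
               "low-confidence")
  }
  if (rules$dedup) {
    key <- paste(records$peptide, records$cdr3, sep = "\r")
    ok <- is.na(reason)
    dup <- ok & duplicated(replace(key, !ok, paste0("\001", seq_len(n))[!ok]))
    set_reason(dup, "duplicate")
  }
  keep <- is.na(reason)
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  if (rules$warn_start_c && nrow(kept)) {
    non_c <- !startsWith(kept$cdr3, "C")
    if (any(non_c)) {
      warning(sum(non_c), " curated CDR3(s) do not start with the canonical cysteine",
              call. = FALSE)
    }
  }
  report <- structure(
    list(kept = sum(keep),
         rejected = data.frame(row = which(!keep),
                               peptide = records$peptide[!keep],
                               cdr3 = records$cdr3[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE)),
    class = "curation_report")
  list(records = kept, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report: kept", x$kept, "of", x$kept + nrow(x$rejected), "records\n")
  if (nrow(x$rejected)) {
    print(table(x$rejected$reason))
  }
  invisible(x)
}

#' Write a curation report to CSV
#'
#' @param report A `curation_report`.
#' @param path Output CSV path (columns row, peptide, cdr3, reason).
#' @export
write_curation_report <- function(report, path) {
  stopifnot(inherits(report, "curation_report"))
  utils::write.csv(report$rejected, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sample negative peptide-CDR3 pairs from a background repertoire
#'
#' Builds label-0 records by uniformly pairing peptides seen in the
#' positive set with CDR3s from a background (healthy-donor style)
#' repertoire. Sampled pairs are distinct, and any pair identical to a
#' known positive is resampled. Deterministic for a fixed seed.
#'
#' @param positive_peptides Character vector of peptides from the
#'   positive set (duplicates allowed; the distinct set is used).
#' @param repertoire Character vector of background CDR3 sequences.
#' @param n Number of negatives to draw.
#' @param seed Integer RNG seed.
#' @param positives Optional data.frame with `peptide` and `cdr3`
#'   columns; sampled negatives never collide with these pairs.
#' @return A pair data.frame of `n` rows, all `label = 0`,
#'   `source = "sampled-negative"`.
#' @export
sample_negative_pairs <- function(positive_peptides, repertoire, n, seed,
                                  positives = NULL) {
  peps <- unique(positive_peptides)
  reps <- unique(repertoire)
  if (!length(peps) || !length(reps)) {
    stop("both the peptide pool and the repertoire must be non-empty", call. = FALSE)
  }
  n <- as.integer(n)
  stopifnot(n >= 0L)
  forbidden <- character()
  if (!is.null(positives)) {
    forbidden <- paste(positives$peptide, positives$cdr3, sep = "\r")
  }
  grid_size <- length(peps) * length(reps)
  n_forbidden_in_grid <- if (!is.null(positives)) {
    u <- unique(positives[, c("peptide", "cdr3")])
    sum(u$peptide %in% peps & u$cdr3 %in% reps)
  } else 0L
  if (n > grid_size - n_forbidden_in_grid) {
    stop("requested ", n, " negatives but only ", grid_size - n_forbidden_in_grid,
         " distinct non-positive pairs exist", call. = FALSE)
  }
  if (n == 0L) return(empty_pair_frame())
  with_seed(seed, {
    chosen <- character(0)
    pep_out <- character(0)
    cdr_out <- character(0)
    while (length(chosen) < n) {
      m <- n - length(chosen)
      p <- sample(peps, m, replace = TRUE)
      r <- sample(reps, m, replace = TRUE)
      key <- paste(p, r, sep = "\r")
      ok <- !(key %in% forbidden) & !(key %in% chosen) & !duplicated(key)
      chosen <- c(chosen, key[ok])
      pep_out <- c(pep_out, p[ok])
      cdr_out <- c(cdr_out, r[ok])
    }
    data.frame(peptide = pep_out, cdr3 = cdr_out, label = 0L,
               source = "sampled-negative", confidence = NA_real_,
               stringsAsFactors = FALSE)
  })
}

#' Split an evaluation set by peptide overlap with training
#'
#' Partitions evaluation records into a peptide-shared subset (records
#' whose peptide occurs in the training peptide set) and a
#' peptide-unique subset (all remaining records). The two subsets are a
#' partition: no overlap, no loss.
#'
#' @param eval_records Pair data.frame.
#' @param training_peptides Character vector of peptides used in training.
#' @return List with data.frames `shared` and `unique`.
#' @export
split_shared_unique <- function(eval_records, training_peptides) {
  in_train <- eval_records$peptide %in% training_peptides
  list(shared = eval_records[in_train, , drop = FALSE],
       unique = eval_records[!in_train, , drop = FALSE])
}

#' Read a CDR3 repertoire file
#'
#' Accepts plain text (one CDR3 per line) or a single-column CSV with a
#' header. A first line containing characters outside the amino-acid
#' alphabet is treated as a header and dropped.
#'
#' @param path File path.
#' @return Character vector of uppercased CDR3 sequences.
#' @export
read_repertoire <- function(path) {
  if (!file.exists(path)) stop("cannot read repertoire: ", path, call. = FALSE)
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- toupper(trimws(x))
  x <- x[nzchar(x)]
  if (length(x) && !is_valid_residues(x[1])) x <- x[-1]
  x
}

#' Write a pair table to CSV
#'
#' @param records Pair data.frame.
#' @param path Output path.
#' @export
write_pair_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
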