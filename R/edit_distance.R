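# Minimum edit distance (Levenshtein) and nearest-training-peptide
# resolution. The positional-preference encoding is defined only for
# peptides seen in training; unseen query peptides borrow the map of the
# closest training peptide under unit-cost edit distance.

#' Levenshtein edit distance between two strings
#'
#' Unit-cost single-character insertions, deletions and substitutions,
#' computed by the standard two-row dynamic programme. Empty strings are
#' allowed.
#'
#' @param a,b Character scalars.
#' @return Non-negative integer distance.
#' @examples
#' edit_distance("kitten", "sitting")   # 3
#' edit_distance("NLVPMVATV", "NLVPMVATI")  # 1
#' @export
edit_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  x <- seq_chars(a)
  y <- seq_chars(b)
  na <- length(x)
  nb <- length(y)
  if (na == 0L) return(nb)
  if (nb == 0L) return(na)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    cur[1L] <- i
    sub_cost <- prev[1:nb] + (x[i] != y)     # substitution (0 if match)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- min(cur[j] + 1L, prev[j + 1L] + 1L, sub_cost[j])
    }
    prev <- cur
  }
  as.integer(prev[nb + 1L])
}

#' Distances from one query to many candidates
#' @noRd
edit_distances <- function(query, candidates) {
  vapply(candidates, function(b) edit_distance(query, b), integer(1),
         USE.NAMES = FALSE)
}

#' Nearest training peptide under minimum edit distance
#'
#' Finds the candidate minimizing the Levenshtein distance to the query.
#' Ties are broken by taking the lexicographically smallest candidate,
#' so the result does not depend on candidate order.
#'
#' @param query Character scalar.
#' @param candidates Non-empty character vector.
#' @return A list of class `edit_distance_result` with fields `query`,
#'   `match` and `distance` (`distance == 0` iff the query itself is a
#'   candidate).
#' @export
nearest_training_peptide <- function(query, candidates) {
  if (!length(candidates)) stop("candidate set is empty", call. = FALSE)
  candidates <- unique(as.character(candidates))
  d <- edit_distances(query, candidates)
  dmin <- min(d)
  best <- sort(candidates[d == dmin])[1L]
  structure(list(query = query, match = best, distance = as.integer(dmin)),
            class = "edit_distance_result")
}

#' @export
print.edit_distance_result <- function(x, ...) {
  cat(sprintf("'%s' -> '%s' (edit distance %d)\n", x$query, x$match, x$distance))
  invisible(x)
}
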