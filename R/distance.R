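#' Levenshtein distance between barcode sequences
#'
#' The minimal number of substitutions, insertions and deletions turning one
#' sequence into the other, at unit cost for each operation (no
#' transpositions). This is the sequence-similarity criterion of the clean-up
#' method: candidate daughters must lie within `max_dist` edits of their
#' mother.
#'
#' `a` and `b` are recycled against each other elementwise;
#' `levenshtein_to_many()` is the one-vs-many form used by the clean-up loop.
#'
#' @param a,b Character vectors of sequences (non-empty strings).
#' @param seq A single sequence.
#' @param others A character vector of sequences.
#' @return Integer vector of distances.
#' @examples
#' levenshtein("AAAA", "AATA")
#' levenshtein("ACGT", "TACG")
#' @export
levenshtein <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (any(!nzchar(a)) || any(!nzchar(b)) || anyNA(a) || anyNA(b)) {
    abort("Sequences must be non-empty strings.")
  }
  n <- max(length(a), length(b))
  if (n %% length(a) != 0 || n %% length(b) != 0) {
    abort("`a` and `b` lengths must recycle.")
  }
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- as.integer(adist(a[i], b[i])[1, 1])
  out
}

#' @rdname levenshtein
#' @export
levenshtein_to_many <- function(seq, others) {
  if (length(seq) != 1 || !nzchar(seq)) abort("`seq` must be one non-empty string.")
  if (length(others) == 0) return(integer(0))
  if (any(!nzchar(others))) abort("Sequences must be non-empty strings.")
  as.integer(drop(adist(seq, others)))
}
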