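#' Pairwise protein sequence identity
#'
#' The comparison measure of the clustering cascade: the two sequences are
#' globally aligned (BLOSUM62 substitution scores, affine gaps with open
#' penalty 10 and extension penalty 1) and identity is the number of
#' identically aligned residues divided by the length of the shorter
#' sequence. This denominator means a short protein fully contained in a
#' longer one scores 1.0, matching the behaviour of the greedy clustering
#' tools the measure emulates. The function is symmetric (arguments are
#' canonically ordered before alignment) and returns 1.0 for identical
#' sequences.
#'
#' @param a,b non-empty amino-acid sequences (single strings)
#' @return identity fraction in \[0, 1\]
#' @export
sequence_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop_pg("sequence_identity: empty sequence")
  if (a == b) return(1.0)
  p <- sort(c(a, b))
  identity_to_many(p[2], p[1])
}

# Identity of one query against many subjects in a single vectorized
# alignment call; the workhorse of greedy clustering. Exact matches shortcut
# to 1.0 without alignment.
identity_to_many <- function(query, subjects) {
  if (!length(subjects)) return(numeric(0))
  out <- numeric(length(subjects))
  eq <- subjects == query
  out[eq] <- 1.0
  if (any(!eq)) {
    al <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(subjects[!eq]),
      subject = query,
      substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 1,
      type = "global")
    out[!eq] <- Biostrings::pid(al, type = "PID3") / 100
  }
  out
}
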