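#' Homopolymer-compress a DNA sequence
#'
#' Collapses every maximal run of identical bases to a single character and
#' records the original run lengths, one per compressed position. Most HiFi
#' sequencing errors are homopolymer run-length errors, so downstream k-mer
#' selection and graph construction operate entirely in this compressed
#' ("HPC") space; run lengths are carried along and restored at output time
#' by [consensus_run()].
#'
#' @param sequence Character scalar over A/C/G/T, non-empty.
#' @param origin Optional read identifier recorded on the result.
#' @return An object of class `hpc_seq`: a list with `chars` (compressed
#'   sequence, no two adjacent characters equal), `run_lengths` (integer
#'   vector, one value >= 1 per compressed position, in bases) and `origin`.
#' @examples
#' h <- hpc_compress("AAACCGTTT")
#' h$chars        # "ACGT"
#' h$run_lengths  # 3 2 1 3
#' hpc_expand(h$chars, h$run_lengths)
#' @export
hpc_compress <- function(sequence, origin = NULL) {
  res <- cpp_hpc_compress(sequence)
  structure(list(chars = res$chars, run_lengths = res$run_lengths,
                 origin = origin),
            class = "hpc_seq")
}

#' Expand a homopolymer-compressed sequence back to base space
#'
#' Position `i` contributes `chars[i]` repeated `run_lengths[i]` times.
#' `hpc_expand(h$chars, h$run_lengths)` is an exact inverse of
#' [hpc_compress()].
#'
#' @param chars HPC-space sequence (character scalar).
#' @param run_lengths Integer vector of positive run lengths, one per
#'   character of `chars`.
#' @return Character scalar in base space.
#' @export
hpc_expand <- function(chars, run_lengths) {
  cpp_hpc_expand(chars, as.integer(run_lengths))
}

#' Run-length consensus of a tally of observations
#'
#' Returns the modal observed run length; ties are broken by taking the
#' smallest length among the tied modes, which makes the consensus
#' deterministic. With one length holding a strict majority of observations
#' that length is always returned.
#'
#' @param lengths Integer vector of distinct observed run lengths (bases).
#' @param counts Integer vector of observation counts, parallel to `lengths`,
#'   all >= 0 with a positive total.
#' @return A single positive integer, the consensus run length.
#' @examples
#' consensus_run(c(3, 2), c(5, 1))  # 3
#' consensus_run(c(2, 4), c(3, 3))  # 2 (tie -> smallest)
#' @export
consensus_run <- function(lengths, counts) {
  lengths <- as.integer(lengths)
  counts <- as.integer(counts)
  if (length(lengths) != length(counts) || length(lengths) == 0L)
    stop("consensus_run: lengths and counts must be non-empty and parallel")
  keep <- counts > 0L
  lengths <- lengths[keep]
  counts <- counts[keep]
  if (length(lengths) == 0L) stop("consensus_run: empty tally")
  o <- order(-counts, lengths)
  lengths[o[1L]]
}

# Vectorised consensus over a (group, runlen, n) tally table; returns one row
# per group with the modal run length, ties to the smallest length.
consensus_table <- function(tally, group_col = "upos") {
  stopifnot(all(c(group_col, "runlen", "n") %in% names(tally)))
  tl <- data.table::copy(tally)
  data.table::setorderv(tl, c(group_col, "n", "runlen"), order = c(1L, -1L, 1L))
  tl[!duplicated(tl[[group_col]])]
}
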