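#' Select minimizer k-mers of an HPC sequence
#'
#' A k-mer start position is selected iff its winnow hash ([winnow_hashes()])
#' is the minimum within at least one window of `w` consecutive start
#' positions; within a window, ties on the hash value go to the leftmost
#' position. Every window therefore contains at least one selected position
#' (the window guarantee), so consecutive selected k-mers are at most `w`
#' apart and, because `w <= k - 1` is enforced, always overlap by at least
#' one HPC base. `w = 1` selects every position (the dense de Bruijn graph
#' case); larger `w` gives sparser graphs with expected selection density
#' `2 / (w + 1)` on random sequence.
#'
#' A sequence with fewer than `w` k-mer positions is treated as a single
#' window (so a sequence of exactly `k` bases selects position 0). No extra
#' terminal positions are forced beyond the window guarantee, so up to
#' `w - 1` HPC bases at each read end may go unrepresented.
#'
#' @param hpc An `hpc_seq` from [hpc_compress()], or a plain character scalar
#'   already in HPC space.
#' @param k K-mer size in HPC bases, >= 2.
#' @param w Window size, `1 <= w <= k - 1`.
#' @return An object of class `minimizer_chain`: list with `positions`
#'   (0-based HPC start positions, strictly increasing), `hash` (128-bit
#'   identity hash per position, hex), `forward` (whether the observed
#'   orientation is the canonical one), `kmer` (canonical k-mer strings) and
#'   `origin`. Empty chain if the sequence is shorter than `k`.
#' @export
select_minimizers <- function(hpc, k, w) {
  k <- as.integer(k)
  w <- as.integer(w)
  if (k < 2L) stop("k must be >= 2")
  if (w < 1L || w > k - 1L) stop("w must satisfy 1 <= w <= k - 1")
  chars <- if (inherits(hpc, "hpc_seq")) hpc$chars else hpc
  origin <- if (inherits(hpc, "hpc_seq")) hpc$origin else NULL
  if (nchar(chars) < k) {
    return(structure(list(positions = integer(0), hash = character(0),
                          forward = logical(0), kmer = character(0),
                          origin = origin),
                     class = "minimizer_chain"))
  }
  ch <- cpp_chain(chars, k, w)
  structure(list(positions = ch$positions, hash = ch$hash,
                 forward = ch$forward, kmer = ch$kmer, origin = origin),
            class = "minimizer_chain")
}

#' Expected minimizer density on random sequence
#'
#' Closed-form expectation of the fraction of k-mer positions selected by
#' random-order winnowing with window size `w`: `2 / (w + 1)`. Diagnostic
#' companion to [select_minimizers()]; the empirical density on random
#' sequence matches this within sampling error.
#'
#' @param w Window size, >= 1.
#' @return Expected selected fraction in (0, 1].
#' @export
expected_density <- function(w) {
  stopifnot(w >= 1)
  2 / (w + 1)
}
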