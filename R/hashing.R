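#' Reverse complement of a DNA string
#'
#' @param sequence Character scalar over A/C/G/T.
#' @return The reverse complement, same length.
#' @export
revcomp <- function(sequence) cpp_revcomp(sequence)

#' Orientation-canonical form of a k-mer
#'
#' Returns whichever of the k-mer and its reverse complement is
#' lexicographically smaller, together with a flag saying whether the forward
#' orientation won. Palindromic k-mers are reported as forward. The canonical
#' form is what the 128-bit identity hash is computed on, so a k-mer and its
#' reverse complement always name the same graph node.
#'
#' @param kmer Character scalar over A/C/G/T.
#' @return List with `kmer` (canonical string) and `forward` (logical).
#' @export
canonical_kmer <- function(kmer) {
  rc <- cpp_revcomp(kmer)
  if (kmer <= rc) list(kmer = kmer, forward = TRUE)
  else list(kmer = rc, forward = FALSE)
}

#' Strand-symmetric rolling winnow hashes of a sequence
#'
#' Computes, for every k-mer start position of `seq`, the 64-bit value used
#' to order k-mers inside winnowing windows. The value is the minimum of an
#' ntHash-style forward rolling hash and the matching reverse-complement
#' rolling hash, so a k-mer and its reverse complement always receive the
#' same value and scanning the reverse-complemented sequence yields the
#' mirrored value sequence. Constants are fixed, so values are stable across
#' runs and platforms.
#'
#' @param seq Character scalar (HPC space, A/C/G/T).
#' @param k K-mer size, >= 2.
#' @return Character vector of length `nchar(seq) - k + 1` (empty if the
#'   sequence is shorter than `k`), each value a 16-digit zero-padded lower
#'   case hex string; fixed-width hex compares in value order.
#' @export
winnow_hashes <- function(seq, k) {
  cpp_rolling_hashes(seq, as.integer(k))
}

#' 128-bit identity hash of a k-mer
#'
#' Hashes the canonical form of the k-mer into a 128-bit integer (reported as
#' a 32-digit hex string). These hashes name the graph nodes: the k-mer
#' string itself is never used as a key, which is what lets `k` grow to
#' thousands of bases at constant per-node cost. Collisions at 128 bits are
#' treated as impossible and are neither detected nor resolved. No
#' per-process salt is used, so hashes are stable across runs.
#'
#' @param kmer Character scalar over A/C/G/T.
#' @return List with `hash` (32-hex-digit string) and `forward` (logical flag
#'   from [canonical_kmer()]).
#' @examples
#' identical(kmer_hash("ACG")$hash, kmer_hash("CGT")$hash)  # TRUE
#' @export
kmer_hash <- function(kmer) {
  can <- canonical_kmer(kmer)
  list(hash = cpp_fnv128_hex(can$kmer), forward = can$forward)
}
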