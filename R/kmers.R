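#' Canonical form of a k-mer
#'
#' A database stores each k-mer in its canonical form: the
#' lexicographically smaller of the k-mer and its reverse complement
#' (alphabet order A < C < G < T). Canonical storage makes the database
#' strand-agnostic, so query reads never need to be reverse-complemented
#' before matching.
#'
#' @param x Character vector of k-mers over the A/C/G/T alphabet
#'   (lowercase accepted and uppercased).
#' @return Character vector of the same length with each element replaced
#'   by its canonical form.
#' @examples
#' canonical_kmer(c("ACGT", "TTTC", "GAAA"))
#' @export
canonical_kmer <- function(x) {
  tryCatch(cpp_canonical(as.character(x)),
           error = function(e) stop_invalid_kmer(conditionMessage(e)))
}

#' Extract canonical k-mers from a sequence
#'
#' Slides a window of width `k` along the sequence and emits the canonical
#' k-mer of every window consisting solely of A/C/G/T. Windows containing
#' any other symbol ('N' or an IUPAC ambiguity code) are dropped, which is
#' also what makes the artificial 'N' separator of concatenated read pairs
#' opaque to matching: no k-mer ever spans the two mates.
#'
#' @param x A single sequence, or a character vector of sequences.
#' @param k Window width in nucleotides (k >= 1).
#' @return For a single sequence, a character vector of canonical k-mers in
#'   window order (possibly empty); for several sequences, a list of such
#'   vectors.
#' @examples
#' extract_kmers("ACGTNGAAA", 4)
#' @export
extract_kmers <- function(x, k) {
  k <- check_k(k)
  x <- as.character(x)
  if (length(x) == 1L) return(cpp_extract_kmers(x, k))
  lapply(x, cpp_extract_kmers, k = k)
}

#' Reverse complement of nucleotide sequences
#'
#' Watson-Crick complement, reversed. IUPAC ambiguity codes are
#' complemented symbol-wise ('N' maps to 'N'); any other symbol raises an
#' invalid-sequence error.
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements (uppercase).
#' @examples
#' reverse_complement("TTTC")
#' @export
reverse_complement <- function(x) {
  tryCatch(cpp_revcomp(as.character(x)),
           error = function(e) stop_invalid_sequence(conditionMessage(e)))
}

check_k <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != as.integer(k))
    stop_config("k must be a single integer >= 1")
  as.integer(k)
}
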