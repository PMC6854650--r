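# Brute-force oracles, written in plain R and independent of the
# package's C++ core: used to cross-check extraction, canonicalization,
# set algebra and coverage scoring on small random instances.

oracle_complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  paste(rev(unname(oracle_complement[chars])), collapse = "")
}

# locale-proof lexicographic comparison via digit mapping (A<C<G<T)
oracle_lex_key <- function(s) chartr("ACGT", "0123", s)

oracle_canonical <- function(s) {
  s <- toupper(s)
  rc <- oracle_revcomp(s)
  if (oracle_lex_key(rc) < oracle_lex_key(s)) rc else s
}

# canonical k-mers of all pure-ACGT windows, in window order
oracle_extract <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  out <- character(0)
  for (s in 1:(n - k + 1)) {
    w <- substr(seq, s, s + k - 1)
    if (grepl("^[ACGT]+$", w)) out <- c(out, oracle_canonical(w))
  }
  out
}

# multiset of canonical k-mer counts over a set of reads
oracle_count <- function(reads, k) {
  tab <- table(unlist(lapply(reads, oracle_extract, k = k)))
  setNames(as.integer(tab), names(tab))
}

# position-coverage match-rate score against a plain character set
oracle_coverage <- function(read, members, k, denominator = "acgt") {
  read <- toupper(read)
  n <- nchar(read)
  chars <- strsplit(read, "", fixed = TRUE)[[1]]
  acgt <- chars %in% c("A", "C", "G", "T")
  cov <- rep(FALSE, n)
  if (n >= k) {
    for (s in 1:(n - k + 1)) {
      w <- substr(read, s, s + k - 1)
      if (grepl("^[ACGT]+$", w) && oracle_canonical(w) %in% members)
        cov[s:(s + k - 1)] <- TRUE
    }
  }
  L <- if (denominator == "full") n else sum(acgt)
  if (L == 0) 0 else 100 * sum(cov) / L
}

random_dna_str <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a kmer_set built from an explicit member list (tests reach for the
# internal constructor so db content is under the oracle's control)
make_kmer_set <- function(members, k, label = "db") {
  kmerclass:::new_kmer_set(sort(unique(members)), k, label)
}

tiny_params <- function(...) {
  classifier_params(k = 4, ci = 1, ...)
}
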