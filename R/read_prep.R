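# Query-sample preparation: FASTQ/FASTA input, paired-end concatenation
# with the 'N' marker, and host-read removal.

#' Construct a query sample
#'
#' A query sample is an ordered set of q reads (for paired-end data, the
#' pair-concatenated sequences), the unit that gets scored against every
#' class database.
#'
#' @param reads Character vector of nucleotide sequences.
#' @param id Sample identifier.
#' @return A `query_sample` with fields `id`, `reads`, `q`.
#' @export
query_sample <- function(reads, id = "") {
  reads <- as.character(reads)
  structure(list(id = id, reads = reads, q = length(reads)),
            class = "query_sample")
}

#' @export
print.query_sample <- function(x, ...) {
  cat(sprintf("query_sample '%s': %d reads\n", x$id, x$q))
  invisible(x)
}

#' Concatenate a read pair into a single query sequence
#'
#' Scoring a pair as one unit requires one sequence per pair: the forward
#' read is kept as-is and the reverse complement of the mate is appended,
#' separated by a single 'N'. The separator can never occur inside a
#' database k-mer (databases hold pure A/C/G/T k-mers), so no k-mer of the
#' concatenated sequence spans the junction and the mates are scored
#' jointly without artefactual junction k-mers.
#'
#' @param fwd Character vector of forward (R1) reads.
#' @param rev Character vector of reverse (R2) reads, or `NULL` for
#'   single-end data (the forward reads are returned unchanged).
#' @return Character vector of concatenated sequences.
#' @examples
#' concat_pair("ACGT", "TTTC")  # "ACGTNGAAA"
#' @export
concat_pair <- function(fwd, rev = NULL) {
  fwd <- as.character(fwd)
  if (is.null(rev)) return(fwd)
  rev <- as.character(rev)
  if (length(fwd) != length(rev))
    stop_data("mate-count mismatch between R1 and R2")
  paste0(fwd, "N", reverse_complement(rev))
}

#' Load a sample from FASTQ/FASTA files
#'
#' Reads one file (single-end) or an R1/R2 pair (paired-end; records must
#' be in matched order) and returns the pair-concatenated query sample.
#' FASTQ and FASTA are auto-detected from the file extension; gzipped
#' input is handled transparently. Quality strings are read and discarded:
#' classification is sequence-only and reads are not trimmed.
#'
#' @param path_r1 Path to the (forward) reads file.
#' @param path_r2 Optional path to the mate file.
#' @param id Sample identifier; defaults to the R1 file name stem.
#' @return A `query_sample`.
#' @export
load_sample <- function(path_r1, path_r2 = NULL, id = NULL) {
  if (is.null(id)) {
    id <- sub("(\\.(fastq|fq|fasta|fa|fna))?(\\.gz)?$", "",
              basename(path_r1))
  }
  r1 <- read_seq_file(path_r1)
  if (is.null(path_r2) || is.na(path_r2) || !nzchar(path_r2)) {
    return(query_sample(r1, id))
  }
  r2 <- read_seq_file(path_r2)
  if (length(r1) != length(r2))
    stop_data(sprintf(
      "mate-count mismatch: %d records in %s vs %d in %s",
      length(r1), path_r1, length(r2), path_r2))
  query_sample(concat_pair(r1, r2), id)
}

read_seq_file <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("no such file: %s", path))
  stem <- sub("\\.gz$", "", basename(path))
  ext <- tolower(tools::file_ext(stem))
  fmt <- switch(ext,
                fastq = , fq = "fastq",
                fasta = , fa = , fna = "fasta",
                stop_data(sprintf("unrecognized sequence file extension: %s",
                                  basename(path))))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) stop_data(sprintf("malformed %s file %s: %s",
                                          fmt, path, conditionMessage(e))))
  as.character(seqs)
}

#' Remove host-contaminated reads from a sample
#'
#' A read carrying at least one host k-mer is dropped from the sample
#' (host-derived sequence is common to samples from every location and
#' carries no information about origin). For concatenated pairs the test
#' covers both mates: a host k-mer in either mate removes the pair. Read
#' order is preserved and `q` is updated; the operation is idempotent.
#'
#' @param sample A `query_sample`.
#' @param host A `kmer_set` of host k-mers (an empty set leaves the
#'   sample unchanged).
#' @return The filtered `query_sample`.
#' @export
remove_host_reads <- function(sample, host) {
  stopifnot(inherits(sample, "query_sample"), inherits(host, "kmer_set"))
  if (length(host$kmers) == 0L || sample$q == 0L) return(sample)
  hit <- cpp_has_db_kmer(sample$reads, host$kmers, host$k)
  query_sample(sample$reads[!hit], sample$id)
}

#' Read a sample manifest
#'
#' Tab-separated table with columns `sample_id`, `class_label`, `path_R1`
#' and optional `path_R2`; relative paths are resolved against the
#' manifest's directory.
#'
#' @param path Manifest TSV path.
#' @return A data.frame with one row per sample.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("no such file: %s", path))
  m <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "class_label", "path_R1")
  missing <- setdiff(required, names(m))
  if (length(missing))
    stop_data(sprintf("manifest lacks column(s): %s",
                      paste(missing, collapse = ", ")))
  if (!"path_R2" %in% names(m)) m$path_R2 <- NA_character_
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(is.na(p) | !nzchar(p) | grepl("^/", p),
                            p, file.path(base, p))
  m$path_R1 <- fix(m$path_R1)
  m$path_R2 <- fix(m$path_R2)
  m
}

# load every manifest row as a (pair-concatenated) query sample
load_manifest_samples <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    load_sample(manifest$path_R1[i],
                if (is.na(manifest$path_R2[i]) ||
                    !nzchar(manifest$path_R2[i])) NULL
                else manifest$path_R2[i],
                id = manifest$sample_id[i])
  })
}
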