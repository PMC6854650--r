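# Counted and set-valued canonical k-mer databases.
#
# A counted database (class "kmer_counted_db") keeps occurrence counts and
# exists to support infrequent-k-mer filtering and class-level count
# summation. A filtered database (class "kmer_set") is presence/absence
# only — downstream match-rate scoring never uses counts — and carries a
# provenance record (filtering level, ci applied, host-subtracted flag).
# Both store their k-mers sorted, which gives cheap set algebra and a
# stable on-disk order.

new_counted_db <- function(kmers, counts, k, label = "", level = "sample") {
  structure(
    list(k = as.integer(k), kmers = kmers, counts = as.integer(counts),
         label = label, level = match.arg(level, c("sample", "class"))),
    class = "kmer_counted_db"
  )
}

new_kmer_set <- function(kmers, k, label = "",
                         provenance = list(level = NA_character_,
                                           ci = NA_integer_,
                                           host_subtracted = FALSE)) {
  structure(
    list(k = as.integer(k), kmers = kmers, label = label,
         provenance = provenance),
    class = "kmer_set"
  )
}

#' Build a counted k-mer database from reads
#'
#' Extracts canonical k-mers from every read (windows containing a non-ACGT
#' symbol are skipped) and records the total occurrence count of each
#' distinct k-mer across the whole read set.
#'
#' @param reads Character vector of nucleotide sequences.
#' @param k K-mer length in nucleotides.
#' @param label Sample or class identifier carried along for reporting.
#' @param level `"sample"` or `"class"`; marks which aggregation level the
#'   database represents.
#' @return A `kmer_counted_db`: k, sorted k-mers, counts, label, level.
#' @examples
#' build_counted_db(c("ACGTNGAAA"), k = 4)
#' @export
build_counted_db <- function(reads, k, label = "", level = "sample") {
  k <- check_k(k)
  res <- cpp_count_kmers(as.character(reads), k)
  new_counted_db(res$kmers, res$counts, k, label, level)
}

#' Drop infrequent k-mers from a counted database
#'
#' K-mers observed fewer than `ci` times are rejected as likely products of
#' sequencing error; the survivors form a presence/absence `kmer_set`
#' whose provenance records the threshold and the level it was applied at.
#'
#' @param db A `kmer_counted_db`.
#' @param ci Minimum occurrence count to retain a k-mer (>= 1; `ci = 1`
#'   keeps everything).
#' @return A `kmer_set`.
#' @export
filter_infrequent <- function(db, ci) {
  stopifnot(inherits(db, "kmer_counted_db"))
  ci <- check_ci(ci)
  keep <- db$counts >= ci
  new_kmer_set(db$kmers[keep], db$k, db$label,
               provenance = list(level = db$level, ci = ci,
                                 host_subtracted = FALSE))
}

#' Merge sample databases into one class-level database
#'
#' Reference samples sharing a class label are combined into a single
#' class database. Infrequent-k-mer filtering can be applied in two
#' variants: `"sample_level"` filters each sample's counts first and takes
#' the union of the survivors, while `"class_level"` sums the counts over
#' all samples and filters the pooled database. The two differ whenever a
#' k-mer is moderately frequent in several samples but reaches `ci` in
#' none of them alone.
#'
#' @param dbs List of `kmer_counted_db` objects sharing the same k.
#' @param ci Minimum occurrence count.
#' @param mode `"sample_level"` or `"class_level"`.
#' @param label Class label for the merged database.
#' @return A `kmer_set` at class level.
#' @export
merge_to_class <- function(dbs, ci, mode = c("sample_level", "class_level"),
                           label = "") {
  mode <- match.arg(mode)
  ci <- check_ci(ci)
  if (inherits(dbs, "kmer_counted_db")) dbs <- list(dbs)
  stopifnot(length(dbs) >= 1, all(vapply(dbs, inherits, TRUE,
                                         "kmer_counted_db")))
  k <- unique(vapply(dbs, function(d) d$k, 1L))
  if (length(k) != 1L)
    stop_incompatible("databases have mixed k-mer lengths")
  if (mode == "sample_level") {
    members <- lapply(dbs, function(d) d$kmers[d$counts >= ci])
    kmers <- sort(unique(unlist(members, use.names = FALSE)))
  } else {
    pooled <- sum_counted_dbs(dbs, label = label)
    kmers <- pooled$kmers[pooled$counts >= ci]
  }
  new_kmer_set(kmers, k, label,
               provenance = list(level = mode, ci = ci,
                                 host_subtracted = FALSE))
}

# count-wise sum of counted databases (same k); used by class_level
# filtering and by leave-one-out folds in class_level mode
sum_counted_dbs <- function(dbs, label = "") {
  k <- unique(vapply(dbs, function(d) d$k, 1L))
  if (length(k) != 1L)
    stop_incompatible("databases have mixed k-mer lengths")
  all_kmers <- unlist(lapply(dbs, `[[`, "kmers"), use.names = FALSE)
  all_counts <- unlist(lapply(dbs, `[[`, "counts"), use.names = FALSE)
  uniq <- sort(unique(all_kmers))
  counts <- as.integer(rowsum(all_counts, match(all_kmers, uniq)))
  new_counted_db(uniq, counts, k, label, "class")
}

#' Subtract one k-mer set from another
#'
#' Set difference of database members; the canonical use is removing the
#' host (human) k-mer database from every class database so that reads of
#' host origin cannot contribute to any class similarity.
#'
#' @param db A `kmer_set` (the class database).
#' @param host A `kmer_set` to subtract (must share k with `db`).
#' @return A `kmer_set` with the host-subtracted provenance flag set.
#' @export
subtract_kmers <- function(db, host) {
  stopifnot(inherits(db, "kmer_set"), inherits(host, "kmer_set"))
  if (db$k != host$k)
    stop_incompatible("databases have mixed k-mer lengths")
  prov <- db$provenance
  prov$host_subtracted <- TRUE
  new_kmer_set(setdiff(db$kmers, host$kmers), db$k, db$label, prov)
}

#' Build the host k-mer database from a reference genome
#'
#' All canonical k-mers of the host reference sequences, unfiltered (a
#' genome assembly has no sequencing-error k-mers to reject).
#'
#' @param x Path to a FASTA file (optionally gzipped) or a character vector
#'   of sequences.
#' @param k K-mer length.
#' @param label Identifier, default `"host"`.
#' @return A `kmer_set`.
#' @export
build_host_db <- function(x, k, label = "host") {
  k <- check_k(k)
  seqs <- if (length(x) == 1L && file.exists(x)) {
    as.character(Biostrings::readDNAStringSet(x))
  } else {
    as.character(x)
  }
  res <- cpp_count_kmers(seqs, k)
  new_kmer_set(res$kmers, k, label,
               provenance = list(level = "host", ci = NA_integer_,
                                 host_subtracted = FALSE))
}

check_ci <- function(ci) {
  if (length(ci) != 1L || is.na(ci) || ci < 1 || ci != as.integer(ci))
    stop_config("ci must be a single integer >= 1")
  as.integer(ci)
}

#' @export
print.kmer_counted_db <- function(x, ...) {
  cat(sprintf("kmer_counted_db '%s' (%s level): %d distinct %d-mers\n",
              x$label, x$level, length(x$kmers), x$k))
  invisible(x)
}

#' @export
print.kmer_set <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "kmer_set '%s': %d %d-mers (level=%s, ci=%s, host_subtracted=%s)\n",
    x$label, length(x$kmers), x$k, as.character(p$level),
    as.character(p$ci), as.character(p$host_subtracted)))
  invisible(x)
}
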