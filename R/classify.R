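# Read-level match-rate scoring, T/M gating, point accumulation and
# per-sample classification — the heart of the method.

#' Classifier parameters
#'
#' @param T Similarity threshold in percent: a read counts as matched to a
#'   class only when its match-rate score reaches `T`. Default 50.
#' @param M Maximum class number threshold: a read matched to more than
#'   `M` classes is considered uninformative and skipped. `NULL` (the
#'   default) means "the number of classes", i.e. no read is ever skipped
#'   for matching too many classes.
#' @param scheme Point-accumulation scheme: `"simple"` (1 point to every
#'   matched class), `"fractional"` (1/n points where n is the number of
#'   matched classes) or `"weighted"` (points proportional to the class's
#'   match-rate score among the matched classes). Default `"weighted"`.
#' @param k K-mer length in nucleotides, default 24.
#' @param ci Minimum k-mer occurrence count for database filtering,
#'   default 4.
#' @param filter_mode Where `ci` filtering is applied when sample
#'   databases are merged into class databases: `"sample_level"`
#'   (default) or `"class_level"`.
#' @param denominator `"acgt"` (default) scores a read against its count
#'   of A/C/G/T symbols, excluding the artificial pair separator;
#'   `"full"` uses the total sequence length.
#' @return A `classifier_params` list.
#' @export
classifier_params <- function(T = 50, M = NULL,
                              scheme = c("weighted", "simple", "fractional"),
                              k = 24, ci = 4,
                              filter_mode = c("sample_level", "class_level"),
                              denominator = c("acgt", "full")) {
  scheme <- match.arg(scheme)
  filter_mode <- match.arg(filter_mode)
  denominator <- match.arg(denominator)
  if (length(T) != 1L || is.na(T) || T < 0 || T > 100)
    stop_config("T must be a percentage in [0, 100]")
  if (!is.null(M) && (length(M) != 1L || is.na(M) || M < 1 ||
                      M != as.integer(M)))
    stop_config("M must be NULL or a single integer >= 1")
  structure(list(T = as.numeric(T),
                 M = if (is.null(M)) NULL else as.integer(M),
                 scheme = scheme, k = check_k(k), ci = check_ci(ci),
                 filter_mode = filter_mode, denominator = denominator),
            class = "classifier_params")
}

# effective M for N classes (M = NULL means M = N); validated against N
effective_M <- function(params, N) {
  M <- if (is.null(params$M)) N else params$M
  if (M > N)
    stop_config(sprintf("M = %d exceeds the number of classes (%d)", M, N))
  M
}

#' Match-rate score of reads against a class database
#'
#' The match-rate score of a read against a class is the percentage of the
#' read's nucleotides covered by at least one k-length window whose
#' canonical k-mer occurs in the class database, i.e. the fraction of the
#' read explainable by k-mer content shared with the class. Windows
#' containing a non-ACGT symbol never match; a read with no valid window
#' scores 0. The denominator is the read's A/C/G/T symbol count by
#' default, so the artificial pair separator does not dilute the score
#' (see [classifier_params()]).
#'
#' The score is realized as the position-coverage union of matched
#' windows, the interpretation that keeps it in \[0, 100\]: overlapping
#' matched windows are not double-counted.
#'
#' @param reads Character vector of query sequences.
#' @param db A `kmer_set` class database.
#' @param denominator `"acgt"` or `"full"`; see [classifier_params()].
#' @return Numeric vector of scores in \[0, 100\], one per read.
#' @export
match_rate_score <- function(reads, db, denominator = c("acgt", "full")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(db, "kmer_set"))
  cpp_match_rate(as.character(reads), db$kmers, db$k,
                 denominator == "full")
}

#' Score reads against every class database
#'
#' @param reads Character vector of query sequences (or a `query_sample`).
#' @param dbs Named list of `kmer_set` class databases sharing one k.
#' @param denominator See [match_rate_score()].
#' @return Numeric matrix of match-rate scores, one row per read and one
#'   column per class (in the order of `dbs`).
#' @export
score_reads <- function(reads, dbs, denominator = c("acgt", "full")) {
  denominator <- match.arg(denominator)
  if (inherits(reads, "query_sample")) reads <- reads$reads
  stopifnot(length(dbs) >= 1, all(vapply(dbs, inherits, TRUE, "kmer_set")))
  ks <- unique(vapply(dbs, function(d) d$k, 1L))
  if (length(ks) != 1L)
    stop_incompatible("class databases have mixed k-mer lengths")
  labels <- class_labels(dbs)
  m <- vapply(dbs, function(d) match_rate_score(reads, d, denominator),
              numeric(length(reads)))
  m <- matrix(m, nrow = length(reads), ncol = length(dbs),
              dimnames = list(NULL, labels))
  m
}

class_labels <- function(dbs) {
  labels <- names(dbs)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- vapply(dbs, function(d) d$label, "")
  if (any(!nzchar(labels)) || anyDuplicated(labels))
    labels <- paste0("class", seq_along(dbs))
  labels
}

#' Classes a read is matched to after T/M gating
#'
#' A read is matched to the classes whose match-rate score is positive
#' and reaches the similarity threshold `T` (the positivity requirement
#' only matters at `T = 0`, where it makes the threshold mean "any shared
#' content" rather than "every class"). If more than `M` classes qualify
#' the read is ambiguous and skipped; a read matching no class is
#' likewise skipped (it could contribute no points anyway).
#'
#' @param scores Numeric vector of one read's match-rate scores, one per
#'   class.
#' @param T Similarity threshold in percent.
#' @param M Maximum class number threshold.
#' @return Integer vector of matched class indices, or `integer(0)` when
#'   the read is skipped.
#' @export
matched_classes <- function(scores, T, M) {
  A <- which(scores >= T & scores > 0)
  if (length(A) == 0L || length(A) > M) integer(0) else A
}

#' Accumulate per-class similarity points over a sample's reads
#'
#' Every non-skipped read contributes points to its matched classes under
#' the chosen scheme: `simple` gives every matched class 1 point;
#' `fractional` splits 1 point evenly over the n matched classes;
#' `weighted` splits 1 point proportionally to the match-rate scores of
#' the matched classes. Under `fractional` and `weighted` each matched
#' read distributes exactly one point in total, so the final similarities
#' are bounded by the matched-read fraction.
#'
#' @param scores Numeric matrix of match-rate scores (reads x classes),
#'   as from [score_reads()].
#' @param params A `classifier_params`.
#' @return Numeric vector of per-class points (named by the matrix's
#'   column names), with attribute `matched_reads` giving the number of
#'   reads that survived gating.
#' @export
accumulate_points <- function(scores, params = classifier_params()) {
  stopifnot(is.matrix(scores))
  N <- ncol(scores)
  M <- effective_M(params, N)
  pts <- numeric(N)
  names(pts) <- colnames(scores)
  matched <- 0L
  for (i in seq_len(nrow(scores))) {
    A <- matched_classes(scores[i, ], params$T, M)
    if (length(A) == 0L) next
    matched <- matched + 1L
    contrib <- switch(params$scheme,
      simple     = rep(1, length(A)),
      fractional = rep(1 / length(A), length(A)),
      weighted   = scores[i, A] / sum(scores[i, A]))
    pts[A] <- pts[A] + contrib
  }
  attr(pts, "matched_reads") <- matched
  pts
}

#' Classify a sample from its per-read score matrix
#'
#' Accumulated points are normalized by the total number of reads in the
#' query sample (including skipped reads), giving a percent similarity to
#' each class; the sample is classified to the class of largest
#' similarity. An all-zero similarity vector leaves the sample
#' unassigned. Ties are broken deterministically towards the
#' lexicographically smallest class label and flagged.
#'
#' @param scores Numeric matrix of match-rate scores (reads x classes).
#' @param params A `classifier_params`.
#' @param q Number of reads in the query sample; defaults to
#'   `nrow(scores)`.
#' @param sample_id Identifier carried into the result.
#' @return A `similarity_vector`: `sample_id`, named `similarity`
#'   percentages, `predicted_class` (`NA` when unassigned), `unassigned`,
#'   `tie_flag`, `matched_reads`, `q`.
#' @export
classify_profiles <- function(scores, params = classifier_params(),
                              q = nrow(scores), sample_id = "") {
  if (q < 1L) stop_empty_sample("query sample contains no reads")
  pts <- accumulate_points(scores, params)
  sim <- 100 * pts / q
  attributes(sim) <- list(names = names(pts))
  labels <- names(sim)
  if (all(sim == 0)) {
    predicted <- NA_character_
    tie <- FALSE
  } else {
    top <- which(sim == max(sim))
    tie <- length(top) > 1L
    predicted <- sort(labels[top])[1L]
  }
  structure(list(sample_id = sample_id, similarity = sim,
                 predicted_class = predicted,
                 unassigned = is.na(predicted), tie_flag = tie,
                 matched_reads = attr(pts, "matched_reads"), q = q),
            class = "similarity_vector")
}

#' Classify a query sample against class databases
#'
#' Scores every read of the sample against every class database, gates
#' and accumulates points per [accumulate_points()], and normalizes by
#' the sample's read count.
#'
#' @param sample A `query_sample` (host-read removal, if wanted, is
#'   applied beforehand with [remove_host_reads()]).
#' @param dbs Named list of `kmer_set` class databases.
#' @param params A `classifier_params`.
#' @return A `similarity_vector`.
#' @export
classify_sample <- function(sample, dbs, params = classifier_params()) {
  stopifnot(inherits(sample, "query_sample"))
  if (sample$q < 1L)
    stop_empty_sample(sprintf("sample '%s' contains no reads", sample$id))
  scores <- score_reads(sample$reads, dbs, params$denominator)
  classify_profiles(scores, params, q = sample$q, sample_id = sample$id)
}

#' @export
print.similarity_vector <- function(x, ...) {
  cat(sprintf("sample '%s': predicted %s%s (%d/%d reads matched)\n",
              x$sample_id,
              if (x$unassigned) "UNASSIGNED" else x$predicted_class,
              if (x$tie_flag) " [tie]" else "",
              x$matched_reads, x$q))
  print(round(x$similarity, 2))
  invisible(x)
}

# similarity vectors -> one TSV-ready data.frame row each
similarity_table <- function(svs) {
  labels <- names(svs[[1]]$similarity)
  rows <- lapply(svs, function(s) {
    d <- as.data.frame(as.list(s$similarity), check.names = FALSE)
    cbind(data.frame(sample_id = s$sample_id, stringsAsFactors = FALSE),
          d,
          data.frame(predicted_class = ifelse(s$unassigned, "UNASSIGNED",
                                              s$predicted_class),
                     tie_flag = s$tie_flag,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
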