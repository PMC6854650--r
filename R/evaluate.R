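# Evaluation: leave-one-out cross-validation, confusion matrices and
# derived metrics, mutual-similarity matrices, row normalization and
# similarity-graph clustering.

#' Build class-level databases from labeled reference samples
#'
#' One counted database per sample, merged per class label under the
#' configured ci filtering mode, then host-subtracted if a host database
#' is supplied.
#'
#' @param samples List of `query_sample` objects (reference role).
#' @param classes Character vector of class labels, one per sample.
#' @param params A `classifier_params` (uses `k`, `ci`, `filter_mode`).
#' @param host Optional host `kmer_set` to subtract.
#' @return Named list of class `kmer_set` databases (sorted by label).
#' @export
build_class_dbs <- function(samples, classes, params = classifier_params(),
                            host = NULL) {
  stopifnot(length(samples) == length(classes))
  counted <- lapply(samples, function(s)
    build_counted_db(s$reads, params$k, label = s$id, level = "sample"))
  labels <- sort(unique(classes))
  dbs <- lapply(labels, function(lab) {
    db <- merge_to_class(counted[classes == lab], params$ci,
                         mode = params$filter_mode, label = lab)
    if (!is.null(host)) db <- subtract_kmers(db, host) else db
  })
  names(dbs) <- labels
  dbs
}

# class db for one label from precomputed per-sample material, excluding
# the sample indices in `exclude`
class_db_from_parts <- function(label, idx, sets, counted, params, host) {
  db <- if (length(idx) == 0L) {
    new_kmer_set(character(0), params$k, label,
                 provenance = list(level = params$filter_mode,
                                   ci = params$ci, host_subtracted = FALSE))
  } else if (params$filter_mode == "sample_level") {
    new_kmer_set(sort(unique(unlist(lapply(sets[idx], `[[`, "kmers"),
                                    use.names = FALSE))),
                 params$k, label,
                 provenance = list(level = "sample_level", ci = params$ci,
                                   host_subtracted = FALSE))
  } else {
    filter_infrequent(sum_counted_dbs(counted[idx], label = label),
                      params$ci)
  }
  db$label <- label
  if (!is.null(host)) db <- subtract_kmers(db, host)
  db
}

#' Leave-one-out cross-validation
#'
#' Each sample is classified once, against class databases in which its
#' own class has been rebuilt from that class's remaining samples (the
#' other classes are unchanged, so they are built once and reused across
#' folds). Host-read removal is applied to the query side and host
#' subtraction to the database side when `host` is given. A held-out
#' sample whose class has no other samples faces an empty own-class
#' database; such folds are still classified and may end up unassigned.
#'
#' @param samples List of `query_sample` objects.
#' @param classes Character vector of true class labels, one per sample.
#' @param params A `classifier_params`.
#' @param host Optional host `kmer_set`.
#' @return A `kc_confusion`: `labels`, `counts` (true x predicted),
#'   `unassigned` (per true class), `predictions` data.frame.
#' @export
loo_cross_validate <- function(samples, classes,
                               params = classifier_params(), host = NULL) {
  stopifnot(length(samples) == length(classes))
  labels <- sort(unique(classes))
  if (length(labels) < 2L)
    stop_data("leave-one-out evaluation needs at least 2 classes")
  counted <- lapply(samples, function(s)
    build_counted_db(s$reads, params$k, label = s$id, level = "sample"))
  sets <- if (params$filter_mode == "sample_level")
    lapply(counted, filter_infrequent, ci = params$ci) else NULL
  queries <- if (is.null(host)) samples
             else lapply(samples, remove_host_reads, host = host)
  full_dbs <- lapply(labels, function(lab)
    class_db_from_parts(lab, which(classes == lab), sets, counted,
                        params, host))
  names(full_dbs) <- labels
  predictions <- data.frame(
    sample_id = vapply(samples, `[[`, "", "id"),
    true = classes,
    predicted = NA_character_,
    tie = FALSE,
    stringsAsFactors = FALSE)
  for (i in seq_along(samples)) {
    own <- classes[i]
    dbs <- full_dbs
    dbs[[own]] <- class_db_from_parts(
      own, setdiff(which(classes == own), i), sets, counted, params, host)
    if (queries[[i]]$q < 1L) next  # fully host-filtered: unassigned
    sv <- classify_sample(queries[[i]], dbs, params)
    predictions$predicted[i] <- sv$predicted_class
    predictions$tie[i] <- sv$tie_flag
  }
  confusion_from_predictions(predictions, labels)
}

confusion_from_predictions <- function(predictions, labels) {
  counts <- matrix(0L, length(labels), length(labels),
                   dimnames = list(true = labels, predicted = labels))
  unassigned <- setNames(integer(length(labels)), labels)
  for (i in seq_len(nrow(predictions))) {
    tr <- predictions$true[i]
    pr <- predictions$predicted[i]
    if (is.na(pr)) unassigned[tr] <- unassigned[tr] + 1L
    else counts[tr, pr] <- counts[tr, pr] + 1L
  }
  structure(list(labels = labels, counts = counts, unassigned = unassigned,
                 predictions = predictions),
            class = "kc_confusion")
}

#' @export
print.kc_confusion <- function(x, ...) {
  cat("Leave-one-out confusion matrix (rows: true, columns: predicted)\n")
  print(cbind(x$counts, UNASSIGNED = x$unassigned))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Per-class recall (true positive rate, correct predictions over class
#' size), per-class precision (positive predictive value, correct
#' predictions over all predictions for the class; `NA` when the class
#' was never predicted) and overall accuracy (total correct over total
#' samples). Unassigned samples count against recall and accuracy but are
#' no class's false positive.
#'
#' @param cm A `kc_confusion`.
#' @return A `kc_metrics` list: `TPR`, `PPV` (named vectors), `ACC`,
#'   `n_per_class`, `N_s`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "kc_confusion"))
  TP <- diag(cm$counts)
  FP <- colSums(cm$counts) - TP
  n_i <- rowSums(cm$counts) + cm$unassigned
  N_s <- sum(n_i)
  if (N_s < 1L) stop_data("confusion matrix contains no samples")
  PPV <- ifelse(TP + FP == 0, NA_real_, TP / (TP + FP))
  structure(list(TPR = TP / n_i, PPV = setNames(PPV, cm$labels),
                 ACC = sum(TP) / N_s, n_per_class = n_i, N_s = N_s),
            class = "kc_metrics")
}

#' @export
print.kc_metrics <- function(x, ...) {
  print(data.frame(TPR = round(x$TPR, 3), PPV = round(x$PPV, 3),
                   n = x$n_per_class))
  cat(sprintf("ACC = %.3f (%d samples)\n", x$ACC, x$N_s))
  invisible(x)
}

#' Mutual similarities between samples
#'
#' Every sample is classified against the single-sample databases of all
#' samples jointly (ci filtering at the sample level, host subtraction
#' when `host` is given, host-read removal on the query side), giving the
#' similarity of sample r to the content of sample c in cell (r, c). The
#' matrix need not be symmetric — the databases differ per column — and
#' the self-similarity diagonal is left undefined (`NA`).
#'
#' @param samples List of `query_sample` objects (>= 2).
#' @param params A `classifier_params`.
#' @param host Optional host `kmer_set`.
#' @return Numeric matrix of percentages with sample ids as dimnames,
#'   `NA` diagonal, and attribute `normalized = FALSE`.
#' @export
mutual_similarity_matrix <- function(samples, params = classifier_params(),
                                     host = NULL) {
  if (length(samples) < 2L)
    stop_data("mutual similarity needs at least 2 samples")
  ids <- vapply(samples, `[[`, "", "id")
  dbs <- lapply(samples, function(s) {
    db <- filter_infrequent(
      build_counted_db(s$reads, params$k, label = s$id, level = "sample"),
      params$ci)
    if (!is.null(host)) subtract_kmers(db, host) else db
  })
  names(dbs) <- ids
  queries <- if (is.null(host)) samples
             else lapply(samples, remove_host_reads, host = host)
  m <- matrix(NA_real_, length(samples), length(samples),
              dimnames = list(ids, ids))
  for (r in seq_along(samples)) {
    if (queries[[r]]$q < 1L) { m[r, ] <- 0; next }
    sv <- classify_sample(queries[[r]], dbs, params)
    m[r, ] <- sv$similarity
  }
  diag(m) <- NA_real_
  attr(m, "normalized") <- FALSE
  m
}

#' Row-normalize a similarity matrix
#'
#' Each row is scaled so that its maximum defined cell equals 100%,
#' making rows comparable when samples differ in matched-read fraction.
#' Rows with no positive defined cell are left unchanged and flagged in
#' the `degenerate_rows` attribute. Idempotent.
#'
#' @param m Similarity matrix as from [mutual_similarity_matrix()].
#' @return The normalized matrix, `normalized = TRUE`.
#' @export
row_normalize <- function(m) {
  stopifnot(is.matrix(m))
  degenerate <- character(0)
  for (r in seq_len(nrow(m))) {
    row <- m[r, ]
    mx <- suppressWarnings(max(row, na.rm = TRUE))
    if (!is.finite(mx) || mx <= 0) {
      degenerate <- c(degenerate, rownames(m)[r])
    } else {
      m[r, ] <- 100 * row / mx
    }
  }
  attr(m, "normalized") <- TRUE
  attr(m, "degenerate_rows") <- degenerate
  m
}

#' Cluster samples from a similarity matrix
#'
#' Two samples are connected when the larger of their two directed
#' similarities reaches `threshold`; the clusters are the connected
#' components of that graph. Cluster ids are numbered by first appearance
#' in the matrix's row order, so the partition is deterministic.
#' Singletons are allowed.
#'
#' @param m (Row-normalized) similarity matrix.
#' @param threshold Edge threshold in percent; above 100 every sample is
#'   a singleton, at 0 all samples join one cluster.
#' @return Named integer vector mapping sample id to cluster id.
#' @export
cluster_samples <- function(m, threshold) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  sym <- pmax(m, t(m), na.rm = TRUE)
  adj <- !is.na(sym) & sym >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected",
                                           diag = FALSE)
  membership <- igraph::components(g)$membership
  cl <- match(membership, unique(membership))
  setNames(as.integer(cl), rownames(m))
}
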