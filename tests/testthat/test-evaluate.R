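# Leave-one-out evaluation, metrics, mutual similarity, clustering.

# two disjoint-genome classes, two samples each, reads = exact fragments
make_tiny_collection <- function(k = 8, n_classes = 2, per_class = 2,
                                 genome_len = 600, read_len = 60,
                                 seed = 41) {
  set.seed(seed)
  genomes <- replicate(n_classes, random_dna_str(genome_len))
  samples <- list(); classes <- character(0)
  for (cl in seq_len(n_classes)) {
    for (s in seq_len(per_class)) {
      starts <- seq(1, genome_len - read_len + 1, by = read_len %/% 2)
      reads <- substring(genomes[cl], starts, starts + read_len - 1)
      samples[[length(samples) + 1]] <-
        query_sample(reads, sprintf("c%d_s%d", cl, s))
      classes <- c(classes, paste0("class", cl))
    }
  }
  list(samples = samples, classes = classes, genomes = genomes)
}

test_that("disjoint-genome leave-one-out recovers a perfect diagonal", {
  col <- make_tiny_collection()
  params <- classifier_params(T = 50, k = 8, ci = 1)
  cm <- loo_cross_validate(col$samples, col$classes, params)
  expect_equal(unname(diag(cm$counts)), c(2L, 2L))
  expect_equal(sum(cm$counts) , 4L)
  expect_equal(unname(cm$unassigned), c(0L, 0L))
  met <- compute_metrics(cm)
  expect_equal(met$ACC, 1)
  expect_equal(unname(met$TPR), c(1, 1))
  expect_equal(unname(met$PPV), c(1, 1))
  # permuting sample order leaves the confusion matrix unchanged
  perm <- sample(seq_along(col$samples))
  cm2 <- loo_cross_validate(col$samples[perm], col$classes[perm], params)
  expect_equal(cm2$counts, cm$counts)
})

test_that("a singleton class leaves its held-out fold unassigned", {
  col <- make_tiny_collection()
  samples <- col$samples[1:3]          # class2 has one sample only
  classes <- col$classes[1:3]
  cm <- loo_cross_validate(samples, classes,
                           classifier_params(T = 50, k = 8, ci = 1))
  expect_equal(unname(cm$unassigned["class2"]), 1L)
  expect_error(loo_cross_validate(col$samples[1:2], rep("one", 2),
                                  classifier_params()),
               class = "kc_data_error")
})

test_that("incremental fold databases equal a naive full rebuild", {
  col <- make_tiny_collection(seed = 42)
  for (mode in c("sample_level", "class_level")) {
    params <- classifier_params(T = 50, k = 8, ci = 2, filter_mode = mode)
    cm <- loo_cross_validate(col$samples, col$classes, params)
    naive <- vapply(seq_along(col$samples), function(i) {
      counted <- lapply(col$samples[-i], function(s)
        build_counted_db(s$reads, params$k, label = s$id))
      labels <- sort(unique(col$classes))
      dbs <- lapply(labels, function(lab) merge_to_class(
        counted[col$classes[-i] == lab], params$ci, mode, label = lab))
      names(dbs) <- labels
      classify_sample(col$samples[[i]], dbs, params)$predicted_class
    }, "")
    expect_equal(cm$predictions$predicted, naive)
  }
})

test_that("metrics agree with a brute-force recount of predictions", {
  preds <- data.frame(
    sample_id = paste0("s", 1:10),
    true = rep(c("A", "B"), c(4, 6)),
    predicted = c("A", "A", "A", "B", "A", "A", "B", "B", "B", "B"),
    tie = FALSE, stringsAsFactors = FALSE)
  cm <- kmerclass:::confusion_from_predictions(preds, c("A", "B"))
  expect_equal(unname(cm$counts), rbind(c(3L, 1L), c(2L, 4L)))
  met <- compute_metrics(cm)
  expect_equal(unname(met$TPR), c(3 / 4, 4 / 6))
  expect_equal(unname(met$PPV), c(3 / 5, 4 / 5))
  expect_equal(met$ACC, 7 / 10)
  # recount independently from the pair list
  acc <- mean(preds$true == preds$predicted)
  expect_equal(met$ACC, acc)
  # identity matrix and never-predicted class edge cases
  ident <- kmerclass:::confusion_from_predictions(
    data.frame(sample_id = 1:2, true = c("A", "B"),
               predicted = c("A", "B"), tie = FALSE), c("A", "B"))
  expect_equal(compute_metrics(ident)$ACC, 1)
  onecol <- kmerclass:::confusion_from_predictions(
    data.frame(sample_id = 1:2, true = c("A", "B"),
               predicted = c("A", "A"), tie = FALSE), c("A", "B"))
  expect_true(is.na(compute_metrics(onecol)$PPV["B"]))
})

test_that("unassigned folds count in row totals but nobody's false positives", {
  preds <- data.frame(sample_id = 1:3, true = c("A", "A", "B"),
                      predicted = c("A", NA, "B"), tie = FALSE)
  cm <- kmerclass:::confusion_from_predictions(preds, c("A", "B"))
  expect_equal(unname(rowSums(cm$counts) + cm$unassigned), c(2L, 1L))
  met <- compute_metrics(cm)
  expect_equal(unname(met$PPV), c(1, 1))   # the unassigned fold is no FP
  expect_equal(met$ACC, 2 / 3)
})

test_that("mutual similarity matrix has NA diagonal and oracle structure", {
  set.seed(43)
  g1 <- random_dna_str(500); g2 <- random_dna_str(500)
  starts <- seq(1, 441, by = 30)
  s1 <- query_sample(substring(g1, starts, starts + 59), "s1")
  s2 <- query_sample(substring(g2, starts, starts + 59), "s2")
  # s3's reads are a subset of s1's content
  s3 <- query_sample(substring(g1, starts[1:5], starts[1:5] + 59), "s3")
  params <- classifier_params(T = 0, k = 24, ci = 1, scheme = "simple")
  m <- mutual_similarity_matrix(list(s1, s2, s3), params)
  expect_equal(dim(m), c(3L, 3L))
  expect_true(all(is.na(diag(m))))
  expect_false(isTRUE(attr(m, "normalized")))
  # disjoint contents score (near) zero both ways
  expect_lt(m["s1", "s2"], 5); expect_lt(m["s2", "s1"], 5)
  # subset relation: s3 fully covered by s1's database at T = 0
  expect_gt(m["s3", "s1"], 95)
})

test_that("row normalization scales each row's max to 100 and is idempotent", {
  m <- rbind(c(NA, 50, 25), c(10, NA, 40), c(0, 0, NA))
  rownames(m) <- colnames(m) <- c("a", "b", "c")
  n1 <- row_normalize(m)
  expect_equal(unname(n1["a", ]), c(NA, 100, 50))
  expect_equal(unname(n1["b", ]), c(25, NA, 100))
  expect_equal(unname(n1["c", ]), c(0, 0, NA))   # degenerate row untouched
  expect_equal(attr(n1, "degenerate_rows"), "c")
  n2 <- row_normalize(n1)
  expect_equal(unname(n2), unname(n1))
  expect_true(attr(n1, "normalized"))
})

# block-structured fixture: two 3-sample blocks, within >= 90, between <= 10
block_fixture <- function() {
  ids <- paste0("s", 1:6)
  m <- matrix(5, 6, 6, dimnames = list(ids, ids))
  m[1:3, 1:3] <- 95
  m[4:6, 4:6] <- 95
  diag(m) <- NA
  m
}

test_that("threshold clustering recovers block structure and edge cases", {
  m <- block_fixture()
  cl <- cluster_samples(m, 50)
  expect_equal(unname(cl), c(1L, 1L, 1L, 2L, 2L, 2L))
  # any threshold strictly inside the block gap gives the same partition
  for (thr in c(20, 50, 90))
    expect_equal(unname(cluster_samples(m, thr)),
                 c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(unname(cluster_samples(m, 101)), 1:6)  # all singletons
  expect_equal(unname(cluster_samples(m, 0)), rep(1L, 6))  # one cluster
})
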