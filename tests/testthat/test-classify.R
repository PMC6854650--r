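# Match-rate scoring, T/M gating, point accumulation, classification.

test_that("match-rate score is the coverage of matched windows", {
  # read with exactly the windows at positions 1 and 5 matching: covered
  # positions {1..4} u {5..8} of 10 -> 80%
  read <- "AAAACCCCGG"
  db <- make_kmer_set(c("AAAA", "CCCC"), 4)
  expect_equal(match_rate_score(read, db), 80)
  expect_equal(match_rate_score(read, make_kmer_set(character(0), 4)), 0)
  # all windows matching -> 100
  full <- make_kmer_set(unique(oracle_extract(read, 4)), 4)
  expect_equal(match_rate_score(read, full), 100)
  # shorter than k -> no windows -> 0
  expect_equal(match_rate_score("ACG", db), 0)
})

test_that("the pair separator is excluded from the denominator", {
  cc <- concat_pair("AAAA", "TTTT")  # "AAAANAAAA", 8 ACGT symbols
  db <- make_kmer_set("AAAA", 4)
  expect_equal(match_rate_score(cc, db, denominator = "acgt"), 100)
  expect_equal(match_rate_score(cc, db, denominator = "full"), 800 / 9)
})

test_that("scores equal the brute-force coverage oracle", {
  set.seed(31)
  for (i in 1:150) {
    k <- sample(c(4, 8, 24), 1)
    read <- random_dna_str(sample(1:60, 1),
                           alphabet = c("A", "C", "G", "T", "N"))
    members <- unique(c(
      replicate(sample(1:30, 1), oracle_canonical(random_dna_str(k))),
      # seed some true windows so matches actually occur
      oracle_extract(read, k)[sample(c(TRUE, FALSE),
                                     length(oracle_extract(read, k)),
                                     replace = TRUE)]))
    db <- make_kmer_set(members, k)
    expect_equal(match_rate_score(read, db),
                 oracle_coverage(read, db$kmers, k))
  }
})

test_that("score is monotone under database growth", {
  set.seed(32)
  k <- 6
  read <- random_dna_str(50)
  members <- replicate(40, oracle_canonical(random_dna_str(k)))
  members <- unique(c(members, oracle_extract(read, k)))
  for (i in 1:20) {
    sub <- sample(members, sample(seq_along(members), 1))
    sup <- unique(c(sub, sample(members, 5)))
    expect_lte(match_rate_score(read, make_kmer_set(sub, k)),
               match_rate_score(read, make_kmer_set(sup, k)))
  }
})

test_that("multi-class scoring preserves class order and k checks", {
  set.seed(33)
  reads <- replicate(5, random_dna_str(30))
  dbs <- list(a = make_kmer_set(oracle_extract(reads[1], 4), 4),
              b = make_kmer_set(character(0), 4),
              c = make_kmer_set(oracle_extract(reads[1], 4), 4))
  m <- score_reads(reads, dbs)
  expect_equal(dim(m), c(5L, 3L))
  expect_equal(colnames(m), c("a", "b", "c"))
  expect_equal(m[, "b"], rep(0, 5))         # empty database scores 0
  expect_equal(m[, "a"], m[, "c"])          # identical databases agree
  for (j in 1:3)
    expect_equal(m[, j], vapply(reads, oracle_coverage, 0,
                                members = dbs[[j]]$kmers, k = 4,
                                USE.NAMES = FALSE))
  dbs$b <- make_kmer_set(character(0), 5)
  expect_error(score_reads(reads, dbs), class = "kc_incompatible_db_error")
})

test_that("T/M gating matches the published decision rule", {
  expect_equal(matched_classes(c(30, 80, 85, 50, 90, 35), 50, 3),
               integer(0))                       # too many classes: skipped
  expect_equal(matched_classes(c(20, 90, 0, 49, 0, 30), 50, 3), 2L)
  expect_equal(matched_classes(c(20, 88, 90, 0, 0, 50), 50, 3), c(2L, 3L, 6L))
  expect_equal(matched_classes(c(10, 20), 50, 2), integer(0))  # no match
})

test_that("tightening the gates is monotone where the method allows it", {
  # lowering M only ever turns matched reads into skipped ones (the
  # matched set A of a surviving read is unchanged), so per-class totals
  # are non-increasing under every scheme; raising T, by contrast, can
  # concentrate fractional/weighted shares or un-skip an ambiguous read
  # when M < N, so monotonicity under T holds per class only for the
  # simple scheme at M = N, and for the matched-read count generally
  set.seed(34)
  for (i in 1:25) {
    N <- sample(3:8, 1)
    scores <- matrix(runif(10 * N, 0, 100), nrow = 10)
    colnames(scores) <- paste0("c", seq_len(N))
    T1 <- runif(1, 0, 80); T2 <- T1 + runif(1, 0, 20)
    M2 <- sample(N, 1)
    M1 <- M2 + sample.int(N - M2 + 1, 1) - 1  # M1 in [M2, N]
    for (scheme in c("simple", "fractional", "weighted")) {
      p_base <- accumulate_points(scores, classifier_params(
        T = T1, M = M1, scheme = scheme))
      p_M <- accumulate_points(scores, classifier_params(
        T = T1, M = M2, scheme = scheme))
      expect_true(all(p_M <= p_base + 1e-12))
      # at M = N, raising T never recruits matched reads
      pN1 <- accumulate_points(scores, classifier_params(
        T = T1, M = NULL, scheme = scheme))
      pN2 <- accumulate_points(scores, classifier_params(
        T = T2, M = NULL, scheme = scheme))
      expect_lte(attr(pN2, "matched_reads"), attr(pN1, "matched_reads"))
      if (scheme == "simple")
        expect_true(all(pN2 <= pN1 + 1e-12))
    }
  }
})

test_that("with T = 0 and M = N every scoring read is matched", {
  set.seed(35)
  scores <- matrix(runif(40, 0, 100), nrow = 10)
  colnames(scores) <- paste0("c", 1:4)
  p <- accumulate_points(scores, classifier_params(T = 0, M = NULL,
                                                   scheme = "simple"))
  expect_equal(attr(p, "matched_reads"), 10L)
})

test_that("classification normalizes by the full read count and breaks ties", {
  # single read matched to exactly one class: 1 point under every scheme
  one <- matrix(c(90, 10, 0), nrow = 1,
                dimnames = list(NULL, c("x", "y", "z")))
  for (scheme in c("simple", "fractional", "weighted")) {
    sv <- classify_profiles(rbind(one, one * 0), classifier_params(
      T = 50, scheme = scheme), q = 2, sample_id = "s")
    expect_equal(unname(sv$similarity["x"]), 100 * 1 / 2)
    expect_equal(sv$predicted_class, "x")
  }
  # all reads skipped -> all-zero vector -> unassigned
  none <- matrix(c(10, 10), nrow = 1, dimnames = list(NULL, c("x", "y")))
  sv0 <- classify_profiles(none, classifier_params(T = 50))
  expect_true(sv0$unassigned)
  expect_true(is.na(sv0$predicted_class))
  # exact tie -> lexicographically smallest label, flagged
  tie <- matrix(c(80, 80), nrow = 1, dimnames = list(NULL, c("b", "a")))
  svt <- classify_profiles(tie, classifier_params(T = 50, scheme = "simple"))
  expect_true(svt$tie_flag)
  expect_equal(svt$predicted_class, "a")
  expect_error(classify_profiles(none[0, , drop = FALSE],
                                 classifier_params()),
               class = "kc_empty_sample_error")
  expect_error(accumulate_points(none, classifier_params(M = 5)),
               class = "kc_config_error")  # M exceeds N
})

test_that("classify_sample ties the pipeline together end to end", {
  set.seed(36)
  genome_a <- random_dna_str(400)
  genome_b <- random_dna_str(400)
  db <- function(g, lab) make_kmer_set(oracle_extract(g, 8), 8, lab)
  dbs <- list(A = db(genome_a, "A"), B = db(genome_b, "B"))
  reads <- substring(genome_a, seq(1, 351, by = 50), seq(50, 400, by = 50))
  sv <- classify_sample(query_sample(reads, "qa"), dbs,
                        classifier_params(T = 50, k = 8))
  expect_equal(sv$predicted_class, "A")
  expect_equal(unname(sv$similarity["A"]), 100)
  expect_equal(unname(sv$similarity["B"]), 0)
})
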