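# Deterministic synthetic-metagenome generator: class genomes with a
# controllable shared fraction, paired-end reads with substitution
# errors, and host contamination — enough structure to exercise every
# stage of the pipeline without external data.

#' Simulation configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' test suite: 4 classes x 3 samples, 50 kb class genomes with no shared
#' content, 2,000 pairs of 100 nt reads per sample, 1% substitution
#' errors, and 10% of pairs drawn from a 20 kb host genome.
#'
#' @param n_classes Number of origin classes.
#' @param samples_per_class Samples generated per class.
#' @param genome_length Class genome length in nucleotides.
#' @param shared_fraction Fraction in \[0, 1\] of each class genome that is
#'   one segment common to all classes (0 = disjoint genomes, 1 =
#'   identical genomes).
#' @param read_length Read length in nucleotides (must be >= k of any
#'   downstream analysis; validated as >= 1 here).
#' @param insert_gap Unsequenced gap between the two mates of a pair.
#' @param pairs_per_sample Read pairs per sample.
#' @param substitution_rate Per-base substitution probability.
#' @param host_genome_length Host genome length in nucleotides.
#' @param host_read_fraction Fraction in \[0, 1\] of pairs drawn from the
#'   host genome instead of the class genome.
#' @param seed Integer seed fixing the entire dataset byte-for-byte;
#'   per-sample seeds are derived from it by stable hashing of sample
#'   ids, so any subset of samples regenerates identically.
#' @param k K-mer length the dataset is destined for (validation only:
#'   reads or genomes shorter than k would carry no k-mers).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_classes = 4, samples_per_class = 3,
                              genome_length = 50000, shared_fraction = 0,
                              read_length = 100, insert_gap = 50,
                              pairs_per_sample = 2000,
                              substitution_rate = 0.01,
                              host_genome_length = 20000,
                              host_read_fraction = 0.1, seed = 1,
                              k = 24) {
  cfg <- list(k = check_k(k),
              n_classes = as.integer(n_classes),
              samples_per_class = as.integer(samples_per_class),
              genome_length = as.integer(genome_length),
              shared_fraction = as.numeric(shared_fraction),
              read_length = as.integer(read_length),
              insert_gap = as.integer(insert_gap),
              pairs_per_sample = as.integer(pairs_per_sample),
              substitution_rate = as.numeric(substitution_rate),
              host_genome_length = as.integer(host_genome_length),
              host_read_fraction = as.numeric(host_read_fraction),
              seed = as.integer(seed))
  with(cfg, {
    if (n_classes < 1 || samples_per_class < 1 || pairs_per_sample < 1)
      stop_config("counts must be positive integers")
    if (read_length < k || insert_gap < 0)
      stop_config("read_length must be >= k (shorter reads carry no k-mers)")
    if (shared_fraction < 0 || shared_fraction > 1 ||
        host_read_fraction < 0 || host_read_fraction > 1 ||
        substitution_rate < 0 || substitution_rate > 1)
      stop_config("proportions must lie in [0, 1]")
    span <- 2 * read_length + insert_gap
    if (genome_length < span || host_genome_length < span)
      stop_config("genomes must be at least 2*read_length + insert_gap long")
  })
  structure(cfg, class = "simulation_config")
}

# deterministic 31-bit seed from a global seed and a string id
stable_seed <- function(seed, id) {
  m <- 2147483647
  h <- seed %% m
  for (code in utf8ToInt(id)) h <- (h * 131 + code) %% m
  as.integer(h)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate class genomes and the host genome
#'
#' Every class genome starts with one shared segment of length
#' `shared_fraction * genome_length` (identical across classes) followed
#' by class-specific i.i.d. uniform sequence; the host genome is fully
#' independent. Reproducible from `cfg$seed`.
#'
#' @param cfg A `simulation_config`.
#' @return List with `class_genomes` (named character vector, classes
#'   `C1..Cn`) and `host_genome`.
#' @export
generate_class_genomes <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(stable_seed(cfg$seed, "genomes"))
  shared_len <- round(cfg$shared_fraction * cfg$genome_length)
  shared <- if (shared_len > 0) random_dna(shared_len) else ""
  genomes <- vapply(seq_len(cfg$n_classes), function(i) {
    paste0(shared, random_dna(cfg$genome_length - shared_len))
  }, "")
  names(genomes) <- paste0("C", seq_len(cfg$n_classes))
  host <- random_dna(cfg$host_genome_length)
  list(class_genomes = genomes, host_genome = host)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed",
                                               envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

apply_substitutions <- function(reads, rate, read_length) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  bases <- c("A", "C", "G", "T")
  # 3 alternatives per base; row = original base
  alt <- matrix(c("C", "G", "T",
                  "A", "G", "T",
                  "A", "C", "T",
                  "A", "C", "G"), nrow = 4, byrow = TRUE)
  v <- unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE)
  err <- which(stats::runif(length(v)) < rate)
  if (length(err)) {
    v[err] <- alt[cbind(match(v[err], bases),
                        sample.int(3, length(err), replace = TRUE))]
  }
  m <- matrix(v, nrow = read_length)
  do.call(paste0, lapply(seq_len(read_length), function(i) m[i, ]))
}

#' Generate one paired-end sample
#'
#' Pairs are drawn uniformly from the class genome in FR orientation
#' (mate 2 is reported as the reverse complement of the downstream
#' fragment); a `host_read_fraction` share of pairs is drawn from the
#' host genome instead; substitution errors are applied per base.
#'
#' @param class_genome Genome string of the sample's class.
#' @param host_genome Host genome string.
#' @param cfg A `simulation_config`.
#' @param sample_id Sample identifier (also seeds the sample via stable
#'   hashing against `cfg$seed`).
#' @return List with `r1`, `r2` (character vectors), `ids`, and `truth`
#'   (data.frame `read_id`, `origin` = class flag `"class"`/`"host"`).
#' @export
generate_sample <- function(class_genome, host_genome, cfg, sample_id) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(stable_seed(cfg$seed, sample_id))
  n <- cfg$pairs_per_sample
  rl <- cfg$read_length
  span <- 2 * rl + cfg$insert_gap
  is_host <- stats::runif(n) < cfg$host_read_fraction
  genome_of <- ifelse(is_host, host_genome, class_genome)
  glen <- ifelse(is_host, cfg$host_genome_length, cfg$genome_length)
  starts <- 1L + floor(stats::runif(n) * (glen - span + 1L))
  fwd <- substring(genome_of, starts, starts + rl - 1L)
  down <- substring(genome_of, starts + rl + cfg$insert_gap,
                    starts + span - 1L)
  rev <- reverse_complement(down)
  fwd <- apply_substitutions(fwd, cfg$substitution_rate, rl)
  rev <- apply_substitutions(rev, cfg$substitution_rate, rl)
  ids <- sprintf("%s_p%05d", sample_id, seq_len(n))
  list(r1 = fwd, r2 = rev, ids = ids,
       truth = data.frame(read_id = ids,
                          origin = ifelse(is_host, "host", "class"),
                          stringsAsFactors = FALSE))
}

write_fastq <- function(seqs, ids, path, gz = FALSE) {
  qual <- strrep("I", nchar(seqs))
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+", qual))
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Generate a complete labeled synthetic dataset on disk
#'
#' Writes per-sample paired FASTQ files (constant Phred-33 quality), the
#' host genome and class genomes as FASTA, a manifest TSV (`sample_id`,
#' `class_label`, `path_R1`, `path_R2`) consumable by [read_manifest()],
#' and a read-level truth table. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A `simulation_config`.
#' @param dir Output directory (created if needed).
#' @param gz Write gzipped FASTQ files.
#' @return List of paths: `manifest`, `host_fasta`, `genome_dir`,
#'   `truth`, plus the `manifest` data.frame and the generated genomes.
#' @export
generate_dataset <- function(cfg, dir, gz = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_data(sprintf("cannot create directory %s", dir))
  genomes <- generate_class_genomes(cfg)
  genome_dir <- file.path(dir, "genomes")
  dir.create(genome_dir, showWarnings = FALSE)
  host_fasta <- file.path(dir, "host.fasta")
  writeLines(c(">host synthetic host genome", genomes$host_genome),
             host_fasta)
  for (cl in names(genomes$class_genomes)) {
    writeLines(c(paste0(">", cl, " synthetic class genome"),
                 genomes$class_genomes[[cl]]),
               file.path(genome_dir, paste0(cl, ".fasta")))
  }
  ext <- if (gz) ".fastq.gz" else ".fastq"
  rows <- list()
  truths <- list()
  for (cl in names(genomes$class_genomes)) {
    for (s in seq_len(cfg$samples_per_class)) {
      sid <- sprintf("%s_s%d", cl, s)
      sm <- generate_sample(genomes$class_genomes[[cl]],
                            genomes$host_genome, cfg, sid)
      p1 <- file.path(dir, paste0(sid, "_R1", ext))
      p2 <- file.path(dir, paste0(sid, "_R2", ext))
      write_fastq(sm$r1, sm$ids, p1, gz)
      write_fastq(sm$r2, sm$ids, p2, gz)
      rows[[sid]] <- data.frame(sample_id = sid, class_label = cl,
                                path_R1 = basename(p1),
                                path_R2 = basename(p2),
                                stringsAsFactors = FALSE)
      truths[[sid]] <- cbind(sample_id = sid, sm$truth)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- do.call(rbind, truths)
  truth_path <- file.path(dir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(manifest = manifest_path, host_fasta = host_fasta,
       genome_dir = genome_dir, truth = truth_path,
       manifest_df = manifest, genomes = genomes)
}
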