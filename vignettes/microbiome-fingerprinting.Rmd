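---
title: "Classifying metagenomic samples to their environmental origin with k-mer fingerprints"
author: "kmerclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying metagenomic samples to their environmental origin with k-mer fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerclass)
```

## The problem

Whole-metagenome shotgun samples collected in different environments —
the motivating case is surface swabs from subway systems in different
cities — carry a characteristic mixture of microbial genomes, a
*microbiome fingerprint* of the location. `kmerclass` classifies a query
sample to one of N origin classes directly from raw reads, with no
taxonomic or functional annotation: the reference samples of each class
are reduced to a set of canonical k-mers, every query read is scored
against every class by shared k-mer content, and the per-read evidence
is aggregated into a per-class similarity.

## The model

### Reference databases

For each reference sample a counted database of canonical k-mers
(default k = 24) is built; a canonical k-mer is the lexicographically
smaller of a k-mer and its reverse complement, which makes matching
strand-agnostic. Windows containing any symbol outside A/C/G/T are
ignored. K-mers observed fewer than `ci` times (default 4) are rejected
as likely sequencing errors, in one of two variants:

* **sample-level** filtering (default): each sample's counts are
  thresholded first, and the class database is the union of the
  survivors;
* **class-level** filtering: counts are pooled across the class's
  samples and the pooled database is thresholded.

The two differ exactly for k-mers that are moderately frequent in
several samples but reach `ci` in none alone; sample-level filtering is
the stricter of the two against sample-specific noise and is the
configuration under which the method performed best.

Host (human) sequence is common to samples from every location and
therefore uninformative; a host database built from a reference genome
is subtracted from every class database, and any query read containing
at least one host k-mer is removed. We subtract the host database
*after* ci filtering of the class databases: subtraction only ever
removes members, and removing them after thresholding cannot
resurrect error k-mers, so the order is immaterial for set content
derived from the same counts — we pick the cheaper order (the
subtraction operates on the smaller, filtered sets).

### Paired-end reads

A read pair is scored as a single unit: the forward read, a single `'N'`
marker, and the reverse complement of the mate are concatenated. Because
databases contain pure A/C/G/T k-mers, no k-mer spanning the marker can
ever match, so the mates are scored jointly without junction artefacts.
Host filtering is applied to the concatenated unit — a host k-mer in
either mate removes the pair, matching the unit of classification.
Reads are not quality-trimmed; scoring is sequence-only.

### Match-rate score

The match-rate score of read i against class j is

$$\Xi_{ij} = 100 \times \frac{\#\{\text{read positions covered by a
matched window}\}}{L_i}$$

where a window is *matched* when its canonical k-mer is in the class
database, and \(L_i\) is the read's A/C/G/T symbol count. Overlapping
matched windows are not double-counted. Two remarks:

* The published description defines the score as "the ratio of the
  number of nucleotides in the k-mers occurring both in the read and in
  the database to the read length" and delegates the exact algorithm to
  the CoMeta matching engine. The position-coverage union used here is
  the interpretation that keeps the score within \[0, 100\] and
  reproduces the percent-scale example values; it is stated prominently
  because an extension-based matcher could differ on adversarial reads.
* The denominator excludes the artificial pair separator (and any
  ambiguity symbol), which can never be covered; counting it would
  dilute every paired read's score by a constant \(1/(2\ell+1)\)
  factor. `denominator = "full"` restores the raw-length convention.

### Gating and point accumulation

For each read the matched class set is
\(A_i = \{j : \Xi_{ij} \ge \mathbb{T},\ \Xi_{ij} > 0\}\) with similarity
threshold \(\mathbb{T}\) (default 50%). A read is *skipped* when
\(|A_i| > \mathbb{M}\) (too ambiguous; \(\mathbb{M}\) defaults to N) or
when \(A_i = \emptyset\). The positivity requirement only matters at
\(\mathbb{T} = 0\), where it makes the threshold mean "any shared
content" rather than "every class", and it guarantees the weighted
denominator below is never zero.

Each surviving read contributes points to its matched classes:

* **simple**: 1 point to every class in \(A_i\);
* **fractional**: \(1/|A_i|\) points to each;
* **weighted** (default): \(\Xi_{ij} / \sum_{a \in A_i} \Xi_{ia}\)
  points to class j.

Under fractional and weighted schemes every matched read distributes
exactly one point, a conservation property the test suite asserts to
1e-9. The similarity of the sample to class j is
\(100 \times \text{points}_j / q\) with q the total read count
*including skipped reads* (forced by the published worked example); the
sample is assigned to the class of largest similarity. An all-zero
vector leaves the sample unassigned; exact ties are broken toward the
lexicographically smallest label and flagged.

A note on monotonicity: lowering \(\mathbb{M}\) can only turn matched
reads into skipped ones, so every class's point total is non-increasing
— under every scheme. Raising \(\mathbb{T}\) is *not* monotone per
class: shrinking \(A_i\) concentrates the fractional/weighted unit
point on fewer classes, and when \(\mathbb{M} < N\) it can un-skip a
previously ambiguous read. What raising \(\mathbb{T}\) does guarantee
(at \(\mathbb{M} = N\)) is a non-increasing matched-read count, and
non-increasing per-class totals under the simple scheme. The tests
check exactly these.

### Precision and reporting

All scores and similarities are computed in double precision and
rounded only at output. The published worked example prints the
weighted point totals at two decimals (1.39, 0.39, 0.22) and derives
the percent similarities from those rounded totals (46.33%, 13%,
7.33%); the golden tests and the acceptance script reproduce that
printed arithmetic, while the classifier itself keeps full precision
(46.20%, 13.16%, 7.31%).

## Evaluation

Leave-one-out cross-validation classifies each labeled sample against
databases in which its own class has been rebuilt from the class's
remaining samples; the other classes are unaffected, so they are built
once and reused (sample-level mode re-unions the remaining per-sample
filtered sets; class-level mode re-sums and re-filters counts). The
equivalence of this incremental rebuild with a naive from-scratch
rebuild is property-tested. A held-out sample whose class has no other
samples faces an empty own-class database and is typically unassigned.
Unassigned folds count in their true class's row total (hurting recall
and accuracy) but are no class's false positive. From the confusion
matrix we report per-class recall \(TPR_i = TP_i/n_i\), precision
\(PPV_i = TP_i/(TP_i + FP_i)\) (NA when the class is never predicted),
and overall accuracy \(ACC = \sum_i TP_i / N_s\).

For unlabeled collections, `mutual_similarity_matrix()` classifies each
sample against the single-sample databases of all samples jointly; the
self-similarity diagonal is left undefined rather than set to 100
(self-comparison is uninformative, and including it would dominate row
normalization). Rows are then normalized so each row's maximum equals
100%, and `cluster_samples()` partitions the samples as the connected
components of the graph with an edge wherever the larger of the two
directed similarities reaches a threshold — an automated version of the
manual sorting by which such matrices are usually read. The matrix is
not symmetrized before normalization because the two directions answer
different questions (r explained by c's content vs c explained by r's).

## The synthetic-data generator

Real urban-metagenome collections are terabyte-scale; the generator
provides a desk-scale stand-in that exercises every code path. Its
defaults are the study conditions used by the test suite: 4 classes × 3
samples, 50 kb class genomes with no shared content, 2,000 pairs of
100 nt reads per sample (FR orientation, 50 nt insert gap), 1%
uniform substitution errors, and 10% of pairs drawn from an independent
20 kb host genome. Genomes are i.i.d. uniform ACGT with an optional
shared prefix segment (`shared_fraction`) common to all classes; a
50 kb random genome shares essentially no 24-mers with another
(expected collisions ≪ 1), so `shared_fraction` cleanly interpolates
between perfectly separable and indistinguishable classes, and the
test suite verifies that the classification margin erodes as it grows.

One global seed fixes the dataset byte-for-byte; per-sample seeds are
derived by stable string hashing of sample ids so any subset
regenerates identically. FASTQ is written with constant Phred-33
qualities, since classification is sequence-only.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: realistic community composition and abundance
profiles, GC bias, repeat structure, indels and platform-specific error
profiles, cross-class ecological overlap beyond a literal shared
segment, and real host-genome content. Perfect leave-one-out accuracy
on the synthetic defaults validates the machinery, not field
performance.

## Parameter summary

| parameter | default | units | meaning |
|---|---|---|---|
| `k` | 24 | nt | k-mer length; long enough that random 24-mer collisions are negligible and a single hit is strong evidence |
| `ci` | 4 | count | minimum occurrences for a k-mer to survive filtering |
| `filter_mode` | `sample_level` | — | where ci filtering is applied during class merging |
| `T` | 50 | % | minimum match-rate score for a read to match a class |
| `M` | N | classes | maximum matched classes before a read is skipped |
| `scheme` | `weighted` | — | per-read point distribution |
| `denominator` | `acgt` | — | read-length convention for the score |

The operating point (k = 24, ci = 4, T = 50, M = N, weighted,
sample-level) mirrors the configuration that performed best in the
study the method originates from.

## Numerical choices and degenerate inputs

* Reads shorter than k have no windows: they score 0 against every
  class and can never be removed by host filtering.
* An empty query sample is an error for classification; in
  leave-one-out a sample emptied by host filtering is recorded as
  unassigned rather than aborting the run.
* `ci` larger than every count empties the databases; the CLI build
  command warns rather than fails.
* Database files carry k in their header; mixing k across databases or
  against the configured parameters is an error, as is a truncated or
  foreign file.
* Row normalization leaves all-zero (or all-NA) rows untouched and
  flags them.
* Problem sizes in the test suite (4×3 samples, 50 kb genomes, 2,000
  pairs for the end-to-end recovery test; hundreds to a thousand random
  instances for the oracle-equivalence properties) were chosen so the
  whole suite completes in about a minute while still covering every
  scheme, filter mode and failure path.

## Limitations

* Desk-scale by design: databases are in-memory R objects; billions of
  k-mers need external-memory counting tools, not this package.
* The coverage-union score is one defensible reading of the published
  score definition; an extension-based matcher could differ on reads
  with interleaved matched/unmatched windows.
* Uniform-random synthetic genomes make separability statements easy to
  analyze but optimistic.
* Clustering is a single-linkage-style component partition; it is meant
  to automate reading a small normalized similarity table, not to
  replace a clustering study.
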