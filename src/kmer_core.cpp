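#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <unordered_set>
#include <unordered_map>

using namespace Rcpp;

// Core k-mer machinery: canonicalization, windowed extraction, counted
// extraction, position-coverage match-rate scoring, host-k-mer screening,
// reverse complement and 2-bit packing. All scanning uses a single pass
// with a running count of consecutive A/C/G/T symbols, so a window is
// valid iff the run ending at its last position has length >= k.

static inline char upper_base(char c) {
  return (c >= 'a' && c <= 'z') ? c - 32 : c;
}

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline char comp_acgt(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return '?';
}

// IUPAC-aware complement; returns 0 for symbols with no defined complement
static inline char comp_iupac(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'U': return 'A';
    case 'R': return 'Y'; case 'Y': return 'R';
    case 'S': return 'S'; case 'W': return 'W';
    case 'K': return 'M'; case 'M': return 'K';
    case 'B': return 'V'; case 'V': return 'B';
    case 'D': return 'H'; case 'H': return 'D';
    case 'N': return 'N';
  }
  return 0;
}

// canonical form (lexicographic min of k-mer and its reverse complement)
// of the window seq[s, s+k); seq must already be uppercase A/C/G/T there
static inline std::string canonical_window(const std::string& seq,
                                           size_t s, int k) {
  std::string fwd = seq.substr(s, k);
  std::string rc(k, 'A');
  for (int j = 0; j < k; ++j) rc[j] = comp_acgt(fwd[k - 1 - j]);
  return (rc < fwd) ? rc : fwd;
}

static std::string upper_copy(const char* p) {
  std::string s(p);
  for (size_t i = 0; i < s.size(); ++i) s[i] = upper_base(s[i]);
  return s;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector kmers) {
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(kmers[i]))
      stop("invalid k-mer: NA");
    std::string s = upper_copy(kmers[i]);
    if (s.empty()) stop("invalid k-mer: empty sequence");
    for (size_t j = 0; j < s.size(); ++j)
      if (!is_acgt(s[j]))
        stop("invalid k-mer: symbol '%s' is not A/C/G/T",
             std::string(1, s[j]).c_str());
    out[i] = canonical_window(s, 0, (int) s.size());
  }
  return out;
}

// canonical k-mers of every valid window, in window order
// [[Rcpp::export]]
CharacterVector cpp_extract_kmers(std::string seq, int k) {
  std::vector<std::string> res;
  for (size_t i = 0; i < seq.size(); ++i) seq[i] = upper_base(seq[i]);
  int n = (int) seq.size();
  int run = 0;
  for (int i = 0; i < n; ++i) {
    run = is_acgt(seq[i]) ? run + 1 : 0;
    if (run >= k) res.push_back(canonical_window(seq, i - k + 1, k));
  }
  return wrap(res);
}

// multiset of canonical k-mers over all sequences, as sorted unique
// k-mers with occurrence counts
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  std::unordered_map<std::string, int> counts;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    if (CharacterVector::is_na(seqs[r])) continue;
    std::string seq = upper_copy(seqs[r]);
    int n = (int) seq.size();
    int run = 0;
    for (int i = 0; i < n; ++i) {
      run = is_acgt(seq[i]) ? run + 1 : 0;
      if (run >= k) ++counts[canonical_window(seq, i - k + 1, k)];
    }
  }
  std::vector<std::string> keys;
  keys.reserve(counts.size());
  for (const auto& kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  IntegerVector cnt(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) cnt[i] = counts[keys[i]];
  return List::create(_["kmers"] = wrap(keys), _["counts"] = cnt);
}

// match-rate score: percent of read positions covered by >=1 window whose
// canonical k-mer is in db; denominator is the count of A/C/G/T symbols
// (full_length = false) or the total read length (full_length = true)
// [[Rcpp::export]]
NumericVector cpp_match_rate(CharacterVector reads, CharacterVector db,
                             int k, bool full_length) {
  std::unordered_set<std::string> set;
  set.reserve(db.size() * 2 + 1);
  for (R_xlen_t i = 0; i < db.size(); ++i)
    set.insert(std::string(db[i]));
  R_xlen_t q = reads.size();
  NumericVector out(q);
  std::vector<char> cov;
  for (R_xlen_t r = 0; r < q; ++r) {
    std::string seq = upper_copy(reads[r]);
    int n = (int) seq.size();
    cov.assign(n, 0);
    int run = 0, L = 0;
    for (int i = 0; i < n; ++i) {
      if (is_acgt(seq[i])) { ++run; ++L; } else run = 0;
      if (run >= k && set.count(canonical_window(seq, i - k + 1, k)))
        for (int p = i - k + 1; p <= i; ++p) cov[p] = 1;
    }
    if (full_length) L = n;
    int covered = 0;
    for (int i = 0; i < n; ++i) covered += cov[i];
    out[r] = (L == 0) ? 0.0 : 100.0 * covered / L;
  }
  return out;
}

// TRUE for reads containing at least one db k-mer (host-read screening)
// [[Rcpp::export]]
LogicalVector cpp_has_db_kmer(CharacterVector reads, CharacterVector db,
                              int k) {
  std::unordered_set<std::string> set;
  set.reserve(db.size() * 2 + 1);
  for (R_xlen_t i = 0; i < db.size(); ++i)
    set.insert(std::string(db[i]));
  R_xlen_t q = reads.size();
  LogicalVector out(q);
  for (R_xlen_t r = 0; r < q; ++r) {
    std::string seq = upper_copy(reads[r]);
    int n = (int) seq.size();
    int run = 0;
    bool hit = false;
    for (int i = 0; i < n && !hit; ++i) {
      run = is_acgt(seq[i]) ? run + 1 : 0;
      if (run >= k && set.count(canonical_window(seq, i - k + 1, k)))
        hit = true;
    }
    out[r] = hit;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(seqs[i])) { out[i] = NA_STRING; continue; }
    std::string s(seqs[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = comp_iupac(upper_base(s[s.size() - 1 - j]));
      if (c == 0)
        stop("invalid nucleotide symbol '%s'",
             std::string(1, s[s.size() - 1 - j]).c_str());
      r[j] = c;
    }
    out[i] = r;
  }
  return out;
}

// 2-bit packing, A=0 C=1 G=2 T=3, first base in the two most significant
// bits of each byte so byte order preserves lexicographic k-mer order
// [[Rcpp::export]]
RawVector cpp_pack_kmers(CharacterVector kmers, int k) {
  int bpk = (k + 3) / 4;
  RawVector out((R_xlen_t) bpk * kmers.size());
  R_xlen_t pos = 0;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = kmers[i];
    for (int b = 0; b < bpk; ++b) {
      unsigned char byte = 0;
      for (int j = 0; j < 4; ++j) {
        int idx = b * 4 + j;
        unsigned char code = 0;
        if (idx < k) {
          switch (s[idx]) {
            case 'A': code = 0; break;
            case 'C': code = 1; break;
            case 'G': code = 2; break;
            case 'T': code = 3; break;
            default: stop("cannot pack non-ACGT k-mer");
          }
        }
        byte |= code << (6 - 2 * j);
      }
      out[pos++] = byte;
    }
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_unpack_kmers(RawVector bytes, int k, int n) {
  static const char* alpha = "ACGT";
  int bpk = (k + 3) / 4;
  if ((R_xlen_t) bpk * n != bytes.size())
    stop("packed payload size does not match record count");
  CharacterVector out(n);
  std::string buf(k, 'A');
  for (int i = 0; i < n; ++i) {
    for (int idx = 0; idx < k; ++idx) {
      unsigned char byte = bytes[(R_xlen_t) i * bpk + idx / 4];
      buf[idx] = alpha[(byte >> (6 - 2 * (idx % 4))) & 3];
    }
    out[i] = buf;
  }
  return out;
}
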