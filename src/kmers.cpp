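#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// 2-bit encoded canonical k-mers, k <= 32, packed into uint64.
// Codes cross the R boundary bit-cast into doubles; they are opaque on the
// R side (never sorted or compared there) and only ever handed back to the
// routines below, which recast and binary-search them as uint64.

static inline double u2d(uint64_t u) { double d; std::memcpy(&d, &u, 8); return d; }
static inline uint64_t d2u(double d) { uint64_t u; std::memcpy(&u, &d, 8); return u; }

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

// Walk a sequence emitting (position, canonical code) for every k-mer made
// of pure ACGT; k-mers touching any other character are skipped.
template <typename F>
static void scan_kmers(const char* s, size_t n, int k, F emit) {
  if ((int)n < k) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;  // length of current valid run
  int shift = 2 * (k - 1);
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      emit((int)(i + 1 - k), canon);
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_kmer_set(CharacterVector seqs, int k, int min_count) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  std::unordered_map<uint64_t, int> counts;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) continue;
    const char* s = CHAR(seqs[i]);
    scan_kmers(s, std::strlen(s), k, [&](int, uint64_t c) { counts[c]++; });
  }
  std::vector<uint64_t> keep;
  for (auto& kv : counts)
    if (kv.second >= min_count) keep.push_back(kv.first);
  std::sort(keep.begin(), keep.end());
  NumericVector out(keep.size());
  for (size_t i = 0; i < keep.size(); ++i) out[i] = u2d(keep[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_unique_kmer_positions(CharacterVector contigs, int k) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  std::unordered_map<uint64_t, int> counts;
  R_xlen_t nc = contigs.size();
  for (R_xlen_t i = 0; i < nc; ++i) {
    const char* s = CHAR(contigs[i]);
    scan_kmers(s, std::strlen(s), k, [&](int, uint64_t c) { counts[c]++; });
  }
  List out(nc);
  for (R_xlen_t i = 0; i < nc; ++i) {
    const char* s = CHAR(contigs[i]);
    std::vector<int> pos;
    scan_kmers(s, std::strlen(s), k, [&](int p, uint64_t c) {
      if (counts[c] == 1) pos.push_back(p);
    });
    out[i] = IntegerVector(pos.begin(), pos.end());
  }
  out.attr("names") = contigs.attr("names");
  return out;
}

static inline bool in_set(const std::vector<uint64_t>& set, uint64_t code) {
  return std::binary_search(set.begin(), set.end(), code);
}

static std::vector<uint64_t> recast(NumericVector codes) {
  std::vector<uint64_t> v(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i) v[i] = d2u(codes[i]);
  return v;  // cpp_kmer_set emits sorted uint64 order
}

// [[Rcpp::export]]
NumericVector cpp_absent_fraction(CharacterVector reads, int k, NumericVector set_codes) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  std::vector<uint64_t> set = recast(set_codes);
  R_xlen_t n = reads.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(reads[i]);
    long total = 0, absent = 0;
    scan_kmers(s, std::strlen(s), k, [&](int, uint64_t c) {
      total++;
      if (!in_set(set, c)) absent++;
    });
    out[i] = total == 0 ? NA_REAL : (double)absent / (double)total;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_match_positions(CharacterVector seq, int k, NumericVector set_codes) {
  if (seq.size() != 1) stop("expected a single sequence");
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  std::vector<uint64_t> set = recast(set_codes);
  const char* s = CHAR(seq[0]);
  std::vector<int> pos;
  scan_kmers(s, std::strlen(s), k, [&](int p, uint64_t c) {
    if (in_set(set, c)) pos.push_back(p);
  });
  return IntegerVector(pos.begin(), pos.end());
}

// [[Rcpp::export]]
CharacterVector cpp_decode_codes(NumericVector codes, int k) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  R_xlen_t n = codes.size();
  CharacterVector out(n);
  std::vector<char> buf(k + 1, '\0');
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t u = d2u(codes[i]);
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = BITS2BASE[u & 3ULL];
      u >>= 2;
    }
    out[i] = std::string(buf.data(), k);
  }
  return out;
}
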