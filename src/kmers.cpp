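#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// 2-bit base codes: A=0, C=1, G=2, T=3; anything else = -1 (window killer).
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char code_base(int b) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  return bases[b];
}

static uint64_t encode_one(const std::string &s) {
  if (s.size() < 1 || s.size() > 31)
    stop("k-mer length must be between 1 and 31");
  uint64_t code = 0;
  for (char c : s) {
    int b = base_code(c);
    if (b < 0) stop("k-mer contains a non-ACGT character: '%s'", s.c_str());
    code = (code << 2) | (uint64_t)b;
  }
  return code;
}

static std::string decode_one(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = code_base(code & 3ULL);
    code >>= 2;
  }
  return s;
}

// reverse complement of a 2-bit packed k-mer: complement is XOR with 3
static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector kmers) {
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    std::string rc(s.size(), 'A');
    for (size_t j = 0; j < s.size(); ++j) {
      int b = base_code(s[s.size() - 1 - j]);
      if (b < 0)
        stop("sequence contains a non-ACGT character: '%c'", s[s.size() - 1 - j]);
      rc[j] = code_base(3 - b);
    }
    out[i] = rc;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector kmer_encode_cpp(CharacterVector kmers) {
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t code = encode_one(as<std::string>(kmers[i]));
    out[i] = std::to_string(code);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector kmer_decode_cpp(CharacterVector codes, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  R_xlen_t n = codes.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string cs = as<std::string>(codes[i]);
    uint64_t code = 0;
    for (char c : cs) {
      if (c < '0' || c > '9') stop("invalid code string '%s'", cs.c_str());
      code = code * 10ULL + (uint64_t)(c - '0');
    }
    out[i] = decode_one(code, k);
  }
  return out;
}

// Enumerate distinct k-mers over all contigs of one taxon. Windows containing
// any non-ACGT character are skipped; windows never span contig boundaries.
// Returned strings are sorted ascending (A<C<G<T), i.e. by integer code.
// [[Rcpp::export]]
CharacterVector enumerate_kmers_cpp(CharacterVector contigs, int k, bool canonical) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_set<uint64_t> seen;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    std::string seq = as<std::string>(contigs[ci]);
    R_xlen_t n = (R_xlen_t)seq.size();
    uint64_t code = 0;
    int valid = 0; // length of current run of ACGT bases ending here
    for (R_xlen_t i = 0; i < n; ++i) {
      int b = base_code(seq[i]);
      if (b < 0) {
        valid = 0;
        code = 0;
        continue;
      }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        uint64_t key = code;
        if (canonical) {
          uint64_t rc = revcomp_code(code, k);
          if (rc < key) key = rc;
        }
        seen.insert(key);
      }
    }
  }
  std::vector<uint64_t> codes(seen.begin(), seen.end());
  std::sort(codes.begin(), codes.end());
  CharacterVector out(codes.size());
  for (size_t i = 0; i < codes.size(); ++i) out[i] = decode_one(codes[i], k);
  return out;
}

// Assemble the presence/absence matrix from per-taxon k-mer string vectors.
// Rows are the union of k-mers, sorted ascending by 2-bit integer code.
// [[Rcpp::export]]
List build_matrix_cpp(List kmersets, int k) {
  int m = kmersets.size();
  std::unordered_map<uint64_t, int> index;
  std::vector<std::vector<uint64_t>> sets(m);
  for (int j = 0; j < m; ++j) {
    CharacterVector v = kmersets[j];
    sets[j].reserve(v.size());
    for (R_xlen_t i = 0; i < v.size(); ++i) {
      std::string s = as<std::string>(v[i]);
      if ((int)s.size() != k)
        stop("k-mer '%s' does not have length %d", s.c_str(), k);
      uint64_t code = encode_one(s);
      sets[j].push_back(code);
      index.emplace(code, 0);
    }
  }
  std::vector<uint64_t> rows;
  rows.reserve(index.size());
  for (auto &kv : index) rows.push_back(kv.first);
  std::sort(rows.begin(), rows.end());
  for (size_t i = 0; i < rows.size(); ++i) index[rows[i]] = (int)i;

  IntegerMatrix X((int)rows.size(), m);
  for (int j = 0; j < m; ++j)
    for (uint64_t code : sets[j]) X(index[code], j) = 1;

  CharacterVector rn(rows.size());
  for (size_t i = 0; i < rows.size(); ++i) rn[i] = decode_one(rows[i], k);
  return List::create(_["X"] = X, _["kmers"] = rn);
}
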