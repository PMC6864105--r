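// MinHash sketching of canonical k-mers.
//
// Each valid (N-free) k-mer is 2-bit encoded together with its reverse
// complement; the lexicographically smaller encoding is hashed with a
// splitmix64-style 64-bit mixer. Hashes are truncated to 53 bits so they are
// exactly representable as R doubles; the sketch is the sorted set of the s
// smallest distinct values.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N or anything else breaks the k-mer run
  }
}

// [[Rcpp::export(name = ".minhash_hashes")]]
NumericVector minhash_hashes(CharacterVector seqs, int k, int s) {
  if (k < 1 || k > 26) stop("k must be in [1, 26] for 2-bit encoding");
  if (s < 1) stop("sketch size s must be >= 1");
  const uint64_t kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const uint64_t hmask = (1ULL << 53) - 1ULL;
  const int shift = 2 * (k - 1);

  std::vector<uint64_t> hashes;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *p = CHAR(STRING_ELT(seqs, i));
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & kmask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        hashes.push_back(mix64(canon) & hmask);
      }
    }
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  const size_t n = std::min<size_t>(s, hashes.size());
  NumericVector out(n);
  for (size_t j = 0; j < n; ++j) out[j] = (double)hashes[j];
  return out;
}
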