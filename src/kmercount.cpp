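#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int code2(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

// Canonical k-mer census: lexicographic min of the k-mer and its reverse
// complement under A<C<G<T; k-mers touching non-ACGT bases are skipped.
// [[Rcpp::export]]
List cpp_kmer_census(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, uint32_t> census;
  census.reserve(1 << 20);
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  for (int r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (const char *p = s; *p; ++p) {
      int c = code2(*p);
      if (c > 3) { run = 0; fwd = rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++census[canon];
      }
    }
  }
  // depth -> number of distinct species
  std::unordered_map<uint32_t, double> hist;
  for (auto &kv : census) ++hist[kv.second];
  std::vector<double> depth, species;
  depth.reserve(hist.size());
  for (auto &kv : hist) { depth.push_back(kv.first); species.push_back(kv.second); }
  return List::create(_["depth"] = wrap(depth), _["species"] = wrap(species));
}
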