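#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// 2-bit encoding; 4 marks any non-ACGT base (breaks k-mer runs).
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static void revcomp(std::string &s) {
  std::reverse(s.begin(), s.end());
  for (auto &c : s) {
    switch (c) {
    case 'A': c = 'T'; break; case 'T': c = 'A'; break;
    case 'C': c = 'G'; break; case 'G': c = 'C'; break;
    case 'a': c = 't'; break; case 't': c = 'a'; break;
    case 'c': c = 'g'; break; case 'g': c = 'c'; break;
    default: break;
    }
  }
}

// Rolling k-mer keys of seq; positions with any non-ACGT base get key
// UINT64_MAX (never matched). k <= 31.
static void kmer_keys(const std::string &seq, int k,
                      std::vector<uint64_t> &keys) {
  const uint64_t BAD = UINT64_MAX;
  size_t n = seq.size();
  keys.assign(n >= (size_t)k ? n - k + 1 : 0, BAD);
  if (keys.empty()) return;
  uint64_t key = 0, mask = (k == 32) ? UINT64_MAX : ((1ULL << (2 * k)) - 1);
  int run = 0;  // valid bases accumulated
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) keys[i - k + 1] = key;
  }
}

struct SeedIndex {
  std::vector<std::pair<uint64_t, uint32_t>> entries;  // (key, global pos)
  std::vector<uint64_t> offsets;                       // chrom start offsets
  std::vector<uint32_t> bucket_start;  // prefix-bucket index into entries
  int k;
  int bucket_shift;
};

static void build_index(const std::vector<std::string> &seqs, int k,
                        SeedIndex &idx) {
  idx.k = k;
  idx.offsets.clear();
  size_t total = 0;
  for (auto &s : seqs) { idx.offsets.push_back(total); total += s.size(); }
  idx.entries.clear();
  idx.entries.reserve(total);
  std::vector<uint64_t> keys;
  for (size_t ci = 0; ci < seqs.size(); ++ci) {
    kmer_keys(seqs[ci], k, keys);
    for (size_t p = 0; p < keys.size(); ++p)
      if (keys[p] != UINT64_MAX)
        idx.entries.emplace_back(keys[p], (uint32_t)(idx.offsets[ci] + p));
  }
  std::sort(idx.entries.begin(), idx.entries.end());
  // prefix buckets on the top bits of the key: O(1) candidate ranges
  int key_bits = 2 * k;
  int b_bits = std::min(24, key_bits);
  idx.bucket_shift = key_bits - b_bits;
  size_t n_buckets = (size_t)1 << b_bits;
  idx.bucket_start.assign(n_buckets + 1, 0);
  for (auto &e : idx.entries) ++idx.bucket_start[(e.first >> idx.bucket_shift) + 1];
  for (size_t b = 1; b <= n_buckets; ++b)
    idx.bucket_start[b] += idx.bucket_start[b - 1];
}

struct Hit { uint32_t tpos; uint32_t qpos; };

struct BestCluster {
  int covered = -1;        // query bases covered by seed matches
  uint64_t tstart = 0, tend = 0;
  int nhits = 0;
  char strand = '+';
};

// Collect hits for one query orientation and scan target-sorted clusters.
static void scan_orientation(const std::string &q, const SeedIndex &idx,
                             int max_occ, int cluster_gap, char strand,
                             std::vector<char> &covmask, BestCluster &best) {
  std::vector<uint64_t> keys;
  kmer_keys(q, idx.k, keys);
  std::vector<Hit> hits;
  for (size_t p = 0; p < keys.size(); ++p) {
    if (keys[p] == UINT64_MAX) continue;
    uint64_t key = keys[p];
    size_t b = key >> idx.bucket_shift;
    size_t lo = idx.bucket_start[b], hi = idx.bucket_start[b + 1];
    size_t first = lo, cnt = 0;
    while (first < hi && idx.entries[first].first < key) ++first;
    size_t last = first;
    while (last < hi && idx.entries[last].first == key) ++last;
    cnt = last - first;
    if (cnt == 0 || cnt > (size_t)max_occ) continue;
    for (size_t it = first; it < last; ++it)
      hits.push_back(Hit{idx.entries[it].second, (uint32_t)p});
  }
  if (hits.empty()) return;
  std::sort(hits.begin(), hits.end(),
            [](const Hit &a, const Hit &b) {
              return a.tpos < b.tpos || (a.tpos == b.tpos && a.qpos < b.qpos);
            });
  size_t qlen = q.size();
  size_t i = 0, n = hits.size();
  while (i < n) {
    size_t j = i + 1;
    while (j < n && hits[j].tpos - hits[j - 1].tpos <= (uint32_t)cluster_gap) ++j;
    std::fill(covmask.begin(), covmask.end(), 0);
    uint64_t tmin = hits[i].tpos, tmax = hits[i].tpos;
    for (size_t h = i; h < j; ++h) {
      uint32_t qp = hits[h].qpos;
      for (int b = 0; b < idx.k; ++b)
        if (qp + b < qlen) covmask[qp + b] = 1;
      tmin = std::min<uint64_t>(tmin, hits[h].tpos);
      tmax = std::max<uint64_t>(tmax, hits[h].tpos);
    }
    int covered = 0;
    for (size_t b = 0; b < qlen; ++b) covered += covmask[b];
    // tie-break: more covered wins; then lower target coordinate; '+' first
    if (covered > best.covered ||
        (covered == best.covered && tmin < best.tstart)) {
      best.covered = covered;
      best.tstart = tmin;
      best.tend = tmax + idx.k;
      best.nhits = (int)(j - i);
      best.strand = strand;
    }
    i = j;
  }
}

// [[Rcpp::export]]
DataFrame cpp_map_queries(CharacterVector queries, CharacterVector target_seqs,
                          CharacterVector target_names, int k = 15,
                          int max_occ = 64, int cluster_gap = 0,
                          bool both_strands = true) {
  std::vector<std::string> tseqs(target_seqs.size());
  for (int i = 0; i < target_seqs.size(); ++i)
    tseqs[i] = as<std::string>(target_seqs[i]);
  SeedIndex idx;
  build_index(tseqs, k, idx);

  std::vector<int> out_query;
  std::vector<int> out_chrom;
  std::vector<double> out_tstart, out_tend;
  std::vector<int> out_matches, out_nhits, out_qlen;
  std::vector<char> out_strand;

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    if ((int)q.size() < k) continue;
    int gap = cluster_gap > 0 ? cluster_gap : (int)q.size() + 200;
    std::vector<char> covmask(q.size());
    BestCluster best;
    scan_orientation(q, idx, max_occ, gap, '+', covmask, best);
    if (both_strands) {
      std::string qr = q;
      revcomp(qr);
      scan_orientation(qr, idx, max_occ, gap, '-', covmask, best);
    }
    if (best.covered <= 0) continue;
    // cluster must stay on one chromosome; locate by start
    size_t ci = (size_t)(std::upper_bound(idx.offsets.begin(),
                                          idx.offsets.end(), best.tstart) -
                         idx.offsets.begin()) - 1;
    uint64_t off = idx.offsets[ci];
    uint64_t chrom_end = (ci + 1 < idx.offsets.size())
                             ? idx.offsets[ci + 1]
                             : off + tseqs[ci].size();
    uint64_t tend = std::min<uint64_t>(best.tend, chrom_end);
    out_query.push_back(qi + 1);
    out_chrom.push_back((int)ci + 1);
    out_tstart.push_back((double)(best.tstart - off));
    out_tend.push_back((double)(tend - off));
    out_matches.push_back(best.covered);
    out_nhits.push_back(best.nhits);
    out_qlen.push_back((int)q.size());
    out_strand.push_back(best.strand);
  }

  CharacterVector chrom(out_chrom.size()), strand(out_strand.size());
  for (size_t i = 0; i < out_chrom.size(); ++i) {
    chrom[i] = target_names[out_chrom[i] - 1];
    strand[i] = std::string(1, out_strand[i]);
  }
  return DataFrame::create(
      _["query"] = wrap(out_query), _["tchrom"] = chrom,
      _["tstart"] = wrap(out_tstart), _["tend"] = wrap(out_tend),
      _["strand"] = strand, _["matches"] = wrap(out_matches),
      _["qlen"] = wrap(out_qlen), _["n_seeds"] = wrap(out_nhits),
      _["stringsAsFactors"] = false);
}
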