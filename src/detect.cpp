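// Word-hash IBD detection on phased haplotypes.
//
// The marker axis is partitioned into consecutive words of `bits` markers
// (a trailing short word is never a seed). Haplotype pairs sharing an
// identical full word become seed pairs; seeds are extended word-by-word
// while the per-word mismatch count stays within the error budget, the two
// boundary markers are refined to the outermost matching marker, segments
// of the same pair separated by at most one word are merged, and segments
// of genetic length >= min_m cM are reported.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

namespace {
inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

inline bool getbit(const std::vector<uint64_t> &row, int s) {
  return (row[s >> 6] >> (s & 63)) & 1ULL;
}
}  // namespace

// [[Rcpp::export]]
DataFrame detect_ibd_cpp(IntegerMatrix H, NumericVector cm, int bits,
                         int err_het, double min_m) {
  const int nh = H.nrow(), m = H.ncol();
  const int nblk = (m + 63) / 64;
  std::vector<std::vector<uint64_t>> packed(nh, std::vector<uint64_t>(nblk, 0));
  for (int h = 0; h < nh; ++h)
    for (int s = 0; s < m; ++s)
      if (H(h, s)) packed[h][s >> 6] |= 1ULL << (s & 63);

  const int W = m / bits;             // full (seedable) words
  const bool tail = (m % bits) != 0;  // trailing short word, extension only
  const int WT = W + (tail ? 1 : 0);
  if (W < 1) stop("fewer markers than one word; reduce 'bits'");

  // word keys (bits <= 64 markers packed into a uint64)
  auto word_key = [&](int h, int w) {
    uint64_t key = 0;
    for (int s = w * bits; s < (w + 1) * bits; ++s)
      key = (key << 1) | (uint64_t)getbit(packed[h], s);
    return key;
  };

  // candidate pairs: identical full word somewhere
  std::unordered_set<uint64_t> cand;
  {
    std::unordered_map<uint64_t, std::vector<int>> groups;
    for (int w = 0; w < W; ++w) {
      groups.clear();
      for (int h = 0; h < nh; ++h) groups[word_key(h, w)].push_back(h);
      for (auto &kv : groups) {
        const std::vector<int> &g = kv.second;
        if (g.size() < 2) continue;
        for (size_t a = 0; a < g.size(); ++a)
          for (size_t b = a + 1; b < g.size(); ++b)
            cand.insert((uint64_t)g[a] * nh + g[b]);
      }
    }
  }
  std::vector<uint64_t> pairs(cand.begin(), cand.end());
  std::sort(pairs.begin(), pairs.end());

  std::vector<int> oi, oj, o_s, o_e, o_mm;
  std::vector<int> wmm(WT), mmpos;
  std::vector<uint64_t> x(nblk);
  for (uint64_t pk : pairs) {
    int i = (int)(pk / nh), j = (int)(pk % nh);
    for (int b = 0; b < nblk; ++b) x[b] = packed[i][b] ^ packed[j][b];
    mmpos.clear();
    for (int b = 0; b < nblk; ++b) {
      uint64_t v = x[b];
      while (v) {
        int s = b * 64 + __builtin_ctzll(v);
        if (s < m) mmpos.push_back(s);
        v &= v - 1;
      }
    }
    std::fill(wmm.begin(), wmm.end(), 0);
    for (int s : mmpos) wmm[std::min(s / bits, WT - 1)]++;
    // maximal runs of words within budget that contain a seed (mm == 0 full word)
    struct Run { int w0, w1; };
    std::vector<Run> runs;
    int w = 0;
    while (w < WT) {
      if (wmm[w] > err_het) { ++w; continue; }
      int w0 = w;
      bool seeded = false;
      while (w < WT && wmm[w] <= err_het) {
        if (w < W && wmm[w] == 0) seeded = true;
        ++w;
      }
      if (seeded) runs.push_back({w0, w - 1});
    }
    // runs are maximal and disjoint by construction, so no same-pair
    // merging is needed: bridging a word that exceeds the mismatch
    // budget would violate the budget (and break exactness at err = 0)
    auto mism = [&](int s) { return getbit(x, s); };
    for (const Run &r : runs) {
      int s0 = r.w0 * bits;
      int s1 = (r.w1 >= W) ? m - 1 : (r.w1 + 1) * bits - 1;
      // shrink ends to the outermost matching marker...
      while (s0 <= s1 && mism(s0)) ++s0;
      while (s1 >= s0 && mism(s1)) --s1;
      if (s0 > s1) continue;
      // ...then extend across matching markers into the flanking words
      while (s0 > 0 && !mism(s0 - 1)) --s0;
      while (s1 < m - 1 && !mism(s1 + 1)) ++s1;
      double len = cm[s1] - cm[s0];
      if (len < min_m) continue;
      int nmm = 0;
      for (int s : mmpos)
        if (s >= s0 && s <= s1) ++nmm;
      oi.push_back(i); oj.push_back(j);
      o_s.push_back(s0); o_e.push_back(s1); o_mm.push_back(nmm);
    }
  }
  return DataFrame::create(_["hap_i"] = oi, _["hap_j"] = oj,
                           _["site_start"] = o_s, _["site_end"] = o_e,
                           _["n_mismatch"] = o_mm);
}
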