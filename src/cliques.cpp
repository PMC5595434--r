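// Window-based connected-component clustering of IBD segments.
//
// Non-overlapping windows of window_cm are anchored at cM 0; a segment
// joins a window only if it covers it fully, so any two haplotypes in one
// component overlap by at least window_cm. Components of >= min_size
// haplotypes become cliques; identical components in adjacent windows are
// merged (interval = union of windows, member-tract intersection
// accumulated).

#include <Rcpp.h>
#include <map>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {
struct Open {
  double cm_lo, cm_hi, tract_lo, tract_hi;
  int last_w;
};

int uf_find(std::vector<int> &par, int x) {
  while (par[x] != x) {
    par[x] = par[par[x]];
    x = par[x];
  }
  return x;
}
}  // namespace

// [[Rcpp::export]]
List cluster_cliques_cpp(IntegerVector h1, IntegerVector h2,
                         NumericVector cs, NumericVector ce,
                         double window_cm, int min_size) {
  const int ns = h1.size();
  double cmax = 0;
  for (int i = 0; i < ns; ++i) cmax = std::max(cmax, ce[i]);
  const int wmax = (int)std::floor(cmax / window_cm);

  // bucket segment indices by fully-covered windows
  std::vector<std::vector<int>> bywin(wmax + 1);
  for (int i = 0; i < ns; ++i) {
    int w0 = (int)std::ceil(cs[i] / window_cm - 1e-9);
    int w1 = (int)std::floor(ce[i] / window_cm + 1e-9) - 1;
    for (int w = std::max(w0, 0); w <= std::min(w1, wmax); ++w)
      bywin[w].push_back(i);
  }

  std::map<std::vector<int>, Open> open;
  std::vector<double> out_lo, out_hi, out_tlo, out_thi;
  std::vector<std::vector<int>> out_members;

  auto emit = [&](const std::vector<int> &key, const Open &o) {
    out_lo.push_back(o.cm_lo);
    out_hi.push_back(o.cm_hi);
    out_tlo.push_back(o.tract_lo);
    out_thi.push_back(o.tract_hi);
    out_members.push_back(key);
  };

  for (int w = 0; w <= wmax; ++w) {
    std::map<std::vector<int>, Open> curm;
    const std::vector<int> &idx = bywin[w];
    if (!idx.empty()) {
      // local union-find over the haplotypes present
      std::unordered_map<int, int> local;
      std::vector<int> haps;
      for (int i : idx) {
        for (int h : {h1[i], h2[i]}) {
          if (!local.count(h)) {
            local[h] = (int)haps.size();
            haps.push_back(h);
          }
        }
      }
      std::vector<int> par(haps.size());
      for (size_t k = 0; k < par.size(); ++k) par[k] = (int)k;
      for (int i : idx) {
        int a = uf_find(par, local[h1[i]]), b = uf_find(par, local[h2[i]]);
        if (a != b) par[a] = b;
      }
      std::unordered_map<int, std::vector<int>> comps;
      for (size_t k = 0; k < haps.size(); ++k)
        comps[uf_find(par, (int)k)].push_back(haps[k]);
      std::unordered_map<int, std::pair<double, double>> tract;
      for (int i : idx) {
        int r = uf_find(par, local[h1[i]]);
        auto it = tract.find(r);
        if (it == tract.end())
          tract[r] = {cs[i], ce[i]};
        else {
          it->second.first = std::max(it->second.first, cs[i]);
          it->second.second = std::min(it->second.second, ce[i]);
        }
      }
      double lo = w * window_cm, hi = lo + window_cm;
      for (auto &kv : comps) {
        if ((int)kv.second.size() < min_size) continue;
        std::vector<int> key = kv.second;
        std::sort(key.begin(), key.end());
        auto tr = tract[kv.first];
        auto it = open.find(key);
        if (it != open.end() && it->second.last_w == w - 1) {
          Open o = it->second;
          o.last_w = w;
          o.cm_hi = hi;
          o.tract_lo = std::max(o.tract_lo, tr.first);
          o.tract_hi = std::min(o.tract_hi, tr.second);
          curm[key] = o;
          open.erase(it);
        } else {
          curm[key] = Open{lo, hi, tr.first, tr.second, w};
        }
      }
    }
    for (auto &kv : open) emit(kv.first, kv.second);
    open.swap(curm);
  }
  for (auto &kv : open) emit(kv.first, kv.second);

  const int nc = (int)out_lo.size();
  List members(nc);
  for (int i = 0; i < nc; ++i)
    members[i] = IntegerVector(out_members[i].begin(), out_members[i].end());
  return List::create(_["cm_lo"] = NumericVector(out_lo.begin(), out_lo.end()),
                      _["cm_hi"] = NumericVector(out_hi.begin(), out_hi.end()),
                      _["tract_cm_lo"] = NumericVector(out_tlo.begin(), out_tlo.end()),
                      _["tract_cm_hi"] = NumericVector(out_thi.begin(), out_thi.end()),
                      _["members"] = members);
}
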