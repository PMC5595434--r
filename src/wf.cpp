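// Forward Wright-Fisher simulation with founder-label copying.
//
// Haplotypes are mosaics of founder labels stored as flat arrays:
// for haplotype h, segments k = off[h] .. off[h+1]-1 cover
// (end[k-1], end[k]] in Morgans (end[off[h+1]-1] == genome length),
// each carrying founder label lab[k]. Exact identity-by-descent between
// two haplotypes is a maximal run where labels agree.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {

struct Pop {
  std::vector<int> off;     // size n_hap + 1
  std::vector<double> end;  // segment right ends (Morgans)
  std::vector<int> lab;     // founder labels
  int n_hap() const { return (int)off.size() - 1; }
  void clear(int reserve_seg) {
    off.assign(1, 0);
    end.clear(); lab.clear();
    end.reserve(reserve_seg); lab.reserve(reserve_seg);
  }
};

// copy a meiosis product of parent haplotypes (h0, h1) into 'out';
// 'phase0' selects the haplotype active at position 0, breakpoints are
// 'brk' (sorted, inside (0, L)).
void meiosis_walk(const Pop &P, int h0, int h1, int phase0,
                  const std::vector<double> &brk, double L, Pop &out) {
  int hap[2] = {h0, h1};
  int phase = phase0;
  double cur = 0.0;
  size_t bi = 0;
  int i[2] = {P.off[h0], P.off[h1]};
  int last_lab = -1;
  while (cur < L) {
    double stop = (bi < brk.size()) ? brk[bi] : L;
    int h = hap[phase];
    int &k = i[phase];
    // advance to the segment containing cur
    while (P.end[k] <= cur) ++k;
    while (cur < stop) {
      double segend = P.end[k] < stop ? P.end[k] : stop;
      int l = P.lab[k];
      if (l == last_lab && !out.lab.empty()) {
        out.end.back() = segend;  // extend previous run of the same label
      } else {
        out.end.push_back(segend);
        out.lab.push_back(l);
        last_lab = l;
      }
      cur = segend;
      if (P.end[k] <= cur && cur < stop) ++k;
    }
    if (bi < brk.size()) ++bi;
    phase ^= 1;
  }
  out.off.push_back((int)out.lab.size());
}

std::vector<double> draw_breaks(double L) {
  int k = (int)R::rpois(L);
  std::vector<double> b(k);
  for (int i = 0; i < k; ++i) b[i] = R::runif(0.0, L);
  std::sort(b.begin(), b.end());
  return b;
}

int label_at(const Pop &P, int h, double x) {
  int k = P.off[h];
  while (P.end[k] <= x) ++k;
  return P.lab[k];
}

}  // namespace

// [[Rcpp::export]]
List wf_simulate_cpp(NumericVector ne, int n_samples, double morgans,
                     double planted_pos, double target_freq, int n_hom,
                     double min_freq) {
  const int G = ne.size();
  Pop cur, nxt;
  // founders: generation G, one segment per haplotype, unique labels
  {
    int N = (int)ne[G - 1];
    cur.clear(2 * N);
    for (int h = 0; h < 2 * N; ++h) {
      cur.end.push_back(morgans);
      cur.lab.push_back(h);
      cur.off.push_back(h + 1);
    }
  }
  // forward through generations G-1 .. 1
  for (int g = G - 1; g >= 1; --g) {
    int N = (int)ne[g - 1];
    int Np = cur.n_hap() / 2;
    nxt.clear((int)(2.2 * N * (cur.end.size() / std::max(1, cur.n_hap()) + 2)));
    for (int ind = 0; ind < N; ++ind) {
      int p1 = (int)(R::unif_rand() * Np);
      int p2 = (int)(R::unif_rand() * Np);
      while (Np > 1 && p2 == p1) p2 = (int)(R::unif_rand() * Np);
      for (int par : {p1, p2}) {
        std::vector<double> brk = draw_breaks(morgans);
        int phase0 = R::unif_rand() < 0.5 ? 0 : 1;
        meiosis_walk(cur, 2 * par, 2 * par + 1, phase0, brk, morgans, nxt);
      }
    }
    std::swap(cur, nxt);
  }
  // choose the planted founder label from generation-1 frequencies
  // (target_freq <= 0 disables planting altogether)
  const bool plant = target_freq > 0;
  if (!plant) n_hom = 0;
  const int NH1 = cur.n_hap();
  std::unordered_map<int, int> cnt;
  std::vector<int> lab1(NH1);
  for (int h = 0; h < NH1; ++h) {
    lab1[h] = label_at(cur, h, planted_pos);
    cnt[lab1[h]]++;
  }
  int planted = -1;
  double best = R_PosInf;
  if (plant) for (auto &kv : cnt) {
    double f = (double)kv.second / NH1;
    if (n_hom > 0 && kv.second < 2) continue;
    double d = std::fabs(f - target_freq);
    if (d < best || (d == best && kv.first < planted)) {
      best = d;
      planted = kv.first;
    }
  }
  if (plant && (planted < 0 || (double)cnt[planted] / NH1 < min_freq))
    stop("planted carrier rate unreachable: no founder lineage at frequency >= %f at the planted site",
         min_freq);
  // carrier individuals in generation 1 (>= 1 haplotype with the label)
  std::vector<int> carriers;
  std::vector<int> carrier_hap;  // which hap (0/1) carries (prefer 0 if both)
  for (int ind = 0; ind < NH1 / 2; ++ind) {
    bool c0 = lab1[2 * ind] == planted, c1 = lab1[2 * ind + 1] == planted;
    if (c0 || c1) {
      carriers.push_back(ind);
      carrier_hap.push_back(c0 ? 0 : 1);
    }
  }
  if (n_hom > 0 && (int)carriers.size() < 2)
    stop("planted carrier rate unreachable: fewer than 2 carrier parents");
  // generation 0: n_samples - n_hom random children + n_hom endogamous
  // carrier-kindred children with forced transmission at the planted site
  int Np = NH1 / 2;
  nxt.clear(2 * n_samples * 30);
  for (int ind = 0; ind < n_samples - n_hom; ++ind) {
    int p1 = (int)(R::unif_rand() * Np);
    int p2 = (int)(R::unif_rand() * Np);
    while (Np > 1 && p2 == p1) p2 = (int)(R::unif_rand() * Np);
    for (int par : {p1, p2}) {
      std::vector<double> brk = draw_breaks(morgans);
      int phase0 = R::unif_rand() < 0.5 ? 0 : 1;
      meiosis_walk(cur, 2 * par, 2 * par + 1, phase0, brk, morgans, nxt);
    }
  }
  int nc = (int)carriers.size();
  for (int ind = 0; ind < n_hom; ++ind) {
    // consanguineous union: both parental lineages descend from the same
    // generation-1 carrier, so the homozygote's two haplotypes are meioses
    // of one carrier individual and share a long tract around the planted
    // site (founder-kindred homozygotes in the real world share a
    // multi-centimorgan boundary, not just the eroded founder-label run)
    int ci = (int)(R::unif_rand() * nc);
    for (int rep = 0; rep < 2; ++rep) {
      int par = carriers[ci];
      int want = carrier_hap[ci];
      if (lab1[2 * par] == planted && lab1[2 * par + 1] == planted)
        want = R::unif_rand() < 0.5 ? 0 : 1;
      std::vector<double> brk = draw_breaks(morgans);
      // parity of crossovers left of the planted site decides which parental
      // haplotype is active there; pick the start phase that transmits the
      // carrying haplotype (an exact conditional draw, by symmetry)
      int parity = 0;
      for (double b : brk) if (b < planted_pos) parity ^= 1;
      int phase0 = want ^ parity;
      meiosis_walk(cur, 2 * par, 2 * par + 1, phase0, brk, morgans, nxt);
    }
  }
  // per-haplotype planted carrier flag
  int NH0 = nxt.n_hap();
  LogicalVector carries(NH0);
  for (int h = 0; h < NH0; ++h) carries[h] = label_at(nxt, h, planted_pos) == planted;
  return List::create(
      _["off"] = IntegerVector(nxt.off.begin(), nxt.off.end()),
      _["end"] = NumericVector(nxt.end.begin(), nxt.end.end()),
      _["lab"] = IntegerVector(nxt.lab.begin(), nxt.lab.end()),
      _["planted_label"] = planted,
      _["hap_carries"] = carries);
}

// Build the 0/1 allele matrix: founder haplotypes get independent alleles
// at frequency p[s]; every descendant copies its founder's allele.
// [[Rcpp::export]]
IntegerMatrix build_alleles_cpp(IntegerVector off, NumericVector end,
                                IntegerVector lab, NumericVector site_pos,
                                NumericVector p) {
  const int nh = off.size() - 1, m = site_pos.size();
  std::unordered_map<int, int> row;
  for (int k = 0; k < lab.size(); ++k)
    if (!row.count(lab[k])) row[lab[k]] = (int)row.size();
  const int nf = (int)row.size();
  std::vector<char> F((size_t)nf * m);
  // deterministic order over labels for reproducibility
  std::vector<int> labs(nf);
  for (auto &kv : row) labs[kv.second] = kv.first;
  std::vector<int> ord(nf);
  for (int i = 0; i < nf; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return labs[a] < labs[b]; });
  for (int oi = 0; oi < nf; ++oi) {
    int r = ord[oi];
    for (int s = 0; s < m; ++s)
      F[(size_t)r * m + s] = R::unif_rand() < p[s] ? 1 : 0;
  }
  IntegerMatrix H(nh, m);
  for (int h = 0; h < nh; ++h) {
    int s = 0;
    for (int k = off[h]; k < off[h + 1] && s < m; ++k) {
      int r = row[lab[k]];
      double e = end[k];
      while (s < m && site_pos[s] < e) {
        H(h, s) = F[(size_t)r * m + s];
        ++s;
      }
    }
  }
  return H;
}

// All-pairs maximal same-label runs >= floor Morgans.
// [[Rcpp::export]]
DataFrame true_segments_cpp(IntegerVector off, NumericVector end,
                            IntegerVector lab, double floor_m) {
  const int nh = off.size() - 1;
  std::vector<int> oi, oj;
  std::vector<double> os, oe;
  for (int i = 0; i < nh; ++i) {
    for (int j = i + 1; j < nh; ++j) {
      int a = off[i], b = off[j];
      double cur = 0.0, run_start = -1.0;
      while (a < off[i + 1] && b < off[j + 1]) {
        bool same = lab[a] == lab[b];
        double stop = std::min(end[a], end[b]);
        if (same && run_start < 0) run_start = cur;
        if (!same && run_start >= 0) {
          if (cur - run_start >= floor_m) {
            oi.push_back(i); oj.push_back(j);
            os.push_back(run_start); oe.push_back(cur);
          }
          run_start = -1.0;
        }
        cur = stop;
        if (end[a] <= cur) ++a;
        if (end[b] <= cur) ++b;
      }
      if (run_start >= 0 && cur - run_start >= floor_m) {
        oi.push_back(i); oj.push_back(j);
        os.push_back(run_start); oe.push_back(cur);
      }
    }
  }
  return DataFrame::create(_["hap_i"] = oi, _["hap_j"] = oj,
                           _["start_m"] = os, _["end_m"] = oe);
}
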