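// Post-inference refinements of the reconstructed cover:
//  - segment-wise copy relabelling (conjugation by products of copy
//    transpositions over contiguous quotient families), and
//  - a hill-climb over family-level DCJ moves applied symmetrically to all
//    r copies.
// Both accept strict labelled-distance improvements only, so they
// terminate; both preserve the r-fold cover structure.

#include <Rcpp.h>
#include <vector>
#include <numeric>
using namespace Rcpp;

namespace {

// DCJ distance between two uncapped partner vectors (1-based ids, 0 =
// telomere): N/2 - cycles - oddPaths/2 over the union components.
struct DistScratch {
  std::vector<char> vis;
  std::vector<int> stack;
};

int dcjDist(const std::vector<int>& pa, const std::vector<int>& pb,
            DistScratch& s) {
  int n = (int)pa.size() - 1;   // index 0 unused
  s.vis.assign(n + 1, 0);
  int cycles = 0, odd = 0;
  for (int v = 1; v <= n; ++v) {
    if (s.vis[v]) continue;
    s.stack.clear();
    s.stack.push_back(v);
    s.vis[v] = 1;
    int cnt = 0;
    bool telo = false;
    while (!s.stack.empty()) {
      int x = s.stack.back();
      s.stack.pop_back();
      ++cnt;
      int a = pa[x], b = pb[x];
      if (a == 0 || b == 0) telo = true;
      if (a && !s.vis[a]) { s.vis[a] = 1; s.stack.push_back(a); }
      if (b && !s.vis[b]) { s.vis[b] = 1; s.stack.push_back(b); }
    }
    if (!telo) ++cycles;
    else if (cnt % 2 == 1) ++odd;
  }
  return n / 2 - cycles - odd / 2;
}

inline int extOf(int fe, int c, int r) {
  int fam = (fe + 1) / 2;
  int t = 2 - (fe & 1);          // odd fe = tail
  return ((fam - 1) * r + c - 1) * 2 + t;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector refine_copy_labels_cpp(IntegerVector pObs0, IntegerVector pH0,
                                     int r, List walks) {
  int N = pObs0.size();
  std::vector<int> pObs(N + 1), pH(N + 1);
  for (int i = 0; i < N; ++i) { pObs[i + 1] = pObs0[i]; pH[i + 1] = pH0[i]; }
  DistScratch scr;
  int D = dcjDist(pObs, pH, scr);
  std::vector<int> m(N + 1), cand(N + 1);
  bool improved = true;
  int guard = 0;
  while (improved) {
    if (++guard > 2000) break;
    improved = false;
    for (int w = 0; w < walks.size() && !improved; ++w) {
      List wk = walks[w];
      IntegerVector fams = wk["fams"];
      bool circ = as<bool>(wk["circular"]);
      int L = fams.size();
      if (L < 1) continue;
      for (int ci = 1; ci <= r - 1 && !improved; ++ci)
        for (int cj = ci + 1; cj <= r && !improved; ++cj)
          for (int i = 1; i <= L && !improved; ++i) {
            int maxLen = circ ? L - 1 : L - i + 1;
            std::iota(m.begin(), m.end(), 0);
            for (int len = 1; len <= maxLen; ++len) {
              int g = fams[(i + len - 2) % L];
              for (int fe = 2 * g - 1; fe <= 2 * g; ++fe) {
                int a = extOf(fe, ci, r), b = extOf(fe, cj, r);
                std::swap(m[a], m[b]);
              }
              if (!circ && len == L) continue;   // whole chromosome: no-op
              for (int x = 1; x <= N; ++x) {
                int p = pH[m[x]];
                cand[x] = p == 0 ? 0 : m[p];
              }
              int D2 = dcjDist(pObs, cand, scr);
              if (D2 < D) {
                pH = cand;
                D = D2;
                improved = true;
                break;
              }
            }
          }
    }
  }
  IntegerVector out(N);
  for (int i = 0; i < N; ++i) out[i] = pH[i + 1];
  return out;
}

namespace {

// family-level partner map implied by pH (copy 1 representative)
std::vector<int> famPartner(const std::vector<int>& pH, int r, int n) {
  std::vector<int> qp(2 * n + 1, 0);
  for (int fe = 1; fe <= 2 * n; ++fe) {
    int p = pH[extOf(fe, 1, r)];
    qp[fe] = p == 0 ? 0 : ((p - 1) / 2) / r * 2 + 2 - (p & 1);
  }
  return qp;
}

inline int cofe(int fe) { return fe % 2 == 1 ? fe + 1 : fe - 1; }

// does the component of any listed family extremity close into a cycle?
bool circularAfter(const std::vector<int>& cand, int r, int n,
                   const std::vector<int>& fes) {
  for (size_t k = 0; k < fes.size(); ++k) {
    int s = fes[k];
    if (s <= 0) continue;
    int cur = s;
    int guard = 0;
    for (;;) {
      if (++guard > 4 * n + 8) return true;   // defensive
      int p = cand[extOf(cur, 1, r)];
      if (p == 0) break;
      int nfe = ((p - 1) / 2) / r * 2 + 2 - (p & 1);
      cur = cofe(nfe);
      if (cur == s) return true;
    }
  }
  return false;
}

void applySymDcj(std::vector<int>& cand, int r, int fa, int fb, int fc,
                 int fd, int type, const std::vector<int>& pH) {
  for (int c = 1; c <= r; ++c) {
    int a = extOf(fa, c, r);
    int b = fb == 0 ? 0 : pH[a];
    int c_ = extOf(fc, c, r);
    int d = fd == 0 ? 0 : pH[c_];
    int j1a, j1b, j2a, j2b;
    if (type == 0) { j1a = a; j1b = c_; j2a = b; j2b = d; }
    else           { j1a = a; j1b = d;  j2a = b; j2b = c_; }
    if (j1a > 0 && j1b > 0) { cand[j1a] = j1b; cand[j1b] = j1a; }
    else if (j1a > 0) cand[j1a] = 0;
    else if (j1b > 0) cand[j1b] = 0;
    if (j2a > 0 && j2b > 0) { cand[j2a] = j2b; cand[j2b] = j2a; }
    else if (j2a > 0) cand[j2a] = 0;
    else if (j2b > 0) cand[j2b] = 0;
  }
}

}  // namespace

// Hill-climb over family-level DCJ moves (rejoin two adjacencies, rejoin an
// adjacency with a telomere, fuse two telomeres, or cut one adjacency),
// applied to all r copies at once; candidates creating circular chromosomes
// are rejected.
// [[Rcpp::export]]
IntegerVector local_search_quotient_cpp(IntegerVector pObs0, IntegerVector pH0,
                                        int r) {
  int N = pObs0.size();
  int n = N / (2 * r);
  std::vector<int> pObs(N + 1), pH(N + 1);
  for (int i = 0; i < N; ++i) { pObs[i + 1] = pObs0[i]; pH[i + 1] = pH0[i]; }
  DistScratch scr;
  int D = dcjDist(pObs, pH, scr);
  std::vector<int> cand(N + 1);
  bool improved = true;
  int guard = 0;
  while (improved) {
    if (++guard > 2000) break;
    improved = false;
    std::vector<int> qp = famPartner(pH, r, n);
    // adjacency slots: (fa, fb) with fa < fb, plus telomeres (fa, 0)
    std::vector<std::pair<int, int> > adj;
    for (int fe = 1; fe <= 2 * n; ++fe) {
      if (qp[fe] == 0) adj.push_back(std::make_pair(fe, 0));
      else if (qp[fe] > fe) adj.push_back(std::make_pair(fe, qp[fe]));
    }
    int nA = (int)adj.size();
    for (int i = 0; i < nA && !improved; ++i) {
      int fa = adj[i].first, fb = adj[i].second;
      if (fb != 0) {
        // cut the adjacency into two telomeres (never circularises)
        cand = pH;
        for (int c = 1; c <= r; ++c) {
          int a = extOf(fa, c, r);
          int b = pH[a];
          cand[a] = 0;
          if (b > 0) cand[b] = 0;
        }
        int D2 = dcjDist(pObs, cand, scr);
        if (D2 < D) { pH = cand; D = D2; improved = true; break; }
      }
      for (int j = i + 1; j < nA && !improved; ++j) {
        int fc = adj[j].first, fd = adj[j].second;
        int nTypes = (fb == 0 && fd == 0) ? 1 : 2;
        for (int type = 0; type < nTypes; ++type) {
          cand = pH;
          applySymDcj(cand, r, fa, fb, fc, fd, type, pH);
          int D2 = dcjDist(pObs, cand, scr);
          if (D2 < D) {
            std::vector<int> fes;
            fes.push_back(fa); fes.push_back(fb);
            fes.push_back(fc); fes.push_back(fd);
            if (!circularAfter(cand, r, n, fes)) {
              pH = cand; D = D2; improved = true; break;
            }
          }
        }
      }
    }
  }
  IntegerVector out(N);
  for (int i = 0; i < N; ++i) out[i] = pH[i + 1];
  return out;
}
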