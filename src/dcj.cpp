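#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Component census of the union of two extremity matchings.  pa/pb are
// 1-based partner vectors over the same extremity set; 0 marks a telomere.
// Components are paths or cycles (every node has at most one partner per
// genome).  A component with no telomere is an alternating cycle; an open
// component with j extremities corresponds to an adjacency-graph path with
// j edges, odd when j is odd.
// [[Rcpp::export]]
IntegerVector dcj_component_counts(IntegerVector pa, IntegerVector pb) {
  int n = pa.size();
  if (pb.size() != n) stop("partner vectors differ in length");
  std::vector<char> vis(n + 1, 0);
  std::vector<int> stack;
  int cycles = 0, odd = 0;
  for (int s = 1; s <= n; ++s) {
    if (vis[s]) continue;
    stack.clear();
    stack.push_back(s);
    vis[s] = 1;
    int cnt = 0;
    bool telo = false;
    while (!stack.empty()) {
      int x = stack.back();
      stack.pop_back();
      ++cnt;
      int a = pa[x - 1], b = pb[x - 1];
      if (a == 0 || b == 0) telo = true;
      if (a != 0 && !vis[a]) { vis[a] = 1; stack.push_back(a); }
      if (b != 0 && !vis[b]) { vis[b] = 1; stack.push_back(b); }
    }
    if (!telo) ++cycles;
    else if (cnt % 2 == 1) ++odd;
  }
  return IntegerVector::create(cycles, odd);
}

// ---- capped-representation helpers for the simulator ---------------------
//
// Extremities 1..nNonCap are gene extremities (tail odd, head even, the two
// extremities of one gene adjacent); ids above nNonCap are cap instances.
// partner[] pairs every extremity with its adjacency partner (cap-cap pairs
// encode null chromosomes).

static bool all_linear(const std::vector<int>& p, int nNonCap) {
  int M = (int)p.size();
  std::vector<char> vis(M + 1, 0);
  for (int c = nNonCap + 1; c <= M; ++c) {
    if (vis[c]) continue;
    vis[c] = 1;
    int e = p[c - 1];
    while (e > 0 && e <= nNonCap) {
      vis[e] = 1;
      int ce = (e % 2 == 1) ? e + 1 : e - 1;
      vis[ce] = 1;
      e = p[ce - 1];
    }
    if (e > 0) vis[e] = 1;
  }
  for (int e = 1; e <= nNonCap; ++e)
    if (!vis[e]) return false;
  return true;
}

// Apply k random DCJ operations: two distinct adjacencies chosen uniformly,
// one of the two rejoinings chosen uniformly; candidates that would create
// a circular chromosome are rejected and redrawn.  Uses R's RNG stream.
// [[Rcpp::export]]
IntegerVector random_dcj_ops(IntegerVector partner0, int nNonCap, int k) {
  std::vector<int> p(partner0.begin(), partner0.end());
  int M = (int)p.size();
  std::vector<std::pair<int, int> > adj;
  for (int e = 1; e <= M; ++e) {
    int q = p[e - 1];
    if (q > e) adj.push_back(std::make_pair(e, q));
  }
  int nA = (int)adj.size();
  if (k > 0 && nA < 2) stop("genome too small to pick two adjacencies");
  for (int op = 0; op < k; ++op) {
    int guard = 0;
    for (;;) {
      if (++guard > 200000) stop("no linear-preserving DCJ candidate found");
      int i = (int)(unif_rand() * nA); if (i >= nA) i = nA - 1;
      int j = (int)(unif_rand() * nA); if (j >= nA) j = nA - 1;
      if (i == j) continue;
      int a = adj[i].first, b = adj[i].second;
      int c = adj[j].first, d = adj[j].second;
      bool alt = unif_rand() < 0.5;
      int x1, y1, x2, y2;
      if (!alt) { x1 = a; y1 = c; x2 = b; y2 = d; }
      else      { x1 = a; y1 = d; x2 = b; y2 = c; }
      p[x1 - 1] = y1; p[y1 - 1] = x1;
      p[x2 - 1] = y2; p[y2 - 1] = x2;
      if (all_linear(p, nNonCap)) {
        adj[i] = std::make_pair(std::min(x1, y1), std::max(x1, y1));
        adj[j] = std::make_pair(std::min(x2, y2), std::max(x2, y2));
        break;
      }
      p[a - 1] = b; p[b - 1] = a;   // revert and redraw
      p[c - 1] = d; p[d - 1] = c;
    }
  }
  return IntegerVector(p.begin(), p.end());
}

// Rebuild chromosomes from a capped partner vector.  Returns signed gene
// slots per chromosome (slot s = (ext+1)/2; positive when entered by the
// tail) plus circular flags.  Null (cap-cap) chromosomes are dropped;
// remaining extremities form circular chromosomes, started at their
// smallest extremity.
// [[Rcpp::export]]
List walk_chromosomes(IntegerVector partner, int nNonCap) {
  std::vector<int> p(partner.begin(), partner.end());
  int M = (int)p.size();
  std::vector<char> vis(M + 1, 0);
  std::vector<SEXP> chroms;
  std::vector<int> circ;
  for (int c = nNonCap + 1; c <= M; ++c) {
    if (vis[c]) continue;
    vis[c] = 1;
    std::vector<int> genes;
    int e = p[c - 1];
    while (e > 0 && e <= nNonCap) {
      int slot = (e + 1) / 2;
      genes.push_back(e % 2 == 1 ? slot : -slot);
      vis[e] = 1;
      int ce = (e % 2 == 1) ? e + 1 : e - 1;
      vis[ce] = 1;
      e = p[ce - 1];
    }
    if (e > 0) vis[e] = 1;
    if (!genes.empty()) {
      chroms.push_back(IntegerVector(genes.begin(), genes.end()));
      circ.push_back(0);
    }
  }
  for (int s = 1; s <= nNonCap; ++s) {
    if (vis[s]) continue;
    std::vector<int> genes;
    int e = s;
    do {
      int slot = (e + 1) / 2;
      genes.push_back(e % 2 == 1 ? slot : -slot);
      vis[e] = 1;
      int ce = (e % 2 == 1) ? e + 1 : e - 1;
      vis[ce] = 1;
      e = p[ce - 1];
    } while (e != s);
    chroms.push_back(IntegerVector(genes.begin(), genes.end()));
    circ.push_back(1);
  }
  List out(chroms.size());
  for (int i = 0; i < (int)chroms.size(); ++i) out[i] = chroms[i];
  return List::create(_["genes"] = out,
                      _["circular"] = LogicalVector(circ.begin(), circ.end()));
}
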