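// Disjoint path engine for the contracted partial graph.
//
// find_path(u, v) must return an edge-path set from u to v such that
//  (1) every path starts and ends with black edges,
//  (2) paths alternate edge colours at matched interior vertices,
//  (3) total use of an edge never exceeds its multiplicity,
//  (4) every unmatched vertex is interior to at most one path, at most once,
// maximising the number of paths (capped) and then minimising total length.
//
// This is solved as unit-augmenting min-cost flow on a transformed network:
// unmatched vertices are split (capacity 1), matched vertices expand into a
// black-in/gray-out node and a gray-in/black-out node, every edge costs 1.
// Successive shortest-path augmentation yields, for each flow value, the
// minimum-cost flow, i.e. the (max count, then min total length) objective.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

namespace {

struct Net {
  int n;
  std::vector<int> to, cap, cost, tag;
  std::vector<std::vector<int> > adj;
  explicit Net(int n_) : n(n_), adj(n_) {}
  void addArc(int u, int v, int c, int w, int tg) {
    adj[u].push_back((int)to.size());
    to.push_back(v); cap.push_back(c); cost.push_back(w); tag.push_back(tg);
    adj[v].push_back((int)to.size());
    to.push_back(u); cap.push_back(0); cost.push_back(-w); tag.push_back(0);
  }
};

const long long INF = std::numeric_limits<long long>::max() / 4;

// one unit of flow along a shortest path (Dijkstra with potentials,
// terminated as soon as the sink settles; potentials of unsettled nodes
// are advanced by dist[t], which keeps all reduced costs non-negative);
// returns false when t is unreachable
bool augment(Net& net, std::vector<long long>& pot, int s, int t) {
  int n = net.n;
  std::vector<long long> dist(n, INF);
  std::vector<int> prevArc(n, -1);
  std::vector<char> settled(n, 0);
  typedef std::pair<long long, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[s] = 0;
  pq.push(QE(0, s));
  bool reached = false;
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    long long d = top.first; int u = top.second;
    if (d > dist[u]) continue;
    settled[u] = 1;
    if (u == t) { reached = true; break; }
    for (size_t k = 0; k < net.adj[u].size(); ++k) {
      int a = net.adj[u][k];
      if (net.cap[a] <= 0) continue;
      int w = net.to[a];
      long long nd = d + net.cost[a] + pot[u] - pot[w];
      if (nd < dist[w]) {
        dist[w] = nd;
        prevArc[w] = a;
        pq.push(QE(nd, w));
      }
    }
  }
  if (!reached) return false;
  long long dt = dist[t];
  for (int i = 0; i < n; ++i)
    pot[i] += settled[i] ? dist[i] : dt;
  for (int x = t; x != s;) {
    int a = prevArc[x];
    net.cap[a] -= 1;
    net.cap[a ^ 1] += 1;
    x = net.to[a ^ 1];
  }
  return true;
}

// Build the transformed network.  Vertices are 0..V-1 (family-extremity
// vertices, already compacted); node 2w = in/black-in side, 2w+1 =
// out/black-out side, node 2V = super source.  matched[w] switches w to the
// colour-alternating expansion.  edges: columns x, y, color (0 black /
// 1 gray), mult.  Self-loops are skipped: a gray self-loop never exists and
// a black self-loop can neither advance toward v nor alternate colours.
Net buildNet(const IntegerMatrix& edges, const LogicalVector& matched,
             int u, int v, int maxPaths) {
  int V = matched.size();
  Net net(2 * V + 1);
  int SS = 2 * V, S = 2 * u + 1, T = 2 * v;
  net.addArc(SS, S, maxPaths, 0, 0);
  for (int w = 0; w < V; ++w)
    if (w != u && w != v && !matched[w])
      net.addArc(2 * w, 2 * w + 1, 1, 0, 0);
  int ne = edges.nrow();
  for (int k = 0; k < ne; ++k) {
    int x = edges(k, 0), y = edges(k, 1), c = edges(k, 2), m = edges(k, 3);
    if (x == y || m <= 0) continue;
    for (int dir = 0; dir < 2; ++dir) {
      int a = dir == 0 ? x : y;
      int b = dir == 0 ? y : x;
      int tail, head;
      if (a == u)      tail = (c == 0) ? 2 * u + 1 : -1;
      else if (a == v) tail = -1;
      else if (matched[a]) tail = (c == 0) ? 2 * a + 1 : 2 * a;
      else             tail = 2 * a + 1;
      if (b == v)      head = (c == 0) ? 2 * v : -1;
      else if (b == u) head = -1;
      else if (matched[b]) head = (c == 0) ? 2 * b : 2 * b + 1;
      else             head = 2 * b;
      if (tail >= 0 && head >= 0)
        net.addArc(tail, head, m, 1, dir == 0 ? (k + 1) : -(k + 1));
    }
  }
  return net;
}

List decompose(Net& net, const std::vector<int>& cap0, int SS, int T) {
  // net forward flow on arc a (even index) = cap of its reverse arc
  std::vector<int> flow(net.to.size() / 2, 0);
  for (size_t a = 0; a < net.to.size(); a += 2)
    flow[a / 2] = net.cap[a + 1];
  (void)cap0;
  std::vector<SEXP> paths;
  for (;;) {
    // any remaining unit out of SS?
    int start = -1;
    for (size_t k = 0; k < net.adj[SS].size(); ++k) {
      int a = net.adj[SS][k];
      if (a % 2 == 0 && flow[a / 2] > 0) { start = a; break; }
    }
    if (start < 0) break;
    std::vector<int> tags;
    int cur = SS;
    int guard = 0;
    while (cur != T) {
      if (++guard > 1000000) stop("internal error: flow decomposition loop");
      int pick = -1;
      for (size_t k = 0; k < net.adj[cur].size(); ++k) {
        int a = net.adj[cur][k];
        if (a % 2 == 0 && flow[a / 2] > 0) { pick = a; break; }
      }
      if (pick < 0) stop("internal error: stranded flow");
      flow[pick / 2] -= 1;
      if (net.tag[pick] != 0) tags.push_back(net.tag[pick]);
      cur = net.to[pick];
    }
    paths.push_back(IntegerVector(tags.begin(), tags.end()));
  }
  List out(paths.size());
  for (int i = 0; i < (int)paths.size(); ++i) out[i] = paths[i];
  return out;
}

List solvePaths(const IntegerMatrix& edges, const LogicalVector& matched,
                int u, int v, int maxPaths) {
  int V = matched.size();
  Net net = buildNet(edges, matched, u, v, maxPaths);
  std::vector<int> cap0(net.cap);
  std::vector<long long> pot(net.n, 0);
  int SS = 2 * V, T = 2 * v;
  int flow = 0;
  while (flow < maxPaths && augment(net, pot, SS, T)) ++flow;
  return decompose(net, cap0, SS, T);
}

}  // namespace

// Paths as signed 1-based indices into the edge table (+k: traversed from
// column x to y; -k: the reverse).
// [[Rcpp::export]]
List find_path_tags(IntegerMatrix edges, LogicalVector matched,
                    int u, int v, int maxPaths) {
  if (u == v) stop("u and v must differ");
  if (u < 0 || v < 0 || u >= matched.size() || v >= matched.size())
    stop("vertex absent from graph");
  return solvePaths(edges, matched, u, v, maxPaths);
}

// Batch scorer for weak-adjacency candidates: per pair the path count N_p,
// S = sum over paths of floor((L_i + 1) / 2), and L = total length.
// [[Rcpp::export]]
IntegerMatrix score_pair_stats(IntegerMatrix edges, LogicalVector matched,
                               IntegerMatrix pairs, int maxPaths) {
  int np = pairs.nrow();
  IntegerMatrix out(np, 3);
  for (int i = 0; i < np; ++i) {
    List paths = solvePaths(edges, matched, pairs(i, 0), pairs(i, 1), maxPaths);
    int N = paths.size(), S = 0, L = 0;
    for (int j = 0; j < N; ++j) {
      int len = Rf_length(paths[j]);
      S += (len + 1) / 2;
      L += len;
    }
    out(i, 0) = N; out(i, 1) = S; out(i, 2) = L;
  }
  return out;
}
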