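// Degree-preserving null ensemble for small binary graphs.
//
// Repeated double-edge swaps with rejection of self-loops and
// multi-edges preserve every node's degree exactly; disconnected draws
// are redrawn up to a retry cap so characteristic path length stays
// finite. For each null the mean binary clustering coefficient
// (degree < 2 scoring 0) and the mean shortest path over connected
// ordered pairs are returned. Uses R's RNG, so results are reproducible
// under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

typedef std::vector<std::vector<int> > AdjBool;

// BFS distances from src; dist = -1 when unreachable
void bfs(const AdjBool &a, int src, std::vector<int> &dist) {
  int n = a.size();
  dist.assign(n, -1);
  std::vector<int> queue;
  queue.reserve(n);
  queue.push_back(src);
  dist[src] = 0;
  for (size_t qi = 0; qi < queue.size(); ++qi) {
    int u = queue[qi];
    for (int v = 0; v < n; ++v) {
      if (a[u][v] && dist[v] < 0) {
        dist[v] = dist[u] + 1;
        queue.push_back(v);
      }
    }
  }
}

bool connected(const AdjBool &a) {
  std::vector<int> dist;
  bfs(a, 0, dist);
  for (size_t i = 0; i < dist.size(); ++i)
    if (dist[i] < 0) return false;
  return true;
}

// mean local clustering (deg < 2 scores 0) and mean shortest path over
// connected ordered pairs
void clusteringPathLength(const AdjBool &a, double &cOut, double &lOut) {
  int n = a.size();
  double cSum = 0.0;
  for (int i = 0; i < n; ++i) {
    std::vector<int> nb;
    for (int j = 0; j < n; ++j)
      if (a[i][j]) nb.push_back(j);
    int k = nb.size();
    if (k < 2) continue;
    int tri = 0;
    for (int u = 0; u < k; ++u)
      for (int v = u + 1; v < k; ++v)
        if (a[nb[u]][nb[v]]) ++tri;
    cSum += 2.0 * tri / (static_cast<double>(k) * (k - 1));
  }
  cOut = cSum / n;
  double dSum = 0.0;
  long cnt = 0;
  std::vector<int> dist;
  for (int i = 0; i < n; ++i) {
    bfs(a, i, dist);
    for (int j = 0; j < n; ++j) {
      if (j != i && dist[j] > 0) {
        dSum += dist[j];
        ++cnt;
      }
    }
  }
  lOut = cnt ? dSum / cnt : R_PosInf;
}

int randInt(int m) { // uniform on 0..m-1 via R's RNG
  int k = static_cast<int>(unif_rand() * m);
  return k >= m ? m - 1 : k;
}

} // namespace

// [[Rcpp::export(name = ".cppGraphMetrics")]]
List cppGraphMetrics(IntegerMatrix adj) {
  int n = adj.nrow();
  AdjBool a(n, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      a[i][j] = adj(i, j) != 0 ? 1 : 0;

  NumericVector ne(n);
  double invSum = 0.0;
  std::vector<int> dist;
  for (int i = 0; i < n; ++i) {
    bfs(a, i, dist);
    double rowInv = 0.0;
    for (int j = 0; j < n; ++j)
      if (j != i && dist[j] > 0) rowInv += 1.0 / dist[j];
    ne[i] = n > 1 ? rowInv / (n - 1) : 0.0;
    invSum += rowInv;
  }
  double eg = n > 1 ? invSum / (static_cast<double>(n) * (n - 1)) : 0.0;

  double elocSum = 0.0;
  for (int i = 0; i < n; ++i) {
    std::vector<int> nb;
    for (int j = 0; j < n; ++j)
      if (a[i][j]) nb.push_back(j);
    int k = nb.size();
    if (k < 2) continue;
    AdjBool sub(k, std::vector<int>(k, 0));
    for (int u = 0; u < k; ++u)
      for (int v = 0; v < k; ++v)
        sub[u][v] = a[nb[u]][nb[v]];
    double subInv = 0.0;
    std::vector<int> sdist;
    for (int u = 0; u < k; ++u) {
      bfs(sub, u, sdist);
      for (int v = 0; v < k; ++v)
        if (v != u && sdist[v] > 0) subInv += 1.0 / sdist[v];
    }
    elocSum += subInv / (static_cast<double>(k) * (k - 1));
  }

  double c, l;
  clusteringPathLength(a, c, l);
  return List::create(
    _["eg"] = eg, _["eloc"] = elocSum / n, _["ne"] = ne,
    _["c"] = c, _["l"] = l
  );
}

// [[Rcpp::export(name = ".cppNullEnsembleCL")]]
NumericMatrix cppNullEnsembleCL(IntegerMatrix adj, int nRand,
                                int swapsFactor, int retryCap) {
  int n = adj.nrow();
  AdjBool base(n, std::vector<int>(n, 0));
  std::vector<std::pair<int, int> > baseEdges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (adj(i, j) != 0) {
        base[i][j] = base[j][i] = 1;
        baseEdges.push_back(std::make_pair(i, j));
      }
  int ne = baseEdges.size();
  if (ne < 2) stop("need at least 2 edges to rewire");

  NumericMatrix out(nRand, 2);
  AdjBool a;
  std::vector<std::pair<int, int> > edges;
  for (int r = 0; r < nRand; ++r) {
    bool ok = false;
    for (int attempt = 0; attempt <= retryCap && !ok; ++attempt) {
      a = base;
      edges = baseEdges;
      int nSwaps = swapsFactor * ne;
      for (int s = 0; s < nSwaps; ++s) {
        int e1 = randInt(ne), e2 = randInt(ne);
        if (e1 == e2) continue;
        int u = edges[e1].first, v = edges[e1].second;
        int x = edges[e2].first, y = edges[e2].second;
        if (unif_rand() < 0.5) std::swap(x, y);
        // proposed edges (u, x) and (v, y); need 4 distinct nodes
        if (u == x || u == y || v == x || v == y) continue;
        if (a[u][x] || a[v][y]) continue;
        a[u][v] = a[v][u] = 0;
        a[x][y] = a[y][x] = 0;
        a[u][x] = a[x][u] = 1;
        a[v][y] = a[y][v] = 1;
        edges[e1] = std::make_pair(u, x);
        edges[e2] = std::make_pair(v, y);
      }
      ok = connected(a);
    }
    if (!ok)
      stop("could not draw a connected degree-preserving null within retry cap");
    for (int i = 0; i < n; ++i) { // invariant: degrees preserved exactly
      int d0 = 0, d1 = 0;
      for (int j = 0; j < n; ++j) {
        d0 += base[i][j];
        d1 += a[i][j];
      }
      if (d0 != d1) stop("internal error: degree sequence not preserved");
    }
    double c, l;
    clusteringPathLength(a, c, l);
    out(r, 0) = c;
    out(r, 1) = l;
  }
  return out;
}
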