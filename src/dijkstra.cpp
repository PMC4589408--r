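#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra over a directed edge list (1-based node ids).
// Exact priority-queue semantics: lazy deletion, first settle wins.
// Returns minutes from the nearest source to every node (R_PosInf if
// unreachable). Non-finite edge weights are treated as absent edges.
// [[Rcpp::export]]
NumericVector cpp_dijkstra(int n_nodes, IntegerVector from, IntegerVector to,
                           NumericVector w, IntegerVector sources) {
  const int m = from.size();
  if (to.size() != m || w.size() != m)
    stop("edge vectors must have equal length");

  // CSR adjacency
  std::vector<int> deg(n_nodes, 0);
  for (int e = 0; e < m; ++e) {
    int u = from[e];
    if (u < 1 || u > n_nodes || to[e] < 1 || to[e] > n_nodes)
      stop("node id out of range");
    if (R_finite(w[e])) deg[u - 1]++;
  }
  std::vector<int> ptr(n_nodes + 1, 0);
  for (int i = 0; i < n_nodes; ++i) ptr[i + 1] = ptr[i] + deg[i];
  std::vector<int> adj_to(ptr[n_nodes]);
  std::vector<double> adj_w(ptr[n_nodes]);
  std::vector<int> fill(ptr.begin(), ptr.end() - 1);
  for (int e = 0; e < m; ++e) {
    if (!R_finite(w[e])) continue;
    if (w[e] < 0) stop("negative edge weight");
    int u = from[e] - 1;
    adj_to[fill[u]] = to[e] - 1;
    adj_w[fill[u]] = w[e];
    fill[u]++;
  }

  std::vector<double> dist(n_nodes, R_PosInf);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int s = 0; s < sources.size(); ++s) {
    int v = sources[s];
    if (v < 1 || v > n_nodes) stop("source id out of range");
    if (dist[v - 1] > 0) { dist[v - 1] = 0.0; pq.push(QE(0.0, v - 1)); }
  }
  if (pq.empty()) stop("no valid sources");

  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first; int u = top.second;
    if (d > dist[u]) continue;  // stale entry
    for (int k = ptr[u]; k < ptr[u + 1]; ++k) {
      int v = adj_to[k];
      double nd = d + adj_w[k];
      if (nd < dist[v]) { dist[v] = nd; pq.push(QE(nd, v)); }
    }
  }
  return NumericVector(dist.begin(), dist.end());
}

// Nearest-neighbour lookup via a uniform bucket grid. Returns the 1-based
// index of the nearest (px,py) point for every query, or NA when none lies
// within max_dist.
// [[Rcpp::export]]
IntegerVector cpp_nearest_point(NumericVector qx, NumericVector qy,
                                NumericVector px, NumericVector py,
                                double max_dist) {
  const int nq = qx.size(), np = px.size();
  IntegerVector out(nq, NA_INTEGER);
  if (np == 0 || nq == 0) return out;
  if (max_dist <= 0) stop("max_dist must be positive");

  double xmin = px[0], ymin = py[0];
  for (int i = 1; i < np; ++i) {
    if (px[i] < xmin) xmin = px[i];
    if (py[i] < ymin) ymin = py[i];
  }
  const double cell = max_dist;
  std::vector<long long> bx(np), by(np);
  long long nbx = 0, nby = 0;
  for (int i = 0; i < np; ++i) {
    bx[i] = (long long)std::floor((px[i] - xmin) / cell);
    by[i] = (long long)std::floor((py[i] - ymin) / cell);
    if (bx[i] + 1 > nbx) nbx = bx[i] + 1;
    if (by[i] + 1 > nby) nby = by[i] + 1;
  }
  // bucket -> point ids
  std::vector<std::vector<int> > bucket((size_t)(nbx * nby));
  for (int i = 0; i < np; ++i)
    bucket[(size_t)(by[i] * nbx + bx[i])].push_back(i);

  const double md2 = max_dist * max_dist;
  for (int q = 0; q < nq; ++q) {
    long long qbx = (long long)std::floor((qx[q] - xmin) / cell);
    long long qby = (long long)std::floor((qy[q] - ymin) / cell);
    double best = md2; int besti = -1;
    for (long long dy = -1; dy <= 1; ++dy) {
      for (long long dx = -1; dx <= 1; ++dx) {
        long long cx = qbx + dx, cy = qby + dy;
        if (cx < 0 || cy < 0 || cx >= nbx || cy >= nby) continue;
        const std::vector<int>& pts = bucket[(size_t)(cy * nbx + cx)];
        for (size_t k = 0; k < pts.size(); ++k) {
          int i = pts[k];
          double ddx = px[i] - qx[q], ddy = py[i] - qy[q];
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 <= best) { best = d2; besti = i; }
        }
      }
    }
    if (besti >= 0) out[q] = besti + 1;
  }
  return out;
}
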