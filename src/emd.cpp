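#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact earth-mover's (transportation) cost between two nonnegative mass
// vectors under an arbitrary ground-cost matrix, by successive shortest
// augmenting paths on the bipartite residual graph (Bellman-Ford; costs are
// small and the graphs tiny, so no potentials are needed).
//
// supply: length N, demand: length M, cost: N x M. Transports
// min(sum(supply), sum(demand)) mass; callers pass balanced problems.
// [[Rcpp::export]]
double emd_exact(NumericVector supply, NumericVector demand,
                 NumericMatrix cost) {
  const int N = supply.size(), M = demand.size();
  if (cost.nrow() != N || cost.ncol() != M)
    stop("cost matrix dimensions do not match supply/demand");
  const double EPS = 1e-14;
  std::vector<double> ra(supply.begin(), supply.end());
  std::vector<double> rb(demand.begin(), demand.end());
  std::vector<std::vector<double> > flow(N, std::vector<double>(M, 0.0));
  double sa = 0.0, sb = 0.0;
  for (int i = 0; i < N; ++i) { if (ra[i] < 0) stop("negative supply"); sa += ra[i]; }
  for (int j = 0; j < M; ++j) { if (rb[j] < 0) stop("negative demand"); sb += rb[j]; }
  double remaining = sa < sb ? sa : sb;
  double total = 0.0;
  const double INF = std::numeric_limits<double>::infinity();

  while (remaining > 1e-12) {
    // Bellman-Ford over nodes: suppliers 0..N-1, consumers N..N+M-1.
    std::vector<double> dist(N + M, INF);
    std::vector<int> parent(N + M, -1);
    for (int i = 0; i < N; ++i) if (ra[i] > EPS) dist[i] = 0.0;
    bool changed = true;
    while (changed) {
      changed = false;
      for (int i = 0; i < N; ++i) {
        if (dist[i] == INF) continue;
        for (int j = 0; j < M; ++j) {
          double nd = dist[i] + cost(i, j);
          if (nd < dist[N + j] - 1e-15) {
            dist[N + j] = nd; parent[N + j] = i; changed = true;
          }
        }
      }
      for (int j = 0; j < M; ++j) {
        if (dist[N + j] == INF) continue;
        for (int i = 0; i < N; ++i) {
          if (flow[i][j] > EPS) {
            double nd = dist[N + j] - cost(i, j);
            if (nd < dist[i] - 1e-15) {
              dist[i] = nd; parent[i] = N + j; changed = true;
            }
          }
        }
      }
    }
    // Cheapest consumer with residual demand.
    int best = -1;
    for (int j = 0; j < M; ++j)
      if (rb[j] > EPS && dist[N + j] < INF &&
          (best < 0 || dist[N + j] < dist[N + best])) best = j;
    if (best < 0) break;  // disconnected residual mass (numerically exhausted)
    // Bottleneck along the augmenting path.
    double delta = rb[best];
    int v = N + best;
    while (parent[v] != -1) {
      int u = parent[v];
      if (u >= N && v < N) {  // reverse edge: consumer u-N -> supplier v
        double f = flow[v][u - N];
        if (f < delta) delta = f;
      }
      v = u;
    }
    if (ra[v] < delta) delta = ra[v];  // v is the source supplier
    if (delta <= EPS) break;
    // Apply augmentation.
    int w = N + best;
    while (parent[w] != -1) {
      int u = parent[w];
      if (u < N && w >= N) flow[u][w - N] += delta;
      else flow[w][u - N] -= delta;
      w = u;
    }
    ra[w] -= delta;
    rb[best] -= delta;
    remaining -= delta;
  }
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < M; ++j) total += flow[i][j] * cost(i, j);
  return total;
}
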