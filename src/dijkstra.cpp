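#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra over an 8-connected grid graph.
// res: resistance values, column-major (nr x nc), NaN = impassable.
// Step cost between adjacent cells = center distance * mean of the two
// cells' resistance; diagonal steps scale the distance by sqrt(2).
// Returns accumulated cost (cwd) and 1-based predecessor indices
// (0 = source or unreached).
// [[Rcpp::export(name = ".dijkstraGrid")]]
List dijkstraGrid(NumericVector res, int nr, int nc, double cellSize,
                  IntegerVector sources) {
  const int n = nr * nc;
  NumericVector dist(n, R_PosInf);
  IntegerVector pred(n, 0);
  std::vector<bool> done(n, false);

  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;

  for (int k = 0; k < sources.size(); ++k) {
    int s = sources[k] - 1;
    if (s < 0 || s >= n) stop("source index out of range");
    if (ISNAN(res[s])) continue;
    dist[s] = 0.0;
    pq.push(QE(0.0, s));
  }

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double sqrt2 = std::sqrt(2.0);

  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = true;
    int ur = u % nr, uc = u / nr;
    for (int k = 0; k < 8; ++k) {
      int vr = ur + dr[k], vc = uc + dc[k];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      int v = vc * nr + vr;
      if (done[v] || ISNAN(res[v])) continue;
      double step = cellSize * ((dr[k] != 0 && dc[k] != 0) ? sqrt2 : 1.0);
      double w = step * 0.5 * (res[u] + res[v]);
      double nd = dist[u] + w;
      if (nd < dist[v]) {
        dist[v] = nd;
        pred[v] = u + 1;
        pq.push(QE(nd, v));
      }
    }
  }
  return List::create(_["cwd"] = dist, _["pred"] = pred);
}
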