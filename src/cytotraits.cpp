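#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Euclidean distance between rows a and b of X (n x d, column-major).
static inline double row_dist(const NumericMatrix& X, int a, int b) {
  double s = 0.0;
  const int d = X.ncol();
  for (int j = 0; j < d; ++j) {
    const double diff = X(a, j) - X(b, j);
    s += diff * diff;
  }
  return std::sqrt(s);
}

// Distance to the k-th nearest neighbour of each point (self excluded).
// Brute force; fine for the event counts this package works at.
// [[Rcpp::export(name = ".core_distances")]]
NumericVector core_distances(NumericMatrix X, int k) {
  const int n = X.nrow();
  if (k < 1) stop("k must be >= 1");
  if (k > n - 1) k = n - 1;
  NumericVector out(n);
  std::vector<double> buf(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      buf[m++] = row_dist(X, i, j);
    }
    std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end());
    out[i] = buf[k - 1];
  }
  return out;
}

// Minimum spanning tree of the mutual-reachability graph
// d_mreach(a, b) = max(core[a], core[b], d(a, b)), Prim's algorithm with
// O(n) memory (distances computed on the fly). Returns (n-1) x 3 matrix of
// (from, to, weight), 1-based vertex indices.
// [[Rcpp::export(name = ".mreach_mst")]]
NumericMatrix mreach_mst(NumericMatrix X, NumericVector core) {
  const int n = X.nrow();
  NumericMatrix edges(n - 1, 3);
  std::vector<double> best(n, R_PosInf);
  std::vector<int> bestFrom(n, 0);
  std::vector<bool> inTree(n, false);
  int current = 0;
  inTree[0] = true;
  for (int e = 0; e < n - 1; ++e) {
    const double core_c = core[current];
    for (int j = 0; j < n; ++j) {
      if (inTree[j]) continue;
      double w = row_dist(X, current, j);
      if (core_c > w) w = core_c;
      if (core[j] > w) w = core[j];
      if (w < best[j]) {
        best[j] = w;
        bestFrom[j] = current;
      }
    }
    int pick = -1;
    double wmin = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (!inTree[j] && best[j] < wmin) {
        wmin = best[j];
        pick = j;
      }
    }
    edges(e, 0) = bestFrom[pick] + 1;
    edges(e, 1) = pick + 1;
    edges(e, 2) = wmin;
    inTree[pick] = true;
    current = pick;
  }
  return edges;
}

// Product-Gaussian kernel density estimate with per-dimension bandwidths h,
// evaluated at the rows of `query`: f(x) = (1/n) sum_i prod_j
// dnorm(x_j; X_ij, h_j).
// [[Rcpp::export(name = ".kde_gaussian")]]
NumericVector kde_gaussian(NumericMatrix query, NumericMatrix data,
                           NumericVector h) {
  const int m = query.nrow(), n = data.nrow(), d = data.ncol();
  if (query.ncol() != d) stop("dimension mismatch between query and data");
  if (h.size() != d) stop("one bandwidth per dimension required");
  double lognorm = 0.0;
  for (int j = 0; j < d; ++j) {
    if (h[j] <= 0) stop("bandwidths must be positive");
    lognorm += std::log(h[j] * std::sqrt(2.0 * M_PI));
  }
  const double norm = std::exp(-lognorm) / static_cast<double>(n);
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      double expo = 0.0;
      for (int j = 0; j < d; ++j) {
        const double z = (query(q, j) - data(i, j)) / h[j];
        expo += z * z;
      }
      acc += std::exp(-0.5 * expo);
    }
    out[q] = acc * norm;
  }
  return out;
}
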