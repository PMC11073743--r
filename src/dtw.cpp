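#include <Rcpp.h>
using namespace Rcpp;

// Euclidean distance between row i of x and row j of y.
static inline double point_dist(const NumericMatrix& x, int i,
                                const NumericMatrix& y, int j) {
  double s = 0.0;
  const int d = x.ncol();
  for (int k = 0; k < d; ++k) {
    const double diff = x(i, k) - y(j, k);
    s += diff * diff;
  }
  return std::sqrt(s);
}

// DTW distance with the unconstrained unit-weight step pattern:
// D(i,j) = c(i,j) + min(D(i-1,j), D(i-1,j-1), D(i,j-1)), c = Euclidean.
static double dtw_pair(const NumericMatrix& x, const NumericMatrix& y) {
  const int n = x.nrow(), m = y.nrow();
  std::vector<double> prev(m), cur(m);
  for (int j = 0; j < m; ++j) {
    prev[j] = point_dist(x, 0, y, j) + (j > 0 ? prev[j - 1] : 0.0);
  }
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + point_dist(x, i, y, 0);
    for (int j = 1; j < m; ++j) {
      const double best = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
      cur[j] = best + point_dist(x, i, y, j);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// [[Rcpp::export]]
double dtw_cost_cpp(NumericMatrix x, NumericMatrix y) {
  if (x.ncol() != y.ncol()) stop("point dimensions differ");
  if (x.nrow() == 0 || y.nrow() == 0) stop("empty sequence");
  return dtw_pair(x, y);
}

// [[Rcpp::export]]
NumericMatrix dtw_to_centers_cpp(List traj, List centers) {
  const int n = traj.size(), k = centers.size();
  NumericMatrix out(n, k);
  std::vector<NumericMatrix> cs(k);
  for (int j = 0; j < k; ++j) cs[j] = as<NumericMatrix>(centers[j]);
  for (int i = 0; i < n; ++i) {
    NumericMatrix xi = as<NumericMatrix>(traj[i]);
    for (int j = 0; j < k; ++j) out(i, j) = dtw_pair(xi, cs[j]);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(List traj) {
  const int n = traj.size();
  NumericMatrix out(n, n);
  std::vector<NumericMatrix> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = as<NumericMatrix>(traj[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double d = dtw_pair(xs[i], xs[j]);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
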