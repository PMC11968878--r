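#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-time-warping dynamic program over monotone step set
// {(1,0),(0,1),(1,1)} with local cost |x_i - y_j| (squared = false) or
// (x_i - y_j)^2 (squared = true). Ties between predecessors prefer the
// diagonal step, both in the forward pass and during backtracking, so the
// returned path is deterministic.

static inline double local_cost(double a, double b, bool squared) {
  double d = a - b;
  return squared ? d * d : std::fabs(d);
}

// [[Rcpp::export(name = ".dtw_cpp")]]
List dtw_cpp(NumericVector x, NumericVector y, bool squared = false,
             bool want_path = true) {
  const int m = x.size(), n = y.size();
  if (m == 0 || n == 0) stop("series must be non-empty");
  NumericMatrix D(m, n);
  D(0, 0) = local_cost(x[0], y[0], squared);
  for (int i = 1; i < m; ++i) D(i, 0) = D(i - 1, 0) + local_cost(x[i], y[0], squared);
  for (int j = 1; j < n; ++j) D(0, j) = D(0, j - 1) + local_cost(x[0], y[j], squared);
  for (int i = 1; i < m; ++i) {
    for (int j = 1; j < n; ++j) {
      double best = D(i - 1, j - 1);              // diagonal preferred on ties
      if (D(i - 1, j) < best) best = D(i - 1, j);
      if (D(i, j - 1) < best) best = D(i, j - 1);
      D(i, j) = best + local_cost(x[i], y[j], squared);
    }
  }
  if (!want_path) {
    return List::create(_["distance"] = D(m - 1, n - 1));
  }
  // Backtrack (path stored reversed, then flipped); indices reported 1-based.
  std::vector<int> pi, pj;
  int i = m - 1, j = n - 1;
  pi.push_back(i); pj.push_back(j);
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      double d_diag = D(i - 1, j - 1), d_up = D(i - 1, j), d_left = D(i, j - 1);
      if (d_diag <= d_up && d_diag <= d_left) { --i; --j; }
      else if (d_up <= d_left) { --i; }
      else { --j; }
    }
    pi.push_back(i); pj.push_back(j);
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k] + 1;
    path(k, 1) = pj[L - 1 - k] + 1;
  }
  return List::create(_["distance"] = D(m - 1, n - 1), _["path"] = path);
}

// Distances from every row of `series` to every row of `centroids`.
// [[Rcpp::export(name = ".dtw_cdist_cpp")]]
NumericMatrix dtw_cdist_cpp(NumericMatrix series, NumericMatrix centroids,
                            bool squared = true) {
  const int n = series.nrow(), k = centroids.nrow();
  NumericMatrix out(n, k);
  for (int c = 0; c < k; ++c) {
    NumericVector cen = centroids(c, _);
    for (int i = 0; i < n; ++i) {
      NumericVector xi = series(i, _);
      List r = dtw_cpp(xi, cen, squared, false);
      out(i, c) = as<double>(r["distance"]);
    }
  }
  return out;
}

// One DTW-barycenter-averaging update: align every member series to the
// current centroid, then replace each centroid sample by the mean of all
// member samples mapped onto it.
// [[Rcpp::export(name = ".dba_update_cpp")]]
NumericVector dba_update_cpp(NumericMatrix members, NumericVector centroid,
                             bool squared = true) {
  const int L = centroid.size();
  NumericVector sums(L), cnts(L);
  for (int i = 0; i < members.nrow(); ++i) {
    NumericVector xi = members(i, _);
    List r = dtw_cpp(xi, centroid, squared, true);
    IntegerMatrix path = r["path"];
    for (int k = 0; k < path.nrow(); ++k) {
      int ii = path(k, 0) - 1, jj = path(k, 1) - 1;
      sums[jj] += xi[ii];
      cnts[jj] += 1.0;
    }
  }
  NumericVector out(L);
  for (int j = 0; j < L; ++j) out[j] = cnts[j] > 0 ? sums[j] / cnts[j] : centroid[j];
  return out;
}
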