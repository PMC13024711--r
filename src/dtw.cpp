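#include <Rcpp.h>
using namespace Rcpp;

// Classic dynamic time warping on two numeric series with |.| local cost.
// symmetric1: D(i,j) = c + min(D(i-1,j), D(i,j-1), D(i-1,j-1))
// symmetric2: the diagonal step counts the local cost twice
// Unnormalized; no window, no endpoint relaxation.
static double dtw_core(const NumericVector& x, const NumericVector& y,
                       bool symmetric2) {
  const int n = x.size(), m = y.size();
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      double c = std::abs(x[i - 1] - y[j - 1]);
      double diag = prev[j - 1] + (symmetric2 ? 2.0 * c : c);
      double step = std::min(prev[j] + c, std::min(cur[j - 1] + c, diag));
      cur[j] = step;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double dtw_dist_cpp(NumericVector x, NumericVector y, bool symmetric2) {
  if (x.size() == 0 || y.size() == 0)
    stop("DTW requires non-empty series");
  return dtw_core(x, y, symmetric2);
}

// [[Rcpp::export]]
NumericMatrix dtw_matrix_cpp(List seqs, bool symmetric2) {
  const int n = seqs.size();
  std::vector<NumericVector> v(n);
  for (int i = 0; i < n; ++i) {
    v[i] = as<NumericVector>(seqs[i]);
    if (v[i].size() == 0) stop("DTW requires non-empty series");
  }
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = dtw_core(v[i], v[j], symmetric2);
      D(i, j) = d;
      D(j, i) = d;
    }
  return D;
}
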