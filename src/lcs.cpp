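#include <Rcpp.h>
using namespace Rcpp;

// Longest-common-subsequence length by dynamic programming over the
// (|x|+1) x (|y|+1) grid, rolling two rows.
static int lcs_len(const int* x, int nx, const int* y, int ny,
                   std::vector<int>& prev, std::vector<int>& cur) {
  std::fill(prev.begin(), prev.begin() + ny + 1, 0);
  for (int i = 1; i <= nx; ++i) {
    cur[0] = 0;
    const int xi = x[i - 1];
    for (int j = 1; j <= ny; ++j) {
      if (xi == y[j - 1])
        cur[j] = prev[j - 1] + 1;
      else
        cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[ny];
}

// [[Rcpp::export]]
int lcs_length_cpp(IntegerVector x, IntegerVector y) {
  int nx = x.size(), ny = y.size();
  if (nx == 0 || ny == 0) return 0;
  std::vector<int> prev(ny + 1), cur(ny + 1);
  return lcs_len(INTEGER(x), nx, INTEGER(y), ny, prev, cur);
}

// Pairwise LCS dissimilarity d(x,y) = |x| + |y| - 2 * lcs_length(x, y)
// for integer-coded sequences stored as the rows of `seqs`.
// [[Rcpp::export]]
IntegerMatrix lcs_pairwise_cpp(IntegerMatrix seqs) {
  const int n = seqs.nrow(), T = seqs.ncol();
  // copy rows into contiguous buffers
  std::vector<int> buf(n * T);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t)
      buf[i * T + t] = seqs(i, t);
  IntegerMatrix d(n, n);
  std::vector<int> prev(T + 1), cur(T + 1);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int L = lcs_len(&buf[i * T], T, &buf[j * T], T, prev, cur);
      int dij = 2 * (T - L);
      d(i, j) = dij;
      d(j, i) = dij;
    }
  }
  return d;
}
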