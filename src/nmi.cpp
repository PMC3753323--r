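#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Plug-in entropies use H = log2(n) - (1/n) sum c*log2(c) with a lookup
// table for c*log2(c), c = 0..n (counts are bounded by the series length).
struct LogTab {
  std::vector<double> clog2c;
  double log2n;
  int n;
  explicit LogTab(int n_) : clog2c(n_ + 1), n(n_) {
    clog2c[0] = 0.0;
    for (int c = 1; c <= n_; ++c) clog2c[c] = c * std::log2((double)c);
    log2n = std::log2((double)n_);
  }
  double entropy(const int *cnt, int ncell) const {
    double s = 0.0;
    for (int i = 0; i < ncell; ++i) s += clog2c[cnt[i]];
    return log2n - s / n;
  }
};

static double marginal_entropy_col(const int *col, int n, int nbins,
                                   const LogTab &lt, std::vector<int> &cnt) {
  std::fill(cnt.begin(), cnt.end(), 0);
  for (int t = 0; t < n; ++t) cnt[col[t]]++;
  return lt.entropy(cnt.data(), nbins);
}

// NMI between two pre-binned series (values in 0..nbins-1).
static double nmi_pair(const int *x, const int *y, int n, int nbins,
                       double hx, double hy, const LogTab &lt,
                       std::vector<int> &joint) {
  if (hx <= 0.0 || hy <= 0.0) return 0.0;
  std::fill(joint.begin(), joint.end(), 0);
  for (int t = 0; t < n; ++t) joint[x[t] * nbins + y[t]]++;
  double hxy = lt.entropy(joint.data(), nbins * nbins);
  double mi = hx + hy - hxy;
  if (mi < 0.0) mi = 0.0;
  double nmi = mi / std::sqrt(hx * hy);
  if (nmi > 1.0) nmi = 1.0;
  return nmi;
}

// All-pairs NMI between columns of one binned matrix (intra-band).
// [[Rcpp::export]]
NumericMatrix cpp_nmi_allpairs(IntegerMatrix B, int nbins) {
  int N = B.ncol(), n = B.nrow();
  LogTab lt(n);
  NumericMatrix W(N, N);
  const int *base = INTEGER(B);
  std::vector<double> h(N);
  std::vector<int> cnt(nbins), joint(nbins * nbins);
  for (int i = 0; i < N; ++i)
    h[i] = marginal_entropy_col(base + (size_t)i * n, n, nbins, lt, cnt);
  for (int i = 0; i < N; ++i) {
    const int *xi = base + (size_t)i * n;
    for (int j = i + 1; j < N; ++j) {
      double v = nmi_pair(xi, base + (size_t)j * n, n, nbins, h[i], h[j], lt,
                          joint);
      W(i, j) = v;
      W(j, i) = v;
    }
  }
  return W;
}

// Full N x N cross-band NMI: raw[i, j] = NMI(Bx[, i], By[, j]).
// [[Rcpp::export]]
NumericMatrix cpp_nmi_cross(IntegerMatrix Bx, IntegerMatrix By, int nbins) {
  int N = Bx.ncol(), n = Bx.nrow();
  if (By.ncol() != N) stop("band matrices must have the same sensor count");
  if (By.nrow() != n) stop("band matrices must have the same sample count");
  LogTab lt(n);
  NumericMatrix W(N, N);
  const int *bx = INTEGER(Bx), *by = INTEGER(By);
  std::vector<double> hx(N), hy(N);
  std::vector<int> cnt(nbins), joint(nbins * nbins);
  for (int i = 0; i < N; ++i) {
    hx[i] = marginal_entropy_col(bx + (size_t)i * n, n, nbins, lt, cnt);
    hy[i] = marginal_entropy_col(by + (size_t)i * n, n, nbins, lt, cnt);
  }
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      W(i, j) = nmi_pair(bx + (size_t)i * n, by + (size_t)j * n, n, nbins,
                         hx[i], hy[j], lt, joint);
  return W;
}

// Equal-width bin assignment for every column of a matrix (0..nbins-1).
// [[Rcpp::export]]
IntegerMatrix cpp_bin_columns(NumericMatrix X, int nbins) {
  int n = X.nrow(), m = X.ncol();
  IntegerMatrix B(n, m);
  for (int j = 0; j < m; ++j) {
    const double *x = REAL(X) + (size_t)j * n;
    int *b = INTEGER(B) + (size_t)j * n;
    double lo = x[0], hi = x[0];
    for (int t = 1; t < n; ++t) {
      if (x[t] < lo) lo = x[t];
      if (x[t] > hi) hi = x[t];
    }
    if (hi <= lo) {
      for (int t = 0; t < n; ++t) b[t] = 0;
      continue;
    }
    double scale = nbins / (hi - lo);
    for (int t = 0; t < n; ++t) {
      int idx = (int)std::floor((x[t] - lo) * scale);
      if (idx >= nbins) idx = nbins - 1;
      if (idx < 0) idx = 0;
      b[t] = idx;
    }
  }
  return B;
}
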