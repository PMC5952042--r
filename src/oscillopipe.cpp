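#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state zi (length
// max(nb,na)-1). a[0] must be 1 (caller normalises).
// [[Rcpp::export]]
NumericVector cpp_lfilter(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nf = std::max(nb, na);
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nf, 0.0);
  for (int i = 0; i < (int)zi.size() && i < nf - 1; ++i) z[i] = zi[i];
  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nf - 2; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}

// Sturm count: number of eigenvalues of the symmetric tridiagonal matrix
// (diag d, off-diag e) strictly less than x.
static int sturm_count(const std::vector<double>& d,
                       const std::vector<double>& e, double x) {
  int n = d.size(), cnt = 0;
  double q = 1.0;
  for (int i = 0; i < n; ++i) {
    double e2 = (i == 0) ? 0.0 : e[i - 1] * e[i - 1];
    q = d[i] - x - ((q != 0.0) ? e2 / q : e2 / 1e-300);
    if (q < 0.0) ++cnt;
  }
  return cnt;
}

// Solve (T - lambda I) v = w for tridiagonal T by LU with partial pivoting.
static void tridiag_solve(const std::vector<double>& d,
                          const std::vector<double>& e, double lambda,
                          std::vector<double>& v) {
  int n = d.size();
  std::vector<double> dl(n, 0.0), dd(n), du(n, 0.0), du2(n, 0.0);
  for (int i = 0; i < n; ++i) dd[i] = d[i] - lambda;
  for (int i = 0; i < n - 1; ++i) { dl[i] = e[i]; du[i] = e[i]; }
  std::vector<int> piv(n, 0);
  // LU factorisation (LAPACK dgttrf style)
  for (int i = 0; i < n - 1; ++i) {
    if (std::fabs(dd[i]) >= std::fabs(dl[i])) {
      if (dd[i] == 0.0) dd[i] = 1e-300;
      double m = dl[i] / dd[i];
      dl[i] = m;
      dd[i + 1] -= m * du[i];
      piv[i] = 0;
    } else {
      double m = dd[i] / dl[i];
      std::swap(dd[i], dl[i]);
      double tmp = du[i];
      du[i] = dd[i + 1];
      dd[i + 1] = tmp - m * dd[i + 1];
      if (i < n - 2) { du2[i] = du[i + 1]; du[i + 1] = -m * du[i + 1]; }
      dl[i] = m;
      piv[i] = 1;
    }
  }
  if (dd[n - 1] == 0.0) dd[n - 1] = 1e-300;
  // forward substitution
  for (int i = 0; i < n - 1; ++i) {
    if (piv[i] == 0) {
      v[i + 1] -= dl[i] * v[i];
    } else {
      double tmp = v[i];
      v[i] = v[i + 1];
      v[i + 1] = tmp - dl[i] * v[i];
    }
  }
  // back substitution
  v[n - 1] /= dd[n - 1];
  if (n > 1) {
    double num = v[n - 2] - du[n - 2] * v[n - 1];
    v[n - 2] = num / dd[n - 2];
  }
  for (int i = n - 3; i >= 0; --i)
    v[i] = (v[i] - du[i] * v[i + 1] - du2[i] * v[i + 2]) / dd[i];
}

// Discrete prolate spheroidal sequences: the k leading eigenvectors of the
// standard tridiagonal commuting matrix, each normalised to unit energy.
// Returns an n x k matrix, columns ordered by decreasing eigenvalue.
// [[Rcpp::export]]
NumericMatrix cpp_dpss(int n, double nw, int k) {
  if (n < 2 || k < 1) stop("invalid dpss request");
  double W = nw / n;
  std::vector<double> d(n), e(n - 1);
  double c = std::cos(2.0 * M_PI * W);
  for (int t = 0; t < n; ++t) {
    double h = (n - 1 - 2.0 * t) / 2.0;
    d[t] = h * h * c;
  }
  for (int t = 1; t < n; ++t) e[t - 1] = t * (n - t) / 2.0;
  // Gershgorin bounds
  double lo = d[0], hi = d[0];
  for (int i = 0; i < n; ++i) {
    double r = 0.0;
    if (i > 0) r += std::fabs(e[i - 1]);
    if (i < n - 1) r += std::fabs(e[i]);
    lo = std::min(lo, d[i] - r);
    hi = std::max(hi, d[i] + r);
  }
  NumericMatrix out(n, k);
  std::vector<std::vector<double> > found;
  for (int m = 0; m < k; ++m) {
    // bisect for the (m+1)-th largest eigenvalue: smallest x with
    // sturm_count(x) >= n - m  gives an upper bracket of lambda_{n-m}
    double a = lo, b = hi;
    for (int it = 0; it < 120 && (b - a) > 1e-12 * std::max(1.0, std::fabs(b));
         ++it) {
      double mid = 0.5 * (a + b);
      if (sturm_count(d, e, mid) >= n - m) b = mid; else a = mid;
    }
    double lambda = 0.5 * (a + b);
    // inverse iteration
    std::vector<double> v(n);
    for (int i = 0; i < n; ++i) v[i] = 1.0 / std::sqrt((double)n);
    for (int iter = 0; iter < 4; ++iter) {
      tridiag_solve(d, e, lambda, v);
      // orthogonalise against previously found vectors
      for (size_t f = 0; f < found.size(); ++f) {
        double dot = 0.0;
        for (int i = 0; i < n; ++i) dot += v[i] * found[f][i];
        for (int i = 0; i < n; ++i) v[i] -= dot * found[f][i];
      }
      double nrm = 0.0;
      for (int i = 0; i < n; ++i) nrm += v[i] * v[i];
      nrm = std::sqrt(nrm);
      if (nrm == 0.0) { v[n / 2] = 1.0; nrm = 1.0; }
      for (int i = 0; i < n; ++i) v[i] /= nrm;
    }
    // polarity convention: symmetric tapers have positive mean; antisymmetric
    // tapers start with a positive lobe
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += v[i];
    if (std::fabs(s) > 1e-7) {
      if (s < 0) for (int i = 0; i < n; ++i) v[i] = -v[i];
    } else {
      double w = 0.0;
      for (int i = 0; i < n / 2; ++i) w += v[i];
      if (w < 0) for (int i = 0; i < n; ++i) v[i] = -v[i];
    }
    for (int i = 0; i < n; ++i) out(i, m) = v[i];
    found.push_back(v);
  }
  return out;
}
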