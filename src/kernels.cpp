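#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Approximate entropy: Phi_m(r) - Phi_{m+1}(r), Chebyshev distance,
// self-matches included. O(n^2), hence compiled: a full night is ~25k beats.
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) stop("series too short for approximate entropy");
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int nt = n - mm + 1;           // number of templates
    double acc = 0.0;
    for (int i = 0; i < nt; ++i) {
      int cnt = 0;
      for (int j = 0; j < nt; ++j) {
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double dk = std::fabs(x[i + k] - x[j + k]);
          if (dk > d) d = dk;
          if (d > r) break;
        }
        if (d <= r) ++cnt;
      }
      acc += std::log((double)cnt / (double)nt);
    }
    phi[s] = acc / (double)nt;
  }
  return phi[0] - phi[1];
}

// Classical Lomb-Scargle periodogram with the per-frequency offset tau.
// Input values must already be mean-subtracted. For each frequency the
// statistic needs only four accumulators,
//   C = sum y cos(wt), S = sum y sin(wt),
//   C2 = sum cos(2wt), S2 = sum sin(2wt),
// which on a uniform frequency grid are built with complex rotation
// recurrences (no trig in the inner loop); an irregular grid falls back to
// the direct sums.
// [[Rcpp::export(name = ".lomb_cpp")]]
NumericVector lomb_cpp(NumericVector t, NumericVector y, NumericVector freq) {
  int n = t.size(), nf = freq.size();
  if (y.size() != n) stop("times and values must have equal length");
  std::vector<double> C(nf, 0.0), S(nf, 0.0), C2(nf, 0.0), S2(nf, 0.0);

  bool uniform = nf > 2;
  double df = nf > 1 ? freq[1] - freq[0] : 0.0;
  for (int f = 2; f < nf && uniform; ++f)
    if (std::fabs((freq[f] - freq[f - 1]) - df) > 1e-9 * std::fabs(df))
      uniform = false;

  if (uniform && nf > 1) {
    double w0 = 2.0 * M_PI * freq[0];
    double dw = 2.0 * M_PI * df;
    for (int i = 0; i < n; ++i) {
      double ti = t[i], yi = y[i];
      double c1 = std::cos(w0 * ti), s1 = std::sin(w0 * ti);
      double cr = std::cos(dw * ti), sr = std::sin(dw * ti);
      double c2 = c1 * c1 - s1 * s1, s2 = 2.0 * s1 * c1;     // angle doubling
      double cr2 = cr * cr - sr * sr, sr2 = 2.0 * sr * cr;
      for (int f = 0; f < nf; ++f) {
        C[f] += yi * c1; S[f] += yi * s1;
        C2[f] += c2; S2[f] += s2;
        double cn = c1 * cr - s1 * sr;            // rotate by dw*ti
        s1 = s1 * cr + c1 * sr; c1 = cn;
        double cn2 = c2 * cr2 - s2 * sr2;
        s2 = s2 * cr2 + c2 * sr2; c2 = cn2;
      }
    }
  } else {
    for (int f = 0; f < nf; ++f) {
      double w = 2.0 * M_PI * freq[f];
      for (int i = 0; i < n; ++i) {
        double a = w * t[i];
        C[f] += y[i] * std::cos(a);
        S[f] += y[i] * std::sin(a);
        C2[f] += std::cos(2.0 * a);
        S2[f] += std::sin(2.0 * a);
      }
    }
  }

  NumericVector p(nf);
  for (int f = 0; f < nf; ++f) {
    double wt = 0.5 * std::atan2(S2[f], C2[f]);   // w * tau
    double ct = std::cos(wt), st = std::sin(wt);
    double yc = C[f] * ct + S[f] * st;            // sum y cos(w(t - tau))
    double ys = S[f] * ct - C[f] * st;            // sum y sin(w(t - tau))
    double half = 0.5 * (C2[f] * std::cos(2.0 * wt) + S2[f] * std::sin(2.0 * wt));
    double cc = 0.5 * n + half;                   // sum cos^2(w(t - tau))
    double ss = 0.5 * n - half;                   // sum sin^2(w(t - tau))
    double pc = (cc > 0.0) ? yc * yc / cc : 0.0;
    double ps = (ss > 0.0) ? ys * ys / ss : 0.0;
    p[f] = 0.5 * (pc + ps);
  }
  return p;
}
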