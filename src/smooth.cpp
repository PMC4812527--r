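#include <Rcpp.h>
using namespace Rcpp;

// Local-likelihood style smoother for one chromosome segment and one
// sample: coverage-weighted tricube local quadratic fit on the logit
// scale, evaluated at every CpG. The window around site i is the smallest
// symmetric window holding at least ns CpGs and spanning at least
// half-width h on each side. Sites with zero coverage carry zero weight
// but still receive a fitted value.
//
// pos: CpG positions (bp, sorted); y: clamped-logit methylation (0 where
// weight is 0); w: coverage weights (>= 0). Returns fitted logit values.
// [[Rcpp::export]]
NumericVector smooth_segment_cpp(IntegerVector pos, NumericVector y,
                                 NumericVector w, int ns, double h) {
  const int n = pos.size();
  NumericVector out(n);
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) {
    // radius: distance to the ns-th nearest CpG (including self), floored
    // at h
    int lo = i, hi = i, cnt = 1;
    double rad = 0.0;
    while (cnt < ns && (lo > 0 || hi < n - 1)) {
      double dl = (lo > 0) ? (double)(pos[i] - pos[lo - 1]) : R_PosInf;
      double dr = (hi < n - 1) ? (double)(pos[hi + 1] - pos[i]) : R_PosInf;
      if (dl <= dr) { --lo; rad = dl; } else { ++hi; rad = dr; }
      ++cnt;
    }
    if (rad < h) rad = h;
    // expand to all sites within rad
    while (lo > 0 && pos[i] - pos[lo - 1] <= rad) --lo;
    while (hi < n - 1 && pos[hi + 1] - pos[i] <= rad) ++hi;
    // weighted quadratic fit of y on centered, kb-scaled position
    double S0 = 0, S1 = 0, S2 = 0, S3 = 0, S4 = 0;
    double T0 = 0, T1 = 0, T2 = 0;
    int npos = 0;
    double denom = rad + 1.0;  // keep boundary weights positive
    for (int j = lo; j <= hi; ++j) {
      double dj = std::abs((double)(pos[j] - pos[i]));
      double u = dj / denom;
      double tri = 1.0 - u * u * u;
      tri = tri * tri * tri;
      double wj = w[j] * tri;
      if (wj <= 0) continue;
      ++npos;
      double x = (double)(pos[j] - pos[i]) / 1000.0;
      double x2 = x * x;
      S0 += wj; S1 += wj * x; S2 += wj * x2;
      S3 += wj * x2 * x; S4 += wj * x2 * x2;
      T0 += wj * y[j]; T1 += wj * x * y[j]; T2 += wj * x2 * y[j];
    }
    if (S0 <= 0) { out[i] = NA_REAL; continue; }
    if (npos >= 3) {
      // solve [S0 S1 S2; S1 S2 S3; S2 S3 S4] b = [T0 T1 T2]
      double a11 = S0, a12 = S1, a13 = S2;
      double a22 = S2, a23 = S3, a33 = S4;
      double det = a11 * (a22 * a33 - a23 * a23)
                 - a12 * (a12 * a33 - a23 * a13)
                 + a13 * (a12 * a23 - a22 * a13);
      double scale = a11 * a22 * a33;
      if (std::abs(det) > 1e-12 * (std::abs(scale) + 1e-12)) {
        // Cramer's rule for the intercept (fit at x = 0)
        double det0 = T0 * (a22 * a33 - a23 * a23)
                    - a12 * (T1 * a33 - a23 * T2)
                    + a13 * (T1 * a23 - a22 * T2);
        out[i] = det0 / det;
        continue;
      }
    }
    if (npos >= 2) {
      double det = S0 * S2 - S1 * S1;
      if (std::abs(det) > 1e-12 * (std::abs(S0 * S2) + 1e-12)) {
        out[i] = (T0 * S2 - S1 * T1) / det;
        continue;
      }
    }
    out[i] = T0 / S0;  // weighted mean fallback
  }
  return out;
}
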