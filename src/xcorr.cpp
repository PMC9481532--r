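#include <Rcpp.h>
using namespace Rcpp;

// Pearson correlation between x and y at every integer shift in [-K, K],
// computed over the overlapping samples only (no zero padding). For shift
// s >= 0, x[(s+1):n] is compared with y[1:(n-s)] (x delayed by s samples
// relative to y). Returns NA where the overlap has zero variance.
// [[Rcpp::export(name = ".xcorr_shifts")]]
NumericVector xcorr_shifts(NumericVector x, NumericVector y, int K) {
  int n = x.size();
  if (y.size() != n) stop("series must have equal length");
  if (K >= n) K = n - 1;
  NumericVector r(2 * K + 1, NA_REAL);
  for (int s = -K; s <= K; ++s) {
    int m = n - std::abs(s);
    if (m < 3) continue;
    const double *xa, *ya;
    if (s >= 0) { xa = &x[s]; ya = &y[0]; }
    else        { xa = &x[0]; ya = &y[-s]; }
    double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    for (int i = 0; i < m; ++i) {
      double a = xa[i], b = ya[i];
      sx += a; sy += b; sxx += a * a; syy += b * b; sxy += a * b;
    }
    double vx = sxx - sx * sx / m;
    double vy = syy - sy * sy / m;
    if (vx <= 0 || vy <= 0) continue;
    r[s + K] = (sxy - sx * sy / m) / std::sqrt(vx * vy);
  }
  return r;
}
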