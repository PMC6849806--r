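#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double beta3w(double t) {
  t = std::fabs(t);
  if (t < 1.0) return (4.0 - 6.0 * t * t + 3.0 * t * t * t) / 6.0;
  if (t < 2.0) { const double u = 2.0 - t; return u * u * u / 6.0; }
  return 0.0;
}

static inline double beta3d(double t) {
  const double a = std::fabs(t), s = t < 0 ? -1.0 : 1.0;
  if (a < 1.0) return s * (-2.0 * a + 1.5 * a * a);
  if (a < 2.0) { const double u = 2.0 - a; return -s * 0.5 * u * u; }
  return 0.0;
}

// Parzen-window mutual information between fixed-image samples f and
// moving-image samples m, with a linear (first-order) kernel on the fixed
// axis and a cubic B-spline kernel on the moving axis.  Returns MI in nats
// and, when want_grad, the derivative of MI with respect to each moving
// intensity sample (the smooth-kernel route needed for stochastic gradient
// descent; the histogram-based estimator lives in R as mutual_information()).
// [[Rcpp::export]]
List cpp_mi_parzen(NumericVector f, NumericVector m, int nbins,
                   double fmin, double fmax, double mmin, double mmax,
                   bool want_grad) {
  const int n = f.size();
  const double df = (fmax - fmin) > 0 ? (fmax - fmin) / nbins : 1.0;
  const double dm = (mmax - mmin) > 0 ? (mmax - mmin) / nbins : 1.0;
  std::vector<double> P((size_t)nbins * nbins, 0.0);
  std::vector<double> pf_pos(n), pm_pos(n);
  int nused = 0;
  for (int i = 0; i < n; ++i) {
    if (!R_finite(f[i]) || !R_finite(m[i])) { pf_pos[i] = NA_REAL; continue; }
    double pf = (f[i] - fmin) / df - 0.5;
    double pm = (m[i] - mmin) / dm - 0.5;
    if (pf < 0.0) pf = 0.0; if (pf > nbins - 1.0) pf = nbins - 1.0;
    if (pm < 1.0) pm = 1.0; if (pm > nbins - 2.0 - 1e-9) pm = nbins - 2.0 - 1e-9;
    pf_pos[i] = pf; pm_pos[i] = pm;
    ++nused;
  }
  if (nused == 0)
    return List::create(_["mi"] = 0.0, _["grad"] = NumericVector(n),
                        _["n"] = 0);
  for (int i = 0; i < n; ++i) {
    if (!R_finite(pf_pos[i])) continue;
    const double pf = pf_pos[i], pm = pm_pos[i];
    const int fb0 = (int)std::floor(pf);
    const double ff = pf - fb0;
    const int mb0 = (int)std::floor(pm) - 1;
    for (int fo = 0; fo < 2; ++fo) {
      const int fb = fb0 + fo;
      if (fb < 0 || fb >= nbins) continue;
      const double wf = fo == 0 ? 1.0 - ff : ff;
      if (wf == 0.0) continue;
      for (int mo = 0; mo < 4; ++mo) {
        const int mb = mb0 + mo;
        if (mb < 0 || mb >= nbins) continue;
        P[(size_t)fb * nbins + mb] += wf * beta3w(pm - mb);
      }
    }
  }
  const double inv_n = 1.0 / nused;
  std::vector<double> Pf(nbins, 0.0), Pm(nbins, 0.0);
  for (int a = 0; a < nbins; ++a)
    for (int b = 0; b < nbins; ++b) {
      P[(size_t)a * nbins + b] *= inv_n;
      Pf[a] += P[(size_t)a * nbins + b];
      Pm[b] += P[(size_t)a * nbins + b];
    }
  double mi = 0.0;
  for (int a = 0; a < nbins; ++a)
    for (int b = 0; b < nbins; ++b) {
      const double p = P[(size_t)a * nbins + b];
      if (p > 1e-300 && Pf[a] > 1e-300 && Pm[b] > 1e-300)
        mi += p * std::log(p / (Pf[a] * Pm[b]));
    }
  NumericVector grad(n);
  if (want_grad) {
    // dMI/dm_i = (1/n) sum_{fb,mb} wf * beta3'(pm_i - mb)/dm * log(P/Pm)
    for (int i = 0; i < n; ++i) {
      if (!R_finite(pf_pos[i])) { grad[i] = 0.0; continue; }
      const double pf = pf_pos[i], pm = pm_pos[i];
      const int fb0 = (int)std::floor(pf);
      const double ff = pf - fb0;
      const int mb0 = (int)std::floor(pm) - 1;
      double g = 0.0;
      for (int fo = 0; fo < 2; ++fo) {
        const int fb = fb0 + fo;
        if (fb < 0 || fb >= nbins) continue;
        const double wf = fo == 0 ? 1.0 - ff : ff;
        if (wf == 0.0) continue;
        for (int mo = 0; mo < 4; ++mo) {
          const int mb = mb0 + mo;
          if (mb < 0 || mb >= nbins) continue;
          const double p = P[(size_t)fb * nbins + mb];
          if (p <= 1e-300 || Pm[mb] <= 1e-300) continue;
          g += wf * beta3d(pm - mb) * std::log(p / Pm[mb]);
        }
      }
      grad[i] = g * inv_n / dm;
    }
  }
  return List::create(_["mi"] = mi, _["grad"] = grad, _["n"] = nused);
}
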