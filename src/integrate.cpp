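#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Centred sigmoid firing function; slope at the origin is r/4.
static inline double sigm(double v, double r) {
  return 1.0 / (1.0 + std::exp(-r * v)) - 0.5;
}

// Derivative field of the coupled three-population neural mass network.
// State layout per source i (6 states): vE, zE, vP, zP, vI, zI.
// H: n x 5 effective intrinsic gains; TE, TI in seconds; AF, AB: n x n
// effective extrinsic coupling strengths (already masked and scaled);
// u: per-source exogenous input held constant over a step.
static void deriv(const double *x, double *dx, int n,
                  const double *H, const double *TE, const double *TI,
                  const double *AF, const double *AB, double slope,
                  const double *u, double *sP) {
  for (int j = 0; j < n; ++j) sP[j] = sigm(x[6 * j + 2], slope);
  for (int i = 0; i < n; ++i) {
    const double te = TE[i], ti = TI[i];
    const double te2 = te * te, ti2 = ti * ti;
    const double vE = x[6 * i], zE = x[6 * i + 1];
    const double vP = x[6 * i + 2], zP = x[6 * i + 3];
    const double vI = x[6 * i + 4], zI = x[6 * i + 5];
    double extE = 0.0, extP = 0.0;
    for (int j = 0; j < n; ++j) {
      extE += AF[i + n * j] * sP[j];
      extP += AB[i + n * j] * sP[j];
    }
    // H1: E->P, H2: P->E, H3: P->I (excitatory); H4: I->P, H5: I->I
    const double h1 = H[i], h2 = H[i + n], h3 = H[i + 2 * n];
    const double h4 = H[i + 3 * n], h5 = H[i + 4 * n];
    dx[6 * i]     = zE;
    dx[6 * i + 1] = (h2 * sP[i] + extE + u[i]) / te2 - 2.0 * zE / te - vE / te2;
    dx[6 * i + 2] = zP;
    dx[6 * i + 3] = (h1 * sigm(vE, slope) - h4 * sigm(vI, slope) + extP) / te2
                    - 2.0 * zP / te - vP / te2;
    dx[6 * i + 4] = zI;
    dx[6 * i + 5] = (h3 * sP[i] - h5 * sigm(vI, slope)) / ti2
                    - 2.0 * zI / ti - vI / ti2;
  }
}

// Fixed-step RK4 integration with zero-order-hold input.
// U: n x nt input matrix; returns pyramidal potentials (n x nt), the final
// full state, and the 1-based step index of divergence (0 if none).
// [[Rcpp::export]]
List nm_integrate_cpp(NumericMatrix H, NumericVector TE, NumericVector TI,
                      NumericMatrix AF, NumericMatrix AB, double slope,
                      NumericMatrix U, double dt, NumericVector x0) {
  const int n = H.nrow(), nt = U.ncol(), ns = 6 * n;
  if ((int)x0.size() != ns) stop("x0 must have 6 states per source");
  NumericMatrix out(n, nt);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), xt(ns), sP(n);
  int diverged_at = 0;
  for (int t = 0; t < nt; ++t) {
    const double *u = &U(0, t);
    deriv(x.data(), k1.data(), n, H.begin(), TE.begin(), TI.begin(),
          AF.begin(), AB.begin(), slope, u, sP.data());
    for (int s = 0; s < ns; ++s) xt[s] = x[s] + 0.5 * dt * k1[s];
    deriv(xt.data(), k2.data(), n, H.begin(), TE.begin(), TI.begin(),
          AF.begin(), AB.begin(), slope, u, sP.data());
    for (int s = 0; s < ns; ++s) xt[s] = x[s] + 0.5 * dt * k2[s];
    deriv(xt.data(), k3.data(), n, H.begin(), TE.begin(), TI.begin(),
          AF.begin(), AB.begin(), slope, u, sP.data());
    for (int s = 0; s < ns; ++s) xt[s] = x[s] + dt * k3[s];
    deriv(xt.data(), k4.data(), n, H.begin(), TE.begin(), TI.begin(),
          AF.begin(), AB.begin(), slope, u, sP.data());
    double amax = 0.0;
    for (int s = 0; s < ns; ++s) {
      x[s] += dt / 6.0 * (k1[s] + 2.0 * k2[s] + 2.0 * k3[s] + k4[s]);
      if (std::fabs(x[s]) > amax) amax = std::fabs(x[s]);
    }
    if (!std::isfinite(amax) || amax > 1e6) { diverged_at = t + 1; break; }
    for (int i = 0; i < n; ++i) out(i, t) = x[6 * i + 2];
  }
  return List::create(_["out"] = out,
                      _["xfinal"] = NumericVector(x.begin(), x.end()),
                      _["diverged_at"] = diverged_at);
}
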