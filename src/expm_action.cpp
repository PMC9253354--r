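#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Action of the mean-field matrix exponential, exp(A t) %*% n0, for the
// stage/generation block matrix A of the multi-stage model with generations:
//   diagonal          -(lambda_g + mu_g)
//   within-generation lambda_g on the first subdiagonal of each block
//   between blocks    2 * lambda_{g-1} at (first stage of g, last of g-1).
//
// Computed by uniformization: with theta >= max(lambda_g + mu_g),
// P = I + A/theta is componentwise nonnegative, so
//   exp(A dt) v = sum_k e^{-m} m^k/k! P^k v,   m = theta * dt,
// is a sum of nonnegative terms -- no cancellation.  The Poisson
// coefficient is carried in log space and the iterate P^k v is renormalised
// by powers of two, so arbitrarily large m is handled in one series pass
// (every term is bounded by the final result, which the caller guarantees
// is inside double range or accepts as non-finite).  Columns from the first
// non-finite state onwards are filled with NA.

// applies P = I + A/theta and returns max(out)
static inline double apply_P(const std::vector<int> &off,
                             const IntegerVector &Ng,
                             const NumericVector &lambda,
                             const NumericVector &mu,
                             double theta,
                             const std::vector<double> &v,
                             std::vector<double> &out) {
  const int G = Ng.size();
  double vmax = 0.0;
  for (int g = 0; g < G; ++g) {
    const double lg = lambda[g] / theta, dg = 1.0 - (lambda[g] + mu[g]) / theta;
    const int o = off[g], n = Ng[g];
    double first = v[o] * dg;
    if (g > 0)
      first += (2.0 * lambda[g - 1] / theta) * v[off[g - 1] + Ng[g - 1] - 1];
    out[o] = first;
    if (first > vmax) vmax = first;
    for (int j = 1; j < n; ++j) {
      const double acc = v[o + j] * dg + lg * v[o + j - 1];
      out[o + j] = acc;
      if (acc > vmax) vmax = acc;
    }
  }
  return vmax;
}

// [[Rcpp::export]]
NumericMatrix cpp_msg_expm_action(IntegerVector Ng, NumericVector lambda,
                                  NumericVector mu, NumericVector n0,
                                  NumericVector times) {
  const int G = Ng.size();
  if (lambda.size() != G || mu.size() != G)
    stop("Ng, lambda and mu must have one entry per generation");
  std::vector<int> off(G);
  int dim = 0;
  for (int g = 0; g < G; ++g) {
    if (Ng[g] < 1) stop("every generation needs at least one stage");
    off[g] = dim;
    dim += Ng[g];
  }
  if (n0.size() != dim) stop("n0 has wrong length");
  const int nt = times.size();
  NumericMatrix res(dim, nt);

  double theta = 0.0;
  for (int g = 0; g < G; ++g) theta = std::max(theta, lambda[g] + mu[g]);
  std::vector<double> v(n0.begin(), n0.end()), w(dim), acc(dim), tmp(dim);
  const double LOG2 = std::log(2.0);

  double t_prev = 0.0;
  bool dead = false;
  for (int it = 0; it < nt; ++it) {
    double dt = times[it] - t_prev;
    if (dt < 0) stop("times must be non-decreasing");
    if (!dead && dt > 0 && theta > 0) {
      const double m = theta * dt;
      const int kmax = (int)(m + 12.0 * std::sqrt(m + 1.0) + 40.0);
      double lc = -m;        // log of e^{-m} m^k / k!, plus w rescalings
      double f0 = std::exp(lc);
      double amax = 0.0, wmax = 0.0;
      for (int i = 0; i < dim; ++i) {
        w[i] = v[i];
        acc[i] = f0 * v[i];
        amax = std::max(amax, acc[i]);
        wmax = std::max(wmax, w[i]);
      }
      for (int k = 1; k <= kmax; ++k) {
        wmax = apply_P(off, Ng, lambda, mu, theta, w, tmp);
        w.swap(tmp);
        lc += std::log(m / k);
        if (wmax > 1e250 || (wmax > 0 && wmax < 1e-250)) {
          int e;
          std::frexp(wmax, &e);
          double s = std::ldexp(1.0, -e);
          for (int i = 0; i < dim; ++i) w[i] *= s;
          lc += e * LOG2;
          wmax *= s;
        }
        const double f = std::exp(lc);
        if (f > 0 && f * wmax > 0) {
          double anew = amax;
          for (int i = 0; i < dim; ++i) {
            acc[i] += f * w[i];
            if (acc[i] > anew) anew = acc[i];
          }
          amax = anew;
        }
        if ((double)k > m && f * wmax < 1e-16 * (amax + 1e-300)) break;
      }
      for (int i = 0; i < dim; ++i) {
        v[i] = acc[i];
        if (!std::isfinite(v[i])) dead = true;
      }
    }
    for (int i = 0; i < dim; ++i)
      res(i, it) = dead ? NA_REAL : v[i];
    t_prev = times[it];
  }
  return res;
}
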