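// Contribution-evaluator kernels for the incident-cases likelihood.
//
// The quadrature layout (growth-rate nodes on a per-size scaled
// Gauss-Laguerre rule, transition-time nodes on the exit-time quantile
// transform) is constructed in R; these kernels evaluate the triple loop
// (size point x r-node x t-node x attended screens) without intermediate
// allocations.  All model mathematics mirrors the R-level growth and
// sensitivity functions.
#include <Rcpp.h>
using namespace Rcpp;

static inline double lesion_size(double age, double r, double k, double pw,
                                 double l0pw, double ipw) {
  return std::pow(k * age * pw / r + l0pw, ipw);
}

// product over attended screens of miss probabilities (and the detection
// screen handled by the caller); base ascending, screens before onset break
static inline double hist_factor(double age_det, double tt, double r,
                                 const double* base, int ns, double dl,
                                 bool skip_zero,
                                 double b0, double b1, double b2,
                                 double k, double pw, double l0pw,
                                 double ipw, double d0) {
  double h = 1.0;
  for (int s = 0; s < ns; ++s) {
    if (skip_zero && base[s] == 0.0 && dl == 0.0) continue;
    const double age = age_det - (base[s] + dl);
    if (age < 0.0) break;
    const double l = lesion_size(age, r, k, pw, l0pw, ipw);
    double lin = b0 + b1 * l;
    if (age >= tt) lin += b2 * d0 * std::exp((age - tt) / (3.0 * r));
    h /= 1.0 + std::exp(lin);
  }
  return h;
}

// invasive detection classes (screen-detected / symptomatic)
// [[Rcpp::export(name = ".eval_invasive_cpp")]]
NumericVector eval_invasive_cpp(NumericVector v, NumericVector delta,
                                NumericVector base,
                                NumericMatrix rmat, NumericMatrix wmat,
                                NumericVector xt, NumericVector wt,
                                bool detection, bool absorb,
                                double beta, double k, double l0, double v0,
                                double eta_T, double eta_D, double eta_I,
                                double b0, double b1, double b2) {
  const int m = v.size(), n_r = rmat.nrow(), n_t = xt.size(),
    ns = base.size();
  const double pw = 1.0 - beta, ipw = 1.0 / pw;
  const double l0pw = std::pow(l0, pw);
  const double pw2 = 2.0 - beta, ipw2 = 1.0 / pw2;
  const double l0pw2 = std::pow(l0, pw2);
  const double d0 = std::cbrt(6.0 * v0 / M_PI);
  const double cc = eta_D / eta_T;
  const double etaDT = eta_D + eta_T;
  NumericVector out(m);
  std::vector<double> mlog1p(n_t);
  for (int i = 0; i < n_t; ++i) mlog1p[i] = -std::log1p(-xt[i]);
  const double* bp = ns ? &base[0] : nullptr;
  for (int p = 0; p < m; ++p) {
    const double vp = v[p], dl = delta[p];
    const double lvr = std::log(vp / v0);
    const double dcase = std::cbrt(6.0 * vp / M_PI);
    double acc = 0.0;
    for (int j = 0; j < n_r; ++j) {
      const double r = rmat(j, p), w_r = wmat(j, p);
      const double ti = r * lvr;
      double kern;
      if (detection) {
        kern = absorb ? r / vp
          : r * std::exp(-eta_I * r * (vp - v0)) / vp;
      } else {
        kern = absorb ? eta_I * r
          : eta_I * r * std::exp(-eta_I * r * (vp - v0));
      }
      double acc_t = 0.0;
      for (int i = 0; i < n_t; ++i) {
        const double phi_t = mlog1p[i] / (etaDT * r);
        const double l_t = std::pow(l0pw2 + k * pw2 * phi_t, ipw2);
        const double tt = r * (std::pow(l_t, pw) - l0pw) / (k * pw);
        const double ad = tt + ti;
        double h = ns ? hist_factor(ad, tt, r, bp, ns, dl, detection,
                                    b0, b1, b2, k, pw, l0pw, ipw, d0)
          : 1.0;
        if (detection) {
          const double l_det = lesion_size(ad, r, k, pw, l0pw, ipw);
          const double lin = b0 + b1 * l_det + b2 * dcase;
          h *= 1.0 / (1.0 + std::exp(-lin));
        }
        acc_t += wt[i] * h;
      }
      acc += w_r * kern * acc_t;
    }
    out[p] = acc / (1.0 + cc);
  }
  return out;
}

// DCIS detection classes; the survival factor is absorbed into the
// quadrature weights in R
// [[Rcpp::export(name = ".eval_dcis_cpp")]]
NumericVector eval_dcis_cpp(NumericVector l, NumericVector delta,
                            NumericVector base,
                            NumericMatrix rmat, NumericMatrix wmat,
                            bool detection,
                            double beta, double k, double l0,
                            double eta_D, double b0, double b1) {
  const int m = l.size(), n_r = rmat.nrow(), ns = base.size();
  const double pw = 1.0 - beta, ipw = 1.0 / pw;
  const double l0pw = std::pow(l0, pw);
  NumericVector out(m);
  const double* bp = ns ? &base[0] : nullptr;
  for (int p = 0; p < m; ++p) {
    const double lp = l[p], dl = delta[p];
    const double lpw = std::pow(lp, pw);
    const double sens_det = detection
      ? 1.0 / (1.0 + std::exp(-(b0 + b1 * lp))) : 1.0;
    double acc = 0.0;
    for (int j = 0; j < n_r; ++j) {
      const double r = rmat(j, p), w_r = wmat(j, p);
      const double g = r * (lpw - l0pw) / (k * pw);
      const double kern = detection ? r * std::pow(lp, -beta) / k
        : eta_D * r * lp * std::pow(lp, -beta) / k;
      double h = ns ? hist_factor(g, R_PosInf, r, bp, ns, dl, detection,
                                  b0, b1, 0.0, k, pw, l0pw, ipw, 1.0)
        : 1.0;
      acc += w_r * kern * h * sens_det;
    }
    out[p] = acc;
  }
  return out;
}
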