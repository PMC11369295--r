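// BB1 two-parameter Archimedean copula: CDF, log-density, conditional
// h-function and its inverse, plus the joint Gaussian-margin likelihood
// used by the per-gene fits. Everything works on the log scale; the
// Clayton-like parameter is phi > 0, the Gumbel-like parameter theta >= 1.
#include <Rcpp.h>
using namespace Rcpp;

static const double U_EPS = 1e-12;

// log(u^-phi - 1), stable for u near 0 and near 1
static inline double log_t(double u, double phi) {
  double a = -phi * std::log(u); // >= 0
  if (a > 35.0) return a;
  return std::log(std::expm1(a));
}

static inline double clamp_u(double u) {
  if (u < U_EPS) return U_EPS;
  if (u > 1.0 - U_EPS) return 1.0 - U_EPS;
  return u;
}

// log C(u1, u2)
static inline double bb1_logcdf_1(double u1, double u2, double phi, double theta) {
  double lt1 = log_t(u1, phi), lt2 = log_t(u2, phi);
  double lx1 = theta * lt1, lx2 = theta * lt2;
  double m = std::max(lx1, lx2);
  double ls = m + std::log(std::exp(lx1 - m) + std::exp(lx2 - m));
  double lw = ls / theta;
  // log(w + 1) = lw + log1p(exp(-lw)) guards large w
  double l1pw = (lw > 35.0) ? lw : std::log1p(std::exp(lw));
  return (-1.0 / phi) * l1pw;
}

// log density log c(u1,u2) = log d2C/du1du2
static inline double bb1_logpdf_1(double u1, double u2, double phi, double theta) {
  double lt1 = log_t(u1, phi), lt2 = log_t(u2, phi);
  double lx1 = theta * lt1, lx2 = theta * lt2;
  double m = std::max(lx1, lx2);
  double ls = m + std::log(std::exp(lx1 - m) + std::exp(lx2 - m));
  double lw = ls / theta;
  double l1pw = (lw > 35.0) ? lw : std::log1p(std::exp(lw));
  // B = (1 + 1/phi) * w / theta + (1 - 1/theta) * (w + 1), on the log scale
  double la = std::log1p(1.0 / phi) + lw - std::log(theta);
  double lB;
  if (theta == 1.0) {
    lB = la;
  } else {
    double lb = std::log1p(-1.0 / theta) + l1pw;
    double mm = std::max(la, lb);
    lB = mm + std::log(std::exp(la - mm) + std::exp(lb - mm));
  }
  return std::log(phi) + std::log(theta) +
    (-1.0 / phi - 2.0) * l1pw + (1.0 / theta - 2.0) * ls + lB +
    (theta - 1.0) * (lt1 + lt2) - (phi + 1.0) * (std::log(u1) + std::log(u2));
}

// h(u2 | u1) = dC/du1, the conditional CDF of U2 given U1 = u1
static inline double bb1_hfunc_1(double u1, double u2, double phi, double theta) {
  double lt1 = log_t(u1, phi), lt2 = log_t(u2, phi);
  double lx1 = theta * lt1, lx2 = theta * lt2;
  double m = std::max(lx1, lx2);
  double ls = m + std::log(std::exp(lx1 - m) + std::exp(lx2 - m));
  double lw = ls / theta;
  double l1pw = (lw > 35.0) ? lw : std::log1p(std::exp(lw));
  double lh = (-1.0 / phi - 1.0) * l1pw + (1.0 / theta - 1.0) * ls +
    (theta - 1.0) * lt1 - (phi + 1.0) * std::log(u1);
  return std::exp(lh);
}

// [[Rcpp::export]]
NumericVector cpp_bb1_cdf(NumericVector u1, NumericVector u2, double phi, double theta) {
  R_xlen_t n = u1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double a = u1[i], b = u2[i];
    if (a <= 0.0 || b <= 0.0) { out[i] = 0.0; continue; }
    if (a >= 1.0 && b >= 1.0) { out[i] = 1.0; continue; }
    if (a >= 1.0) { out[i] = b; continue; }
    if (b >= 1.0) { out[i] = a; continue; }
    out[i] = std::exp(bb1_logcdf_1(a, b, phi, theta));
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_bb1_logpdf(NumericVector u1, NumericVector u2, double phi, double theta) {
  R_xlen_t n = u1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = bb1_logpdf_1(clamp_u(u1[i]), clamp_u(u2[i]), phi, theta);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_bb1_hfunc(NumericVector u1, NumericVector u2, double phi, double theta) {
  R_xlen_t n = u1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = bb1_hfunc_1(clamp_u(u1[i]), clamp_u(u2[i]), phi, theta);
  return out;
}

// Invert q = h(u2 | u1) in u2 by monotone bisection to |interval| < tol
// [[Rcpp::export]]
NumericVector cpp_bb1_hinv(NumericVector u1, NumericVector q, double phi, double theta,
                           double tol = 1e-10) {
  R_xlen_t n = u1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double a = clamp_u(u1[i]), qq = q[i];
    double lo = U_EPS, hi = 1.0 - U_EPS;
    for (int it = 0; it < 200 && (hi - lo) > tol; ++it) {
      double mid = 0.5 * (lo + hi);
      if (bb1_hfunc_1(a, mid, phi, theta) < qq) lo = mid; else hi = mid;
    }
    out[i] = 0.5 * (lo + hi);
  }
  return out;
}

// ---- joint Gaussian-margin likelihood -------------------------------------
// Parameter vector for k design columns:
//   par[0..k-1]   coefficients, margin 1 (log SAT)
//   par[k]        log sigma1
//   par[k+1..2k]  coefficients, margin 2 (SAT/TAT)
//   par[2k+1]     log sigma2
//   par[2k+2]     log phi
//   par[2k+3]     log(theta - 1)
static double joint_nll_impl(const double* par, const NumericVector& y1,
                             const NumericVector& y2, const NumericMatrix& X) {
  const int n = X.nrow(), k = X.ncol();
  const double s1 = std::exp(par[k]), s2 = std::exp(par[2 * k + 1]);
  const double phi = std::exp(par[2 * k + 2]);
  const double theta = 1.0 + std::exp(par[2 * k + 3]);
  if (!R_finite(s1) || !R_finite(s2) || !R_finite(phi) || !R_finite(theta) ||
      phi <= 0.0) return 1e10;
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double m1 = 0.0, m2 = 0.0;
    for (int j = 0; j < k; ++j) {
      double x = X(i, j);
      m1 += par[j] * x;
      m2 += par[k + 1 + j] * x;
    }
    double z1 = (y1[i] - m1) / s1, z2 = (y2[i] - m2) / s2;
    double u1 = clamp_u(R::pnorm(z1, 0.0, 1.0, 1, 0));
    double u2 = clamp_u(R::pnorm(z2, 0.0, 1.0, 1, 0));
    double ll = bb1_logpdf_1(u1, u2, phi, theta) +
      R::dnorm(y1[i], m1, s1, 1) + R::dnorm(y2[i], m2, s2, 1);
    if (!R_finite(ll)) return 1e10;
    nll -= ll;
  }
  return nll;
}

// [[Rcpp::export]]
double cpp_joint_nll(NumericVector par, NumericVector y1, NumericVector y2,
                     NumericMatrix X) {
  return joint_nll_impl(par.begin(), y1, y2, X);
}

// partial derivatives of the BB1 log-density with respect to u1 and u2
static inline void bb1_dlogc_du(double u1, double u2, double phi, double theta,
                                double* d1, double* d2) {
  double lt1 = log_t(u1, phi), lt2 = log_t(u2, phi);
  double lx1 = theta * lt1, lx2 = theta * lt2;
  double m = std::max(lx1, lx2);
  double ls = m + std::log(std::exp(lx1 - m) + std::exp(lx2 - m));
  double lw = ls / theta;
  double w = std::exp(lw);
  double l1pw = (lw > 35.0) ? lw : std::log1p(w);
  double w_over_1pw = std::exp(lw - l1pw);
  // B and K as in the density; dB/dw = K
  double K = (1.0 + 1.0 / phi) / theta + (1.0 - 1.0 / theta);
  double B = (1.0 + 1.0 / phi) * w / theta + (1.0 - 1.0 / theta) * (w + 1.0);
  // r = d log t / du = -phi u^{-phi-1} / t = -phi / (u * (1 - u^phi))
  double r1 = -phi / (u1 * (-std::expm1(phi * std::log(u1))));
  double r2 = -phi / (u2 * (-std::expm1(phi * std::log(u2))));
  double q1 = std::exp(lx1 - ls) * theta * r1; // (dx1/du1) / s
  double q2 = std::exp(lx2 - ls) * theta * r2;
  double cw = (-1.0 / phi - 2.0) * w_over_1pw / theta +
              (1.0 / theta - 2.0) +
              K * (w / theta) / B;
  *d1 = cw * q1 + (theta - 1.0) * r1 - (phi + 1.0) / u1;
  *d2 = cw * q2 + (theta - 1.0) * r2 - (phi + 1.0) / u2;
}

// gradient of the negative log-likelihood: analytic in the marginal
// coefficients and log-sigmas, central differences in the two copula
// parameters
// [[Rcpp::export]]
NumericVector cpp_joint_nll_grad(NumericVector par, NumericVector y1,
                                 NumericVector y2, NumericMatrix X) {
  const int n = X.nrow(), k = X.ncol();
  const int p = par.size();
  NumericVector g(p);
  const double s1 = std::exp(par[k]), s2 = std::exp(par[2 * k + 1]);
  const double phi = std::exp(par[2 * k + 2]);
  const double theta = 1.0 + std::exp(par[2 * k + 3]);
  for (int i = 0; i < n; ++i) {
    double m1 = 0.0, m2 = 0.0;
    for (int j = 0; j < k; ++j) {
      double x = X(i, j);
      m1 += par[j] * x;
      m2 += par[k + 1 + j] * x;
    }
    double z1 = (y1[i] - m1) / s1, z2 = (y2[i] - m2) / s2;
    double u1 = clamp_u(R::pnorm(z1, 0.0, 1.0, 1, 0));
    double u2 = clamp_u(R::pnorm(z2, 0.0, 1.0, 1, 0));
    double d1, d2;
    bb1_dlogc_du(u1, u2, phi, theta, &d1, &d2);
    double pdf1 = R::dnorm(z1, 0.0, 1.0, 0), pdf2 = R::dnorm(z2, 0.0, 1.0, 0);
    // d loglik / d m: copula term via u, Gaussian term z/s
    double a1 = d1 * pdf1 * (-1.0 / s1) + z1 / s1;
    double a2 = d2 * pdf2 * (-1.0 / s2) + z2 / s2;
    for (int j = 0; j < k; ++j) {
      double x = X(i, j);
      g[j] -= a1 * x;
      g[k + 1 + j] -= a2 * x;
    }
    // d loglik / d log sigma
    g[k] -= d1 * pdf1 * (-z1) + (z1 * z1 - 1.0);
    g[2 * k + 1] -= d2 * pdf2 * (-z2) + (z2 * z2 - 1.0);
  }
  // copula parameters by central differences of the full objective
  std::vector<double> w(par.begin(), par.end());
  for (int j = 2 * k + 2; j < p; ++j) {
    double h = 1e-6 * std::max(1.0, std::fabs(w[j]));
    double orig = w[j];
    w[j] = orig + h;
    double fp = joint_nll_impl(w.data(), y1, y2, X);
    w[j] = orig - h;
    double fm = joint_nll_impl(w.data(), y1, y2, X);
    w[j] = orig;
    g[j] = (fp - fm) / (2.0 * h);
  }
  return g;
}

// pure central-difference gradient, kept as an independent cross-check
// [[Rcpp::export]]
NumericVector cpp_joint_nll_grad_fd(NumericVector par, NumericVector y1,
                                    NumericVector y2, NumericMatrix X) {
  const int p = par.size();
  std::vector<double> w(par.begin(), par.end());
  NumericVector g(p);
  for (int j = 0; j < p; ++j) {
    double h = 1e-6 * std::max(1.0, std::fabs(w[j]));
    double orig = w[j];
    w[j] = orig + h;
    double fp = joint_nll_impl(w.data(), y1, y2, X);
    w[j] = orig - h;
    double fm = joint_nll_impl(w.data(), y1, y2, X);
    w[j] = orig;
    g[j] = (fp - fm) / (2.0 * h);
  }
  return g;
}

// observed information: central differences of the gradient, symmetrized
// [[Rcpp::export]]
NumericMatrix cpp_joint_nll_hess(NumericVector par, NumericVector y1,
                                 NumericVector y2, NumericMatrix X) {
  const int p = par.size();
  NumericMatrix H(p, p);
  NumericVector w = clone(par);
  for (int j = 0; j < p; ++j) {
    double h = 1e-5 * std::max(1.0, std::fabs(w[j]));
    double orig = w[j];
    w[j] = orig + h;
    NumericVector gp = cpp_joint_nll_grad(w, y1, y2, X);
    w[j] = orig - h;
    NumericVector gm = cpp_joint_nll_grad(w, y1, y2, X);
    w[j] = orig;
    for (int i = 0; i < p; ++i) H(i, j) = (gp[i] - gm[i]) / (2.0 * h);
  }
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < i; ++j) {
      double v = 0.5 * (H(i, j) + H(j, i));
      H(i, j) = v; H(j, i) = v;
    }
  return H;
}
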