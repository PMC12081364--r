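// Analytic compartmental disposition and FOCE/Laplace marginal likelihood.
//
// Concentrations are superpositions of closed-form constant-rate-infusion
// responses of a 1/2/3-compartment mammillary model with first-order
// elimination from the central compartment.  The FOCE objective is the
// per-subject Laplace approximation at the conditional mode of the random
// effects, with the Gauss-Newton (J'WJ) curvature and residual variance
// evaluated at the conditional prediction (interaction).

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659472811;

// Exponents and bolus coefficients (per unit amount) of the disposition
// polyexponential: C(t) = amount * sum_m coef[m] * exp(-lam[m] t).
// th = {cl, vc, q, vp, q2, vp2}.  Degenerate q <= 0 collapses to fewer
// compartments (avoids 0/0 in the two-compartment coefficients).
static void exp_coefs(int ncmt, const double* th, double* lam, double* coef,
                      int& nexp) {
  double cl = th[0], vc = th[1], q = th[2], vp = th[3], q2 = th[4],
         vp2 = th[5];
  double k10 = cl / vc;
  if (ncmt <= 1 || q <= 0.0) {
    nexp = 1;
    lam[0] = k10;
    coef[0] = 1.0 / vc;
    return;
  }
  double k12 = q / vc, k21 = q / vp;
  if (ncmt == 2 || q2 <= 0.0) {
    double s = k10 + k12 + k21, pr = k10 * k21;
    double disc = s * s - 4.0 * pr;
    if (disc < 0.0) disc = 0.0;
    disc = std::sqrt(disc);
    double l1 = 0.5 * (s + disc), l2 = 0.5 * (s - disc);
    nexp = 2;
    lam[0] = l1;
    lam[1] = l2;
    coef[0] = (k21 - l1) / ((l2 - l1) * vc);
    coef[1] = (k21 - l2) / ((l1 - l2) * vc);
    return;
  }
  // three compartments: roots of l^3 - a1 l^2 + a2 l - a3 via the
  // trigonometric method (all roots real/positive for a compartmental model)
  double k13 = q2 / vc, k31 = q2 / vp2;
  double a1 = k10 + k12 + k13 + k21 + k31;
  double a2 = k10 * k21 + k10 * k31 + k12 * k31 + k13 * k21 + k21 * k31;
  double a3 = k10 * k21 * k31;
  double p = a2 - a1 * a1 / 3.0;
  double qd = -2.0 * a1 * a1 * a1 / 27.0 + a1 * a2 / 3.0 - a3;
  double m = 2.0 * std::sqrt(-p / 3.0);
  double arg = 3.0 * qd / (p * m);
  if (arg > 1.0) arg = 1.0;
  if (arg < -1.0) arg = -1.0;
  double th3 = std::acos(arg) / 3.0;
  double l[3];
  for (int k = 0; k < 3; k++)
    l[k] = m * std::cos(th3 - 2.0 * M_PI * k / 3.0) + a1 / 3.0;
  std::sort(l, l + 3, std::greater<double>());
  nexp = 3;
  for (int mi = 0; mi < 3; mi++) {
    lam[mi] = l[mi];
    double denom = vc;
    for (int j = 0; j < 3; j++)
      if (j != mi) denom *= (l[j] - l[mi]);
    coef[mi] = (k21 - l[mi]) * (k31 - l[mi]) / denom;
  }
}

// Central concentration at time t from sorted infusion segments
// (start ss, duration sd, rate sr).  -expm1(-l*win)/l is stable as l -> 0.
static double conc_point(double t, const double* ss, const double* sd,
                         const double* sr, int nseg, const double* lam,
                         const double* coef, int nexp) {
  double c = 0.0;
  for (int s = 0; s < nseg; s++) {
    if (ss[s] >= t) break;
    double end = ss[s] + sd[s];
    double te = t < end ? t : end;
    double win = te - ss[s], tail = t - te;
    for (int m = 0; m < nexp; m++) {
      double l = lam[m];
      c += sr[s] * coef[m] * (-std::expm1(-l * win) / l) * std::exp(-l * tail);
    }
  }
  return c;
}

// [[Rcpp::export]]
NumericVector cpp_conc_profile(NumericVector times, NumericVector seg_start,
                               NumericVector seg_dur, NumericVector seg_rate,
                               NumericVector theta, int ncmt) {
  double th[6] = {0, 0, 0, 0, 0, 0};
  for (int i = 0; i < theta.size() && i < 6; i++) th[i] = theta[i];
  double lam[3], coef[3];
  int nexp;
  exp_coefs(ncmt, th, lam, coef, nexp);
  int nt = times.size(), ns = seg_start.size();
  NumericVector out(nt);
  for (int j = 0; j < nt; j++)
    out[j] = conc_point(times[j], seg_start.begin(), seg_dur.begin(),
                        seg_rate.begin(), ns, lam, coef, nexp);
  return out;
}

// Many parameter sets (rows of `pars`, columns cl vc q vp [q2 vp2]) on one
// design; returns nrow(pars) x length(times).  Used by simulation (VPC/NPDE).
// [[Rcpp::export]]
NumericMatrix cpp_conc_profile_multi(NumericVector times,
                                     NumericVector seg_start,
                                     NumericVector seg_dur,
                                     NumericVector seg_rate,
                                     NumericMatrix pars, int ncmt) {
  int np = pars.nrow(), nt = times.size(), ns = seg_start.size();
  NumericMatrix out(np, nt);
  double th[6] = {0, 0, 0, 0, 0, 0};
  double lam[3], coef[3];
  int nexp;
  for (int i = 0; i < np; i++) {
    for (int k = 0; k < pars.ncol() && k < 6; k++) th[k] = pars(i, k);
    exp_coefs(ncmt, th, lam, coef, nexp);
    for (int j = 0; j < nt; j++)
      out(i, j) = conc_point(times[j], seg_start.begin(), seg_dur.begin(),
                             seg_rate.begin(), ns, lam, coef, nexp);
  }
  return out;
}

// ---------------------------------------------------------------------------
// FOCE engine
// ---------------------------------------------------------------------------

struct SubjView {
  const double* y;
  const double* t;
  const int* cens;
  int nobs;
  const double* ss;
  const double* sd;
  const double* sr;
  int nseg;
  double th[6];  // typical cl vc q vp q2 vp2 for this subject
};

static void subj_pred(const SubjView& S, int ncmt, const int* emap, int d,
                      const double* eta, double* f) {
  double th[6];
  for (int i = 0; i < 6; i++) th[i] = S.th[i];
  for (int k = 0; k < d; k++) th[emap[k]] *= std::exp(eta[k]);
  double lam[3], coef[3];
  int nexp;
  exp_coefs(ncmt, th, lam, coef, nexp);
  for (int j = 0; j < S.nobs; j++)
    f[j] = conc_point(S.t[j], S.ss, S.sd, S.sr, S.nseg, lam, coef, nexp);
}

// g(eta) = -2 log p(y | eta) - 2 log p(eta), all constants included so that
// the d = 0 case is the exact Gaussian -2 log-likelihood.
static double g_eval(const SubjView& S, int ncmt, const int* emap, int d,
                     const double* eta, const double* oinv, double logdetO,
                     double sa2, double sp2, double lloq, bool censlik,
                     double* f) {
  subj_pred(S, ncmt, emap, d, eta, f);
  double g = d * LOG2PI + logdetO;
  for (int k = 0; k < d; k++) g += eta[k] * eta[k] * oinv[k];
  for (int j = 0; j < S.nobs; j++) {
    if (!std::isfinite(f[j])) return R_PosInf;
    double v = sa2 + sp2 * f[j] * f[j];
    if (v < 1e-12) v = 1e-12;
    if (censlik && S.cens[j]) {
      double z = (lloq - f[j]) / std::sqrt(v);
      g += -2.0 * R::pnorm(z, 0.0, 1.0, 1, 1);
    } else {
      double r = S.y[j] - f[j];
      g += std::log(v) + LOG2PI + r * r / v;
    }
  }
  return g;
}

// Cholesky solve / log-determinant for the tiny (d <= 4) inner systems.
static bool chol_factor(double* A, int d) {
  for (int i = 0; i < d; i++) {
    for (int j = 0; j <= i; j++) {
      double s = A[i * d + j];
      for (int k = 0; k < j; k++) s -= A[i * d + k] * A[j * d + k];
      if (i == j) {
        if (s <= 0.0) return false;
        A[i * d + i] = std::sqrt(s);
      } else {
        A[i * d + j] = s / A[j * d + j];
      }
    }
  }
  return true;
}

static void chol_backsolve(const double* A, double* b, int d) {
  for (int i = 0; i < d; i++) {
    double s = b[i];
    for (int k = 0; k < i; k++) s -= A[i * d + k] * b[k];
    b[i] = s / A[i * d + i];
  }
  for (int i = d - 1; i >= 0; i--) {
    double s = b[i];
    for (int k = i + 1; k < d; k++) s -= A[k * d + i] * b[k];
    b[i] = s / A[i * d + i];
  }
}

// Newton search for the conditional mode of eta, quasi-Newton with the
// Gauss-Newton curvature and analytic gradient (Jacobian by central FD).
// On return: eta is the mode, f the conditional prediction, J the Jacobian
// at the mode, g_out the penalized -2 log-likelihood there.
static int inner_mode(const SubjView& S, int ncmt, const int* emap, int d,
                      const double* oinv, double logdetO, double sa2,
                      double sp2, double lloq, bool censlik, double* eta,
                      double* g_out, std::vector<double>& J,
                      std::vector<double>& f) {
  int n = S.nobs;
  const double h = 1e-4;
  std::vector<double> fp(n), fm(n), ftmp(n);
  double etatry[4];
  double g = g_eval(S, ncmt, emap, d, eta, oinv, logdetO, sa2, sp2, lloq,
                    censlik, f.data());
  if (!std::isfinite(g)) {
    for (int k = 0; k < d; k++) eta[k] = 0.0;
    g = g_eval(S, ncmt, emap, d, eta, oinv, logdetO, sa2, sp2, lloq, censlik,
               f.data());
    if (!std::isfinite(g)) {
      *g_out = g;
      return -1;
    }
  }
  int iter;
  for (iter = 0; iter < 300; iter++) {
    for (int k = 0; k < d; k++) {
      double e0 = eta[k];
      eta[k] = e0 + h;
      subj_pred(S, ncmt, emap, d, eta, fp.data());
      eta[k] = e0 - h;
      subj_pred(S, ncmt, emap, d, eta, fm.data());
      eta[k] = e0;
      for (int j = 0; j < n; j++)
        J[(size_t)k * n + j] = (fp[j] - fm[j]) / (2.0 * h);
    }
    double grad[4] = {0, 0, 0, 0}, H[16] = {0};
    for (int j = 0; j < n; j++) {
      double fj = f[j];
      double v = sa2 + sp2 * fj * fj;
      if (v < 1e-12) v = 1e-12;
      double w = 1.0 / v;
      if (censlik && S.cens[j]) {
        double sv = std::sqrt(v);
        double z = (lloq - fj) / sv;
        double lr = std::exp(R::dnorm(z, 0.0, 1.0, 1) -
                             R::pnorm(z, 0.0, 1.0, 1, 1));
        for (int k = 0; k < d; k++) {
          double Jk = J[(size_t)k * n + j];
          double dv = 2.0 * sp2 * fj * Jk;
          double dz = (-Jk * sv - (lloq - fj) * dv / (2.0 * sv)) * w;
          grad[k] += -2.0 * lr * dz;
        }
      } else {
        double r = S.y[j] - fj;
        for (int k = 0; k < d; k++) {
          double Jk = J[(size_t)k * n + j];
          double dv = 2.0 * sp2 * fj * Jk;
          grad[k] += dv * w - 2.0 * r * Jk * w - r * r * dv * w * w;
        }
      }
      for (int k = 0; k < d; k++)
        for (int l = 0; l <= k; l++)
          H[k * d + l] += 2.0 * w * J[(size_t)k * n + j] * J[(size_t)l * n + j];
    }
    for (int k = 0; k < d; k++) {
      grad[k] += 2.0 * oinv[k] * eta[k];
      H[k * d + k] += 2.0 * oinv[k];
    }
    for (int k = 0; k < d; k++)
      for (int l = k + 1; l < d; l++) H[k * d + l] = H[l * d + k];
    double gn = 0.0;
    for (int k = 0; k < d; k++) gn = std::max(gn, std::fabs(grad[k]));
    if (gn < 1e-9 * (1.0 + std::fabs(g))) break;
    // Levenberg-damped (quasi-)Newton step: increase the diagonal damping
    // until a damped step produces a strict decrease.
    double diagmean = 0.0;
    for (int k = 0; k < d; k++) diagmean += H[k * d + k];
    diagmean = std::max(diagmean / d, 1e-12);
    double lambda = 0.0;
    bool moved = false;
    for (int attempt = 0; attempt < 10 && !moved; attempt++) {
      double step[4], A[16];
      for (int k = 0; k < d; k++) step[k] = -grad[k];
      std::copy(H, H + d * d, A);
      for (int k = 0; k < d; k++) A[k * d + k] += lambda;
      if (!chol_factor(A, d)) {
        lambda = (lambda == 0.0) ? 1e-4 * diagmean : lambda * 10.0;
        continue;
      }
      chol_backsolve(A, step, d);
      double alpha = 1.0;
      for (int ls = 0; ls < 8; ls++) {
        for (int k = 0; k < d; k++) etatry[k] = eta[k] + alpha * step[k];
        double gt = g_eval(S, ncmt, emap, d, etatry, oinv, logdetO, sa2,
                           sp2, lloq, censlik, ftmp.data());
        if (std::isfinite(gt) && gt < g - 1e-14 * std::fabs(g)) {
          std::copy(etatry, etatry + d, eta);
          std::copy(ftmp.begin(), ftmp.end(), f.begin());
          g = gt;
          moved = true;
          break;
        }
        alpha *= 0.5;
      }
      if (!moved)
        lambda = (lambda == 0.0) ? 1e-4 * diagmean : lambda * 10.0;
    }
    if (!moved) break;
  }
  *g_out = g;
  return iter;
}

// Exact curvature term of the Laplace approximation: log det(Hess(g)/2)
// with the Hessian of the penalized -2 log-likelihood taken by central
// finite differences at the mode.  The Gauss-Newton form J'WJ + Omega^-1
// (which drops the variance-derivative terms of the interaction model)
// serves as the fallback when the exact Hessian is not positive definite.
// When `Lout` is non-null and the factorization succeeds, the lower
// Cholesky factor of Hess(g)/2 is stored there (used by the adaptive
// Gauss-Hermite refinement).
static double exact_logdet(const SubjView& S, int ncmt, const int* emap,
                           int d, const double* eta, const double* oinv,
                           double logdetO, double sa2, double sp2,
                           double lloq, bool censlik,
                           std::vector<double>& fbuf, bool& ok,
                           double* Lout = 0) {
  const double h = 1e-3;
  double H[16];
  double e[4];
  double g0 = g_eval(S, ncmt, emap, d, eta, oinv, logdetO, sa2, sp2, lloq,
                     censlik, fbuf.data());
  for (int a = 0; a < d; a++) {
    std::copy(eta, eta + d, e);
    e[a] = eta[a] + h;
    double gp = g_eval(S, ncmt, emap, d, e, oinv, logdetO, sa2, sp2, lloq,
                       censlik, fbuf.data());
    e[a] = eta[a] - h;
    double gm = g_eval(S, ncmt, emap, d, e, oinv, logdetO, sa2, sp2, lloq,
                       censlik, fbuf.data());
    H[a * d + a] = (gp - 2.0 * g0 + gm) / (h * h);
    for (int b = 0; b < a; b++) {
      double q[4];
      std::copy(eta, eta + d, e);
      e[a] = eta[a] + h;
      e[b] = eta[b] + h;
      q[0] = g_eval(S, ncmt, emap, d, e, oinv, logdetO, sa2, sp2, lloq,
                    censlik, fbuf.data());
      e[b] = eta[b] - h;
      q[1] = g_eval(S, ncmt, emap, d, e, oinv, logdetO, sa2, sp2, lloq,
                    censlik, fbuf.data());
      e[a] = eta[a] - h;
      q[2] = g_eval(S, ncmt, emap, d, e, oinv, logdetO, sa2, sp2, lloq,
                    censlik, fbuf.data());
      e[b] = eta[b] + h;
      q[3] = g_eval(S, ncmt, emap, d, e, oinv, logdetO, sa2, sp2, lloq,
                    censlik, fbuf.data());
      H[a * d + b] = H[b * d + a] = (q[0] - q[1] + q[2] - q[3]) /
                                    (4.0 * h * h);
    }
  }
  bool finite = true;
  for (int k = 0; k < d * d; k++)
    if (!std::isfinite(H[k])) finite = false;
  if (finite) {
    double A[16];
    // Hess(g)/2 is the matrix whose determinant enters the -2 log scale
    for (int k = 0; k < d * d; k++) A[k] = H[k] / 2.0;
    double Acopy[16];
    std::copy(A, A + d * d, Acopy);
    if (chol_factor(Acopy, d)) {
      ok = true;
      double ld = 0.0;
      for (int k = 0; k < d; k++) ld += std::log(Acopy[k * d + k]);
      if (Lout) std::copy(Acopy, Acopy + d * d, Lout);
      return 2.0 * ld;
    }
  }
  ok = false;
  return 0.0;
}

// Adaptive Gauss-Hermite correction on top of the Laplace approximation:
// -2 log sum_k w_k exp(-(g(m + C z_k) - g(m))/2 + |z_k|^2/2) with
// C = (L')^{-1}, L the lower Cholesky factor of Hess(g)/2, nodes z_k the
// tensor grid of the 1-D rule (z, w normalized for N(0,1)).  Returns 0
// (i.e. falls back to pure Laplace) when a node evaluation fails.
static double agq_correction(const SubjView& S, int ncmt, const int* emap,
                             int d, const double* eta, const double* oinv,
                             double logdetO, double sa2, double sp2,
                             double lloq, bool censlik, const double* L,
                             double g0, const std::vector<double>& z,
                             const std::vector<double>& w,
                             std::vector<double>& fbuf) {
  int nn = (int)z.size();
  int K = 1;
  for (int k = 0; k < d; k++) K *= nn;
  std::vector<double> terms(K);
  double tmax = R_NegInf;
  double zz[4], x[4], e[4];
  for (int k = 0; k < K; k++) {
    int rem = k;
    double z2 = 0.0, lw = 0.0;
    for (int a = 0; a < d; a++) {
      int idx = rem % nn;
      rem /= nn;
      zz[a] = z[idx];
      z2 += zz[a] * zz[a];
      lw += std::log(w[idx]);
    }
    // x = (L')^{-1} z  (back substitution with the transposed factor)
    for (int i = d - 1; i >= 0; i--) {
      double s = zz[i];
      for (int j = i + 1; j < d; j++) s -= L[j * d + i] * x[j];
      x[i] = s / L[i * d + i];
    }
    for (int a = 0; a < d; a++) e[a] = eta[a] + x[a];
    double gk = g_eval(S, ncmt, emap, d, e, oinv, logdetO, sa2, sp2, lloq,
                       censlik, fbuf.data());
    if (!std::isfinite(gk)) return 0.0;
    terms[k] = lw - (gk - g0) / 2.0 + z2 / 2.0;
    if (terms[k] > tmax) tmax = terms[k];
  }
  double s = 0.0;
  for (int k = 0; k < K; k++) s += std::exp(terms[k] - tmax);
  return -2.0 * (tmax + std::log(s));
}

// Gauss-Newton curvature term log det(J'WJ + Omega^-1) at the mode.
static double foce_logdet(const SubjView& S, int d, const double* oinv,
                          double sa2, double sp2,
                          const std::vector<double>& J,
                          const std::vector<double>& f, bool& ok) {
  double M[16] = {0};
  int n = S.nobs;
  for (int j = 0; j < n; j++) {
    double v = sa2 + sp2 * f[j] * f[j];
    if (v < 1e-12) v = 1e-12;
    double w = 1.0 / v;
    for (int k = 0; k < d; k++)
      for (int l = 0; l <= k; l++)
        M[k * d + l] += w * J[(size_t)k * n + j] * J[(size_t)l * n + j];
  }
  for (int k = 0; k < d; k++) M[k * d + k] += oinv[k];
  for (int k = 0; k < d; k++)
    for (int l = k + 1; l < d; l++) M[k * d + l] = M[l * d + k];
  double A[16];
  std::copy(M, M + d * d, A);
  if (!chol_factor(A, d)) {
    std::copy(M, M + d * d, A);
    for (int k = 0; k < d; k++) A[k * d + k] += 1e-8 + 1e-6 * M[k * d + k];
    if (!chol_factor(A, d)) {
      ok = false;
      return 0.0;
    }
  }
  ok = true;
  double ld = 0.0;
  for (int k = 0; k < d; k++) ld += std::log(A[k * d + k]);
  return 2.0 * ld;
}

static SubjView make_view(int i, const NumericVector& y,
                          const NumericVector& tobs, const IntegerVector& cens,
                          const IntegerVector& optr, const NumericVector& ss,
                          const NumericVector& sd, const NumericVector& sr,
                          const IntegerVector& sptr, const NumericVector& tcl,
                          const NumericVector& tvc, const NumericVector& tq,
                          const NumericVector& tvp, const NumericVector& tq2,
                          const NumericVector& tvp2) {
  SubjView S;
  int o0 = optr[i], o1 = optr[i + 1];
  int s0 = sptr[i], s1 = sptr[i + 1];
  S.y = y.begin() + o0;
  S.t = tobs.begin() + o0;
  S.cens = cens.begin() + o0;
  S.nobs = o1 - o0;
  S.ss = ss.begin() + s0;
  S.sd = sd.begin() + s0;
  S.sr = sr.begin() + s0;
  S.nseg = s1 - s0;
  S.th[0] = tcl[i];
  S.th[1] = tvc[i];
  S.th[2] = tq[i];
  S.th[3] = tvp[i];
  S.th[4] = tq2.size() ? tq2[i] : 0.0;
  S.th[5] = tvp2.size() ? tvp2[i] : 0.0;
  return S;
}

// Total FOCE objective (-2 log approximate marginal likelihood).
// eta0 supplies warm starts for the inner search; the updated modes are
// returned so successive calls during an outer optimization stay warm.
// [[Rcpp::export]]
List cpp_foce(List dat, NumericVector tcl, NumericVector tvc, NumericVector tq,
              NumericVector tvp, NumericVector tq2, NumericVector tvp2,
              int ncmt, IntegerVector emap, NumericVector omega,
              double sig_add, double sig_prop, double lloq, bool censlik,
              NumericMatrix eta0, bool detail, NumericVector agq_z,
              NumericVector agq_w) {
  NumericVector y = dat["y"], tobs = dat["tobs"], ss = dat["ss"],
                sd = dat["sd"], sr = dat["sr"];
  IntegerVector cens = dat["cens"], optr = dat["obs_ptr"],
                sptr = dat["seg_ptr"];
  int nsub = optr.size() - 1;
  int d = emap.size();
  double oinv[4] = {0, 0, 0, 0};
  double logdetO = 0.0;
  for (int k = 0; k < d; k++) {
    double o2 = omega[k] * omega[k];
    oinv[k] = 1.0 / o2;
    logdetO += std::log(o2);
  }
  double sa2 = sig_add * sig_add, sp2 = sig_prop * sig_prop;
  NumericMatrix etas(nsub, d);
  bool warm = eta0.nrow() == nsub && eta0.ncol() == d;
  double total = 0.0;
  bool allok = true;
  NumericVector ofv_i(detail ? nsub : 0), ipred(detail ? y.size() : 0);
  for (int i = 0; i < nsub; i++) {
    SubjView S = make_view(i, y, tobs, cens, optr, ss, sd, sr, sptr, tcl, tvc,
                           tq, tvp, tq2, tvp2);
    std::vector<double> J((size_t)std::max(d, 1) * S.nobs), f(S.nobs);
    double eta[4] = {0, 0, 0, 0};
    if (warm)
      for (int k = 0; k < d; k++) eta[k] = eta0(i, k);
    double oi;
    if (d == 0) {
      oi = g_eval(S, ncmt, emap.begin(), 0, eta, oinv, logdetO, sa2, sp2, lloq,
                  censlik, f.data());
    } else {
      double g;
      int it = inner_mode(S, ncmt, emap.begin(), d, oinv, logdetO, sa2, sp2,
                          lloq, censlik, eta, &g, J, f);
      if (it < 0 || !std::isfinite(g)) {
        allok = false;
        oi = R_PosInf;
      } else {
        bool ok;
        std::vector<double> fbuf(S.nobs);
        double Lh[16];
        double ld = exact_logdet(S, ncmt, emap.begin(), d, eta, oinv,
                                 logdetO, sa2, sp2, lloq, censlik, fbuf,
                                 ok, Lh);
        double corr = 0.0;
        if (ok && agq_z.size() > 1) {
          std::vector<double> zv(agq_z.begin(), agq_z.end()),
              wv(agq_w.begin(), agq_w.end());
          corr = agq_correction(S, ncmt, emap.begin(), d, eta, oinv,
                                logdetO, sa2, sp2, lloq, censlik, Lh, g,
                                zv, wv, fbuf);
        }
        if (!ok) ld = foce_logdet(S, d, oinv, sa2, sp2, J, f, ok);
        if (!ok) allok = false;
        oi = g - d * LOG2PI + ld + corr;
      }
    }
    if (!std::isfinite(oi)) {
      allok = false;
      oi = 1e10;
    }
    total += oi;
    for (int k = 0; k < d; k++) etas(i, k) = eta[k];
    if (detail) {
      ofv_i[i] = oi;
      for (int j = 0; j < S.nobs; j++) ipred[optr[i] + j] = f[j];
    }
  }
  if (detail)
    return List::create(_["ofv"] = total, _["eta"] = etas, _["ok"] = allok,
                        _["ofv_i"] = ofv_i, _["ipred"] = ipred);
  return List::create(_["ofv"] = total, _["eta"] = etas, _["ok"] = allok);
}

// Predictions for every observation row at supplied eta values (zero rows of
// `eta` give the population prediction PRED).
// [[Rcpp::export]]
NumericVector cpp_pred(List dat, NumericVector tcl, NumericVector tvc,
                       NumericVector tq, NumericVector tvp, NumericVector tq2,
                       NumericVector tvp2, int ncmt, IntegerVector emap,
                       NumericMatrix eta) {
  NumericVector y = dat["y"], tobs = dat["tobs"], ss = dat["ss"],
                sd = dat["sd"], sr = dat["sr"];
  IntegerVector cens = dat["cens"], optr = dat["obs_ptr"],
                sptr = dat["seg_ptr"];
  int nsub = optr.size() - 1;
  int d = emap.size();
  NumericVector out(y.size());
  std::vector<double> f;
  for (int i = 0; i < nsub; i++) {
    SubjView S = make_view(i, y, tobs, cens, optr, ss, sd, sr, sptr, tcl, tvc,
                           tq, tvp, tq2, tvp2);
    f.resize(S.nobs);
    double et[4] = {0, 0, 0, 0};
    for (int k = 0; k < d; k++) et[k] = eta(i, k);
    subj_pred(S, ncmt, emap.begin(), d, et, f.data());
    for (int j = 0; j < S.nobs; j++) out[optr[i] + j] = f[j];
  }
  return out;
}

// Conditional weighted residuals (FOCE linearization at the eta mode):
// cwres_j = (y_j - f_j(eta*) + (J eta*)_j) / sqrt((J Omega J')_jj + v_j),
// with v_j the residual variance at the conditional prediction.
// [[Rcpp::export]]
List cpp_cwres(List dat, NumericVector tcl, NumericVector tvc,
               NumericVector tq, NumericVector tvp, NumericVector tq2,
               NumericVector tvp2, int ncmt, IntegerVector emap,
               NumericVector omega, double sig_add, double sig_prop,
               double lloq, bool censlik, NumericMatrix eta0) {
  NumericVector y = dat["y"], tobs = dat["tobs"], ss = dat["ss"],
                sd = dat["sd"], sr = dat["sr"];
  IntegerVector cens = dat["cens"], optr = dat["obs_ptr"],
                sptr = dat["seg_ptr"];
  int nsub = optr.size() - 1;
  int d = emap.size();
  double oinv[4] = {0, 0, 0, 0};
  double logdetO = 0.0;
  for (int k = 0; k < d; k++) {
    double o2 = omega[k] * omega[k];
    oinv[k] = 1.0 / o2;
    logdetO += std::log(o2);
  }
  double sa2 = sig_add * sig_add, sp2 = sig_prop * sig_prop;
  bool warm = eta0.nrow() == nsub && eta0.ncol() == d;
  NumericVector cw(y.size()), ipred(y.size()), pred(y.size());
  NumericMatrix etas(nsub, d);
  for (int i = 0; i < nsub; i++) {
    SubjView S = make_view(i, y, tobs, cens, optr, ss, sd, sr, sptr, tcl, tvc,
                           tq, tvp, tq2, tvp2);
    std::vector<double> J((size_t)std::max(d, 1) * S.nobs), f(S.nobs),
        f0(S.nobs);
    double eta[4] = {0, 0, 0, 0};
    if (warm)
      for (int k = 0; k < d; k++) eta[k] = eta0(i, k);
    if (d > 0) {
      double g;
      inner_mode(S, ncmt, emap.begin(), d, oinv, logdetO, sa2, sp2, lloq,
                 censlik, eta, &g, J, f);
    } else {
      subj_pred(S, ncmt, emap.begin(), 0, eta, f.data());
    }
    double z[4] = {0, 0, 0, 0};
    subj_pred(S, ncmt, emap.begin(), d, z, f0.data());
    for (int j = 0; j < S.nobs; j++) {
      double v = sa2 + sp2 * f[j] * f[j];
      if (v < 1e-12) v = 1e-12;
      double lin = 0.0, var = v;
      for (int k = 0; k < d; k++) {
        double Jk = J[(size_t)k * S.nobs + j];
        lin += Jk * eta[k];
        var += Jk * Jk * omega[k] * omega[k];
      }
      cw[optr[i] + j] = (S.y[j] - f[j] + lin) / std::sqrt(var);
      ipred[optr[i] + j] = f[j];
      pred[optr[i] + j] = f0[j];
    }
    for (int k = 0; k < d; k++) etas(i, k) = eta[k];
  }
  return List::create(_["cwres"] = cw, _["ipred"] = ipred, _["pred"] = pred,
                      _["eta"] = etas);
}
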