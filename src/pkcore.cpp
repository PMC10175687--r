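// Analytic two-compartment infusion kinetics and the per-subject Laplace
// objective. Everything here is deterministic; all randomness stays in R.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Disp {
  double k21, alpha, beta, V1;
};

inline Disp disposition(double CL, double V1, double Q, double V2) {
  double k10 = CL / V1, k12 = Q / V1, k21 = Q / V2;
  double s = k10 + k12 + k21, p = k10 * k21;
  double disc = s * s - 4.0 * p;
  if (disc < 0.0) disc = 0.0;   // numerically tangent roots
  double beta = 0.5 * (s - std::sqrt(disc));
  Disp d;
  d.k21 = k21;
  d.alpha = s - beta;
  d.beta = beta;
  d.V1 = V1;
  return d;
}

// Central concentration at elapsed time t (h) since the start of one
// constant-rate infusion of `amt` mg over `dur` h. Zero for t <= 0, so a dose
// starting exactly at an evaluation time contributes nothing (pre-dose value).
inline double conc_one(double t, double amt, double dur, const Disp& d) {
  if (t <= 0.0 || amt <= 0.0) return 0.0;
  double R0 = amt / dur;
  double A = (d.alpha - d.k21) / (d.alpha - d.beta);
  double B = (d.k21 - d.beta) / (d.alpha - d.beta);
  double te = t < dur ? t : dur;
  double cA = A / d.alpha * (1.0 - std::exp(-d.alpha * te));
  double cB = B / d.beta * (1.0 - std::exp(-d.beta * te));
  if (t > dur) {
    cA *= std::exp(-d.alpha * (t - dur));
    cB *= std::exp(-d.beta * (t - dur));
  }
  return R0 / d.V1 * (cA + cB);
}

// Exact integral of conc_one over elapsed-time window [u0, u1], u0 >= 0.
inline double auc_one(double u0, double u1, double amt, double dur,
                      const Disp& d) {
  if (amt <= 0.0 || u1 <= 0.0) return 0.0;
  if (u0 < 0.0) u0 = 0.0;
  double R0 = amt / dur;
  double A = (d.alpha - d.k21) / (d.alpha - d.beta);
  double B = (d.k21 - d.beta) / (d.alpha - d.beta);
  double total = 0.0;
  // antiderivative pieces per exponential term
  const double coef[2] = {A, B};
  const double lam[2] = {d.alpha, d.beta};
  for (int i = 0; i < 2; ++i) {
    double c = coef[i], L = lam[i];
    // during infusion: c/L * (1 - exp(-L u)); integral = c/L * (u + (exp(-L u)-1)/L)
    double a0 = u0 < dur ? u0 : dur, a1 = u1 < dur ? u1 : dur;
    if (a1 > a0) {
      double F1 = a1 + (std::exp(-L * a1) - 1.0) / L;
      double F0 = a0 + (std::exp(-L * a0) - 1.0) / L;
      total += c / L * (F1 - F0);
    }
    // after infusion: c/L*(1-exp(-L dur)) * exp(-L (u-dur)); integral over [b0,b1]
    double b0 = u0 > dur ? u0 : dur, b1 = u1;
    if (b1 > b0) {
      double amp = c / L * (1.0 - std::exp(-L * dur));
      total += amp / L * (std::exp(-L * (b0 - dur)) - std::exp(-L * (b1 - dur)));
    }
  }
  return R0 / d.V1 * total;
}

}  // namespace

// [[Rcpp::export(name = ".conc2_cpp")]]
NumericVector conc2_cpp(NumericVector times, NumericVector dose_start,
                        NumericVector dose_amt, NumericVector dose_dur,
                        double CL, double V1, double Q, double V2) {
  Disp d = disposition(CL, V1, Q, V2);
  int nt = times.size(), nd = dose_start.size();
  NumericVector out(nt);
  for (int i = 0; i < nt; ++i) {
    double c = 0.0;
    for (int j = 0; j < nd; ++j)
      c += conc_one(times[i] - dose_start[j], dose_amt[j], dose_dur[j], d);
    out[i] = c;
  }
  return out;
}

// [[Rcpp::export(name = ".auc2_cpp")]]
double auc2_cpp(double t0, double t1, NumericVector dose_start,
                NumericVector dose_amt, NumericVector dose_dur, double CL,
                double V1, double Q, double V2) {
  Disp d = disposition(CL, V1, Q, V2);
  double total = 0.0;
  for (int j = 0; j < dose_start.size(); ++j)
    total += auc_one(t0 - dose_start[j], t1 - dose_start[j], dose_amt[j],
                     dose_dur[j], d);
  return total;
}

namespace {

// Joint negative log density for one subject: residual log-likelihood with
// proportional error evaluated at the conditional prediction (eta-eps
// interaction) plus the N(0, Omega) prior on eta. `free` maps the reduced eta
// vector onto the four structural parameters (CL, V1, Q, V2).
struct Subject {
  std::vector<double> t, y;             // observations
  std::vector<double> ds, da, dd;       // dose events
};

struct Model {
  double tv[4];          // typical CL, V1, Q, V2 for this subject (covariates applied)
  double omega2[4];      // IIV variances; <= 0 means eta fixed at zero
  double sigma2;         // proportional residual variance
  std::vector<int> free; // indices with omega2 > 0
};

const double LOG2PI = 1.8378770664093453;

// predicted concentrations at a subject's observation times for eta
inline bool conc_subject(const Subject& s, const Model& m,
                         const std::vector<double>& eta,
                         std::vector<double>& f) {
  double p[4];
  for (int k = 0; k < 4; ++k) p[k] = m.tv[k];
  for (size_t r = 0; r < m.free.size(); ++r)
    p[m.free[r]] *= std::exp(eta[r]);
  Disp d = disposition(p[0], p[1], p[2], p[3]);
  for (size_t j = 0; j < s.t.size(); ++j) {
    double fj = 0.0;
    for (size_t q = 0; q < s.ds.size(); ++q)
      fj += conc_one(s.t[j] - s.ds[q], s.da[q], s.dd[q], d);
    if (!(fj > 0.0) || !std::isfinite(fj)) return false;
    f[j] = fj;
  }
  return true;
}

// residual -log likelihood given predictions
inline double resid_nll(const Subject& s, const Model& m,
                        const std::vector<double>& f) {
  double g = 0.0;
  for (size_t j = 0; j < s.t.size(); ++j) {
    double v = m.sigma2 * f[j] * f[j];
    double r = s.y[j] - f[j];
    g += 0.5 * (r * r / v + std::log(v) + LOG2PI);
  }
  return g;
}

inline double neg_joint(const Subject& s, const Model& m,
                        const std::vector<double>& eta, bool* bad) {
  std::vector<double> f(s.t.size());
  if (!conc_subject(s, m, eta, f)) { *bad = true; return R_PosInf; }
  double g = resid_nll(s, m, f);
  for (size_t r = 0; r < m.free.size(); ++r)
    g += 0.5 * (eta[r] * eta[r] / m.omega2[m.free[r]] +
                std::log(m.omega2[m.free[r]]) + LOG2PI);
  return g;
}

// dense symmetric solve / log-determinant via Cholesky, dim <= 4
inline bool chol_inplace(std::vector<double>& A, int n) {
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * n + j];
      for (int k = 0; k < j; ++k) s -= A[i * n + k] * A[j * n + k];
      if (i == j) {
        if (s <= 0.0) return false;
        A[i * n + i] = std::sqrt(s);
      } else {
        A[i * n + j] = s / A[j * n + j];
      }
    }
  }
  return true;
}

inline void chol_solve(const std::vector<double>& Lm, int n,
                       const std::vector<double>& b, std::vector<double>& x) {
  std::vector<double> z(n);
  for (int i = 0; i < n; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= Lm[i * n + k] * z[k];
    z[i] = s / Lm[i * n + i];
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = z[i];
    for (int k = i + 1; k < n; ++k) s -= Lm[k * n + i] * x[k];
    x[i] = s / Lm[i * n + i];
  }
}

// gradient and Hessian of g at eta by central differences on g itself;
// returns g(eta). 1 + 2d + 2d(d-1) evaluations.
inline double fd_grad_hess(const Subject& s, const Model& m,
                           std::vector<double>& eta, std::vector<double>& gr,
                           std::vector<double>& H, double h, bool* bad) {
  int n = (int)eta.size();
  double g0 = neg_joint(s, m, eta, bad);
  std::vector<double> gp(n), gm(n);
  for (int i = 0; i < n; ++i) {
    double e0 = eta[i];
    eta[i] = e0 + h;
    gp[i] = neg_joint(s, m, eta, bad);
    eta[i] = e0 - h;
    gm[i] = neg_joint(s, m, eta, bad);
    eta[i] = e0;
    gr[i] = (gp[i] - gm[i]) / (2.0 * h);
    H[i * n + i] = (gp[i] + gm[i] - 2.0 * g0) / (h * h);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double ei = eta[i], ej = eta[j];
      eta[i] = ei + h; eta[j] = ej + h;
      double fpp = neg_joint(s, m, eta, bad);
      eta[j] = ej - h;
      double fpm = neg_joint(s, m, eta, bad);
      eta[i] = ei - h; eta[j] = ej + h;
      double fmp = neg_joint(s, m, eta, bad);
      eta[j] = ej - h;
      double fmm = neg_joint(s, m, eta, bad);
      eta[i] = ei; eta[j] = ej;
      double v = (fpp - fpm - fmp + fmm) / (4.0 * h * h);
      H[i * n + j] = H[j * n + i] = v;
    }
  }
  return g0;
}

// Damped Fisher-scoring minimization of the joint negative log density from
// a given start; eta is updated in place, *gout receives the final value.
// The gradient uses the analytic derivative of the proportional-error
// likelihood with a finite-difference Jacobian of the predictions; the step
// matrix is the expected information (always positive definite once the
// prior precision is added), which keeps the iteration monotone under the
// line search. Returns true when the gradient norm dropped below gtol.
inline bool newton_mode(const Subject& s, const Model& m,
                        std::vector<double>& eta, double h, double gtol,
                        int maxit, double* gout) {
  int d = (int)eta.size();
  int nobs = (int)s.t.size();
  std::vector<double> f(nobs), fp(nobs), fm(nobs);
  if (!conc_subject(s, m, eta, f)) {
    std::fill(eta.begin(), eta.end(), 0.0);
    if (!conc_subject(s, m, eta, f)) { *gout = R_PosInf; return false; }
  }
  double prior = 0.0;
  for (size_t r = 0; r < m.free.size(); ++r)
    prior += 0.5 * (eta[r] * eta[r] / m.omega2[m.free[r]] +
                    std::log(m.omega2[m.free[r]]) + LOG2PI);
  double g = resid_nll(s, m, f) + prior;

  std::vector<double> G(nobs * d), gr(d), H(d * d), Hc(d * d), step(d),
      trial(d), ftr(nobs);
  bool conv = false;
  for (int it = 0; it < maxit; ++it) {
    // FD Jacobian of predictions wrt eta
    bool ok = true;
    for (int k = 0; k < d; ++k) {
      double e0 = eta[k];
      eta[k] = e0 + h;
      ok = ok && conc_subject(s, m, eta, fp);
      eta[k] = e0 - h;
      ok = ok && conc_subject(s, m, eta, fm);
      eta[k] = e0;
      if (!ok) break;
      for (int j = 0; j < nobs; ++j)
        G[j * d + k] = (fp[j] - fm[j]) / (2.0 * h);
    }
    if (!ok) break;
    // analytic residual derivative and expected information weight per obs
    // l(f) = 0.5[(y-f)^2/(s2 f^2) + log(2 pi s2 f^2)]
    // l'(f) = -(y-f)/(s2 f^2) - (y-f)^2/(s2 f^3) + 1/f
    // E l''(f) = 1/(s2 f^2) + 2/f^2
    std::fill(gr.begin(), gr.end(), 0.0);
    std::fill(H.begin(), H.end(), 0.0);
    for (int j = 0; j < nobs; ++j) {
      double fj = f[j], r = s.y[j] - fj;
      double lp = -r / (m.sigma2 * fj * fj) -
                  r * r / (m.sigma2 * fj * fj * fj) + 1.0 / fj;
      double w = 1.0 / (m.sigma2 * fj * fj) + 2.0 / (fj * fj);
      for (int k = 0; k < d; ++k) {
        gr[k] += lp * G[j * d + k];
        for (int l = 0; l <= k; ++l)
          H[k * d + l] += w * G[j * d + k] * G[j * d + l];
      }
    }
    for (int k = 0; k < d; ++k) {
      gr[k] += eta[k] / m.omega2[m.free[k]];
      H[k * d + k] += 1.0 / m.omega2[m.free[k]];
      for (int l = k + 1; l < d; ++l) H[k * d + l] = H[l * d + k];
    }
    double gn = 0.0;
    for (int r = 0; r < d; ++r) gn += gr[r] * gr[r];
    gn = std::sqrt(gn);
    if (gn < gtol) { conv = true; break; }
    double ridge = 0.0;
    for (int attempt = 0; attempt < 8; ++attempt) {
      Hc = H;
      for (int r = 0; r < d; ++r) Hc[r * d + r] += ridge;
      if (chol_inplace(Hc, d)) break;
      ridge = ridge == 0.0 ? 1e-4 : ridge * 10.0;
    }
    chol_solve(Hc, d, gr, step);
    double lam = 1.0, gnew = R_PosInf;
    for (int ls = 0; ls < 30; ++ls) {
      for (int r = 0; r < d; ++r) trial[r] = eta[r] - lam * step[r];
      if (conc_subject(s, m, trial, ftr)) {
        double ptr = 0.0;
        for (size_t r = 0; r < m.free.size(); ++r)
          ptr += 0.5 * (trial[r] * trial[r] / m.omega2[m.free[r]] +
                        std::log(m.omega2[m.free[r]]) + LOG2PI);
        gnew = resid_nll(s, m, ftr) + ptr;
        if (std::isfinite(gnew) && gnew <= g + 1e-12) break;
      }
      lam *= 0.5;
    }
    if (!(std::isfinite(gnew)) || gnew > g) { conv = gn < 1e-4; break; }
    eta = trial;
    f = ftr;
    g = gnew;
  }
  *gout = g;
  return conv;
}

}  // namespace

// Laplace -2 log marginal likelihood, summed over subjects. `subjects` is a
// list of list(times, dv, dose_start, dose_amt, dose_dur); `tv` is n x 4 with
// covariate-adjusted typical values. Returns the OFV, per-subject
// contributions, conditional modes (n x 4, zero where omega2 == 0) and a
// convergence flag per subject.
// [[Rcpp::export(name = ".ofv_laplace_cpp")]]
List ofv_laplace_cpp(List subjects, NumericMatrix tv, NumericVector omega2,
                     double sigma2, NumericMatrix eta_start, double gtol,
                     int maxit, bool dual) {
  int n = subjects.size();
  Model base;
  base.sigma2 = sigma2;
  for (int k = 0; k < 4; ++k) {
    base.omega2[k] = omega2[k];
    if (omega2[k] > 0.0) base.free.push_back(k);
  }
  int d = (int)base.free.size();
  NumericVector ofv_i(n);
  NumericMatrix eta_hat(n, 4);
  LogicalVector ok(n);
  double total = 0.0;
  const double h = 1e-4;

  for (int i = 0; i < n; ++i) {
    List si = subjects[i];
    Subject s;
    s.t = as<std::vector<double> >(si["times"]);
    s.y = as<std::vector<double> >(si["dv"]);
    s.ds = as<std::vector<double> >(si["dose_start"]);
    s.da = as<std::vector<double> >(si["dose_amt"]);
    s.dd = as<std::vector<double> >(si["dose_dur"]);
    Model m = base;
    for (int k = 0; k < 4; ++k) m.tv[k] = tv(i, k);

    bool bad = false;
    std::vector<double> eta(d);
    bool conv = true;

    if (d > 0) {
      // the joint density can be multimodal under sparse sampling: solve from
      // the warm start and from the prior mode, keep the lower mode
      std::vector<double> e1(d), e2(d, 0.0);
      for (int r = 0; r < d; ++r) e1[r] = eta_start(i, base.free[r]);
      double norm1 = 0.0;
      for (int r = 0; r < d; ++r) norm1 += e1[r] * e1[r];
      double g1, g2;
      bool c1 = newton_mode(s, m, e1, h, gtol, maxit, &g1);
      bool c2 = true;
      g2 = R_PosInf;
      if (dual && norm1 > 1e-12) c2 = newton_mode(s, m, e2, h, gtol, maxit, &g2);
      double g;
      if (std::isfinite(g2) && g2 < g1) {
        eta = e2; g = g2; conv = c2;
      } else {
        eta = e1; g = g1; conv = c1;
      }
      if (!std::isfinite(g)) { ofv_i[i] = R_PosInf; ok[i] = false; continue; }
      // curvature at the winning mode for the Laplace correction
      std::vector<double> gr(d), H(d * d), Hc(d * d);
      fd_grad_hess(s, m, eta, gr, H, h, &bad);
      double ridge = 0.0;
      bool pd = false;
      for (int attempt = 0; attempt < 10; ++attempt) {
        Hc = H;
        for (int r = 0; r < d; ++r) Hc[r * d + r] += ridge;
        if (chol_inplace(Hc, d)) { pd = true; break; }
        ridge = ridge == 0.0 ? 1e-6 : ridge * 10.0;
      }
      if (!pd) conv = false;
      double logdet = 0.0;
      for (int r = 0; r < d; ++r) logdet += 2.0 * std::log(Hc[r * d + r]);
      ofv_i[i] = 2.0 * g + logdet - d * LOG2PI;
    } else {
      double g = neg_joint(s, m, eta, &bad);
      ofv_i[i] = 2.0 * g;
    }
    for (int r = 0; r < d; ++r) eta_hat(i, base.free[r]) = eta[r];
    ok[i] = conv && std::isfinite(ofv_i[i]);
    total += ofv_i[i];
  }
  return List::create(_["ofv"] = total, _["ofv_i"] = ofv_i,
                      _["eta"] = eta_hat, _["converged"] = ok);
}
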