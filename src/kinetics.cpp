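#include <Rcpp.h>
using namespace Rcpp;

// Exponential convolution of a piecewise-linear input, exact per segment.
//
// For a linear segment y(s) = a + b*(s - t0) over [t0, t0 + dt] and decay
// rate theta, the state C(t) = int_0^t exp(-theta (t - s)) y(s) ds and its
// running time-integral are advanced in closed form using the stable
// helpers
//   E0(x) = (1 - e^{-x})/x,  E1(x) = (1 - E0)/x,  E2(x) = (1/2 - E1)/x,
// with series expansions near x = 0 to avoid catastrophic cancellation.

static inline double E0f(double x) {
  if (x < 1e-8) return 1.0 - x / 2.0 + x * x / 6.0;
  return -expm1(-x) / x;
}
static inline double E1f(double x) {
  if (x < 1e-3)
    return 0.5 - x / 6.0 + x * x / 24.0 - x * x * x / 120.0;
  return (1.0 - E0f(x)) / x;
}
static inline double E2f(double x) {
  if (x < 1e-2)
    return 1.0 / 6.0 - x / 24.0 + x * x / 120.0 - x * x * x / 720.0 +
           x * x * x * x / 5040.0;
  return (0.5 - E1f(x)) / x;
}

// C[m] = conv state at grid point m; I[m] = int_0^{t_m} C(u) du.
static void conv_exp(const double* t, const double* y, int M, double theta,
                     double* C, double* I) {
  C[0] = 0.0;
  I[0] = 0.0;
  for (int m = 0; m + 1 < M; ++m) {
    double dt = t[m + 1] - t[m];
    double a = y[m];
    double b = (y[m + 1] - y[m]) / dt;
    double x = theta * dt;
    double e0 = E0f(x), e1 = E1f(x), e2 = E2f(x);
    double em = 1.0 - x * e0; // = exp(-x), exactly, without a second exp call
    C[m + 1] = em * C[m] + dt * (a * e0 + b * dt * e1);
    I[m + 1] = I[m] + C[m] * dt * e0 + a * dt * dt * e1 + b * dt * dt * dt * e2;
  }
}

// [[Rcpp::export(name = ".conv_exp_grid")]]
List conv_exp_grid(NumericVector t, NumericVector y, double theta) {
  int M = t.size();
  NumericVector C(M), I(M);
  conv_exp(t.begin(), y.begin(), M, theta, C.begin(), I.begin());
  return List::create(_["state"] = C, _["integral"] = I);
}

struct TwoTC {
  double th1, th2, phi1, phi2; // impulse response phi1 e^{-th1 t} + phi2 e^{-th2 t}
};

static inline TwoTC twotc_irf(double K1, double VND, double BPND, double k4) {
  double k2 = K1 / VND;
  double k3 = BPND * k4;
  double s = k2 + k3 + k4;
  double disc2 = s * s - 4.0 * k2 * k4;
  double disc = disc2 > 0 ? std::sqrt(disc2) : 0.0;
  double th1 = 0.5 * (s + disc);
  double th2 = 0.5 * (s - disc);
  double den = th1 - th2;
  if (den < 1e-12 * s + 1e-300) { // repeated root: nudge apart (measure-zero case)
    th1 += 1e-9 * (1.0 + s);
    den = th1 - th2;
  }
  TwoTC o;
  o.th1 = th1;
  o.th2 = th2;
  o.phi1 = K1 * (th1 - k3 - k4) / den;
  o.phi2 = K1 * (k3 + k4 - th2) / den;
  return o;
}

// Frame averages of the 2TCM curve
//   C_model(t) = (1 - vB) (C1 + C2)(t) + vB C_wp(t)
// on a grid that contains every frame boundary. wpI is the cumulative
// time-integral of the whole-plasma curve at the grid points (exact for a
// piecewise-linear curve). istart/iend are 0-based grid indices of frame
// boundaries.
// [[Rcpp::export(name = ".tac_2tc_frames")]]
NumericVector tac_2tc_frames(NumericVector t, NumericVector cp,
                             NumericVector wpI, IntegerVector istart,
                             IntegerVector iend, double K1, double VND,
                             double BPND, double k4, double vB) {
  int M = t.size(), F = istart.size();
  TwoTC o = twotc_irf(K1, VND, BPND, k4);
  std::vector<double> C1(M), I1(M), C2(M), I2(M);
  conv_exp(t.begin(), cp.begin(), M, o.th1, C1.data(), I1.data());
  conv_exp(t.begin(), cp.begin(), M, o.th2, C2.data(), I2.data());
  NumericVector out(F);
  for (int f = 0; f < F; ++f) {
    int s = istart[f], e = iend[f];
    double dur = t[e] - t[s];
    double tis = o.phi1 * (I1[e] - I1[s]) + o.phi2 * (I2[e] - I2[s]);
    out[f] = ((1.0 - vB) * tis + vB * (wpI[e] - wpI[s])) / dur;
  }
  return out;
}

// Pointwise 2TCM model curve on the grid (for oracle/property tests).
// [[Rcpp::export(name = ".tac_2tc_curve")]]
NumericVector tac_2tc_curve(NumericVector t, NumericVector cp,
                            NumericVector wp, double K1, double VND,
                            double BPND, double k4, double vB) {
  int M = t.size();
  TwoTC o = twotc_irf(K1, VND, BPND, k4);
  std::vector<double> C1(M), I1(M), C2(M), I2(M);
  conv_exp(t.begin(), cp.begin(), M, o.th1, C1.data(), I1.data());
  conv_exp(t.begin(), cp.begin(), M, o.th2, C2.data(), I2.data());
  NumericVector out(M);
  for (int m = 0; m < M; ++m)
    out[m] = (1.0 - vB) * (o.phi1 * C1[m] + o.phi2 * C2[m]) + vB * wp[m];
  return out;
}

// SRTM frame averages: C_T = R1 C_ref + (k2 - R1 k2a) [C_ref (x) e^{-k2a t}],
// refI = cumulative integral of the reference curve at grid points.
// [[Rcpp::export(name = ".tac_srtm_frames")]]
NumericVector tac_srtm_frames(NumericVector t, NumericVector cref,
                              NumericVector refI, IntegerVector istart,
                              IntegerVector iend, double R1, double k2prime,
                              double BPND) {
  int M = t.size(), F = istart.size();
  double k2 = R1 * k2prime;
  double k2a = k2 / (1.0 + BPND);
  std::vector<double> C(M), I(M);
  conv_exp(t.begin(), cref.begin(), M, k2a, C.data(), I.data());
  NumericVector out(F);
  for (int f = 0; f < F; ++f) {
    int s = istart[f], e = iend[f];
    double dur = t[e] - t[s];
    out[f] =
        (R1 * (refI[e] - refI[s]) + (k2 - R1 * k2a) * (I[e] - I[s])) / dur;
  }
  return out;
}

// [[Rcpp::export(name = ".tac_srtm_curve")]]
NumericVector tac_srtm_curve(NumericVector t, NumericVector cref, double R1,
                             double k2prime, double BPND) {
  int M = t.size();
  double k2 = R1 * k2prime;
  double k2a = k2 / (1.0 + BPND);
  std::vector<double> C(M), I(M);
  conv_exp(t.begin(), cref.begin(), M, k2a, C.data(), I.data());
  NumericVector out(M);
  for (int m = 0; m < M; ++m)
    out[m] = R1 * cref[m] + (k2 - R1 * k2a) * C[m];
  return out;
}

// ---------------------------------------------------------------------------
// Metropolis update of per-TAC log kinetic parameter vectors inside the joint
// hierarchical sampler. Each TAC's theta = (log K1, log VND, log BP, log k4,
// log vB) has a Gaussian prior N(pmean_i, diag(psd^2)) from the hierarchy and
// a frame-level likelihood through the 2TCM. bp_pp_mode = 1 means theta[2]
// stores log(VND * BPND) (the BP_P / BP_F parameterizations), so
// BPND = exp(theta[2] - theta[1]).
// ---------------------------------------------------------------------------

static double tac_loglik(const double* t, const double* cp, const double* wpI,
                         int M, const int* is, const int* ie, int F,
                         const double* y, const double* w, double sigma,
                         double nu, const double* th, int bp_pp_mode,
                         double* mu_out) {
  double K1 = std::exp(th[0]);
  double VND = std::exp(th[1]);
  double BPND = bp_pp_mode ? std::exp(th[2] - th[1]) : std::exp(th[2]);
  double k4 = std::exp(th[3]);
  double vB = std::exp(th[4]);
  TwoTC o = twotc_irf(K1, VND, BPND, k4);
  static thread_local std::vector<double> C1, I1, C2, I2;
  C1.resize(M); I1.resize(M); C2.resize(M); I2.resize(M);
  conv_exp(t, cp, M, o.th1, C1.data(), I1.data());
  conv_exp(t, cp, M, o.th2, C2.data(), I2.data());
  double ll = 0.0;
  for (int f = 0; f < F; ++f) {
    int s = is[f], e = ie[f];
    double dur = t[e] - t[s];
    double tis = o.phi1 * (I1[e] - I1[s]) + o.phi2 * (I2[e] - I2[s]);
    double mu = ((1.0 - vB) * tis + vB * (wpI[e] - wpI[s])) / dur;
    if (mu_out) mu_out[f] = mu;
    double z = (y[f] - mu) * w[f] / sigma;
    if (nu > 0.0)
      ll += -0.5 * (nu + 1.0) * std::log1p(z * z / nu);
    else
      ll += -0.5 * z * z;
  }
  return ll;
}

// Total frame-level log-likelihood over all TACs at a given theta matrix
// (used by the joint location-shift Metropolis moves).
// [[Rcpp::export(name = ".hier_loglik_total")]]
double hier_loglik_total(List sub_t, List sub_cp, List sub_wpI, List sub_is,
                         List sub_ie, IntegerVector tac_sub,
                         IntegerVector tac_reg, NumericMatrix y,
                         NumericMatrix w, NumericMatrix theta,
                         NumericVector sigma_reg, double nu, int bp_pp_mode) {
  int ntac = theta.nrow();
  int F = y.ncol();
  int nsub = sub_t.size();
  std::vector<NumericVector> Ts(nsub), CPs(nsub), WPs(nsub);
  std::vector<IntegerVector> ISs(nsub), IEs(nsub);
  for (int i = 0; i < nsub; ++i) {
    Ts[i] = as<NumericVector>(sub_t[i]);
    CPs[i] = as<NumericVector>(sub_cp[i]);
    WPs[i] = as<NumericVector>(sub_wpI[i]);
    ISs[i] = as<IntegerVector>(sub_is[i]);
    IEs[i] = as<IntegerVector>(sub_ie[i]);
  }
  double total = 0.0;
  std::vector<double> th(5), yk(F), wk(F);
  for (int k = 0; k < ntac; ++k) {
    int si = tac_sub[k], rj = tac_reg[k];
    for (int p = 0; p < 5; ++p) th[p] = theta(k, p);
    for (int f = 0; f < F; ++f) {
      yk[f] = y(k, f);
      wk[f] = w(k, f);
    }
    total += tac_loglik(Ts[si].begin(), CPs[si].begin(), WPs[si].begin(),
                        Ts[si].size(), ISs[si].begin(), IEs[si].begin(), F,
                        yk.data(), wk.data(), sigma_reg[rj], nu, th.data(),
                        bp_pp_mode, NULL);
  }
  return total;
}

// [[Rcpp::export(name = ".hier_update_theta")]]
List hier_update_theta(List sub_t, List sub_cp, List sub_wpI, List sub_is,
                       List sub_ie, IntegerVector tac_sub,
                       IntegerVector tac_reg, NumericMatrix y, NumericMatrix w,
                       NumericMatrix theta, NumericMatrix pmean,
                       NumericVector psd, NumericVector sigma_reg,
                       List prop_chol, int nprop, double nu, int bp_pp_mode,
                       double logvb_max) {
  int ntac = theta.nrow();
  int F = y.ncol();
  NumericMatrix th_out(clone(theta));
  NumericMatrix mu_out(ntac, F);
  IntegerVector acc(ntac);
  NumericVector wssr(ntac);
  NumericVector llvec(ntac);

  // cache pointers per subject
  int nsub = sub_t.size();
  std::vector<NumericVector> Ts(nsub), CPs(nsub), WPs(nsub);
  std::vector<IntegerVector> ISs(nsub), IEs(nsub);
  for (int i = 0; i < nsub; ++i) {
    Ts[i] = as<NumericVector>(sub_t[i]);
    CPs[i] = as<NumericVector>(sub_cp[i]);
    WPs[i] = as<NumericVector>(sub_wpI[i]);
    ISs[i] = as<IntegerVector>(sub_is[i]);
    IEs[i] = as<IntegerVector>(sub_ie[i]);
  }
  std::vector<NumericMatrix> Ls(prop_chol.size());
  for (int j = 0; j < prop_chol.size(); ++j)
    Ls[j] = as<NumericMatrix>(prop_chol[j]);

  RNGScope scope;
  std::vector<double> cur(5), prop(5), muf(F), mup(F);

  for (int k = 0; k < ntac; ++k) {
    int si = tac_sub[k], rj = tac_reg[k];
    const double* t = Ts[si].begin();
    const double* cp = CPs[si].begin();
    const double* wpI = WPs[si].begin();
    const int* is = ISs[si].begin();
    const int* ie = IEs[si].begin();
    int M = Ts[si].size();
    double sigma = sigma_reg[rj];
    NumericMatrix L = Ls[k]; // per-TAC proposal cholesky (lower)

    for (int p = 0; p < 5; ++p) cur[p] = th_out(k, p);
    // gather row k of y and w contiguously
    std::vector<double> yk(F), wk(F);
    for (int f = 0; f < F; ++f) {
      yk[f] = y(k, f);
      wk[f] = w(k, f);
    }
    double llcur = tac_loglik(t, cp, wpI, M, is, ie, F, yk.data(), wk.data(),
                              sigma, nu, cur.data(), bp_pp_mode, muf.data());
    double lpcur = 0.0;
    for (int p = 0; p < 5; ++p) {
      double z = (cur[p] - pmean(k, p)) / psd[p];
      lpcur += -0.5 * z * z;
    }

    for (int it = 0; it < nprop; ++it) {
      double zs[5];
      for (int p = 0; p < 5; ++p) zs[p] = R::norm_rand();
      for (int p = 0; p < 5; ++p) {
        double step = 0.0;
        for (int q = 0; q <= p; ++q) step += L(p, q) * zs[q];
        prop[p] = cur[p] + step;
      }
      bool ok = true;
      for (int p = 0; p < 5; ++p)
        if (!std::isfinite(prop[p]) || std::fabs(prop[p]) > 15.0) ok = false;
      if (prop[4] > logvb_max) ok = false;
      if (!ok) continue;
      double llp = tac_loglik(t, cp, wpI, M, is, ie, F, yk.data(), wk.data(),
                              sigma, nu, prop.data(), bp_pp_mode, mup.data());
      double lpp = 0.0;
      for (int p = 0; p < 5; ++p) {
        double z = (prop[p] - pmean(k, p)) / psd[p];
        lpp += -0.5 * z * z;
      }
      if (std::log(R::unif_rand()) < (llp + lpp) - (llcur + lpcur)) {
        for (int p = 0; p < 5; ++p) cur[p] = prop[p];
        llcur = llp;
        lpcur = lpp;
        std::copy(mup.begin(), mup.end(), muf.begin());
        acc[k] += 1;
      }
    }
    for (int p = 0; p < 5; ++p) th_out(k, p) = cur[p];
    double ss = 0.0;
    for (int f = 0; f < F; ++f) {
      mu_out(k, f) = muf[f];
      double e = (yk[f] - muf[f]) * wk[f];
      ss += e * e;
    }
    wssr[k] = ss;
    llvec[k] = llcur;
  }
  return List::create(_["theta"] = th_out, _["mu"] = mu_out, _["accept"] = acc,
                      _["wssr"] = wssr, _["loglik"] = llvec);
}
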