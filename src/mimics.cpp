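#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Flat parameter vector layout (built by .paramVector() on the R side):
//  0 v_slope, 1 v_int, 2 a_v,
//  3-8   v_mod  (r_m, r_s, r_a, k_m, k_s, k_a),
//  9     vmax_scale,
//  10-15 k_slope per flux (m, s, a, m, s, a),
//  16 k_int, 17 a_k,
//  18-23 k_mod per flux (a-fluxes unscaled; texture scalar applied here),
//  24 p_scalar_a, 25 p_scalar_b,
//  26-27 k_o (r, k),
//  28-31 cue (r_m, r_s, k_m, k_s),
//  32-33 tau_base (r, k), 34 tau_mod_r, 35 tau_mod_k, 36 beta,
//  37-38 f_phys_r (a, b), 39-40 f_phys_k,
//  41-42 f_chem_r (a, b), 43-44 f_chem_k,
//  45-46 f_i (m, s), 47 d_base, 48 d_clay,
//  49 f_met0, 50 f_met_slope, 51 f_met_min, 52 f_met_max, 53 depth_cm
//
// State order: lit_m, lit_s, mic_r, mic_k, som_p, som_c, som_a.

struct Ctx {
  double vmax[6], km[6];
  double moist, i_m, i_s;
  double tau_r, tau_k, beta;
  double fphys_r, fphys_k, fchem_r, fchem_k, favai_r, favai_k;
  double cue[4], fi_m, fi_s, ko_r, ko_k, des_rate;
};

static void resolve_kinetics(double temp, double clay, const double* p,
                             double* vmax, double* km) {
  const double vbase = std::exp(p[0] * temp + p[1]) * p[2] * p[9];
  const double pscal = p[24] * std::exp(p[25] * std::sqrt(clay));
  for (int j = 0; j < 6; ++j) {
    vmax[j] = vbase * p[3 + j];
    double kmod = p[18 + j];
    if (j == 2 || j == 5) kmod *= pscal;  // available-SOM uptake, texture effect
    km[j] = std::exp(p[10 + j] * temp + p[16]) * p[17] / kmod;
  }
}

// precompute everything that is constant under fixed forcing
static Ctx make_ctx(double temp, double moist, double input, double fmet,
                    double clay, const double* p) {
  Ctx c;
  resolve_kinetics(temp, clay, p, c.vmax, c.km);
  c.moist = moist;
  c.i_m = input * fmet;
  c.i_s = input * (1.0 - fmet);
  c.tau_r = p[32] * std::exp(p[34] * fmet);
  c.tau_k = p[33] * std::exp(p[35] * fmet);
  c.beta = p[36];
  c.fphys_r = p[37] * std::exp(p[38] * clay);
  c.fphys_k = p[39] * std::exp(p[40] * clay);
  c.fchem_r = p[41] * std::exp(p[42] * fmet);
  c.fchem_k = p[43] * std::exp(p[44] * fmet);
  c.favai_r = 1.0 - c.fphys_r - c.fchem_r;
  c.favai_k = 1.0 - c.fphys_k - c.fchem_k;
  for (int i = 0; i < 4; ++i) c.cue[i] = p[28 + i];
  c.fi_m = p[45]; c.fi_s = p[46];
  c.ko_r = p[26]; c.ko_k = p[27];
  c.des_rate = p[47] * std::exp(p[48] * clay);
  return c;
}

// derivatives + respiration for one state under a resolved context
static void rhs_ctx(const double* x, const Ctx& c, double* out) {
  const double lit_m = x[0], lit_s = x[1], mic_r = x[2], mic_k = x[3];
  const double som_p = x[4], som_c = x[5], som_a = x[6];

  const double l1r = mic_r * c.vmax[0] * lit_m / (c.km[0] + lit_m) * c.moist;
  const double l2r = mic_r * c.vmax[1] * lit_s / (c.km[1] + lit_s) * c.moist;
  const double ar  = mic_r * c.vmax[2] * som_a / (c.km[2] + som_a) * c.moist;
  const double l1k = mic_k * c.vmax[3] * lit_m / (c.km[3] + lit_m) * c.moist;
  const double l2k = mic_k * c.vmax[4] * lit_s / (c.km[4] + lit_s) * c.moist;
  const double ak  = mic_k * c.vmax[5] * som_a / (c.km[5] + som_a) * c.moist;

  // oxidation of chemically protected SOM (structural-litter kinetics, Km
  // amplified by k_o)
  const double oxr = mic_r * c.vmax[1] * som_c / (c.ko_r * c.km[1] + som_c) * c.moist;
  const double oxk = mic_k * c.vmax[4] * som_c / (c.ko_k * c.km[4] + som_c) * c.moist;

  const double trn_r = std::pow(mic_r, c.beta) * c.tau_r;
  const double trn_k = std::pow(mic_k, c.beta) * c.tau_k;
  const double des = som_p * c.des_rate;

  out[0] = c.i_m * (1.0 - c.fi_m) - l1r - l1k;
  out[1] = c.i_s * (1.0 - c.fi_s) - l2r - l2k;
  out[2] = c.cue[0] * (l1r + ar) + c.cue[1] * l2r - trn_r;
  out[3] = c.cue[2] * (l1k + ak) + c.cue[3] * l2k - trn_k;
  out[4] = c.i_m * c.fi_m + trn_r * c.fphys_r + trn_k * c.fphys_k - des;
  out[5] = c.i_s * c.fi_s + trn_r * c.fchem_r + trn_k * c.fchem_k - oxr - oxk;
  out[6] = trn_r * c.favai_r + trn_k * c.favai_k + des + oxr + oxk - ar - ak;
  out[7] = (1.0 - c.cue[0]) * (l1r + ar) + (1.0 - c.cue[1]) * l2r +
           (1.0 - c.cue[2]) * (l1k + ak) + (1.0 - c.cue[3]) * l2k;
}

// [[Rcpp::export(name = ".mimicsRhsCpp")]]
NumericVector mimics_rhs_cpp(NumericVector state, double temp, double moisture,
                             double input, double fmet, double clay,
                             NumericVector par) {
  if (state.size() != 7) stop("state must have length 7");
  Ctx c = make_ctx(temp, moisture, input, fmet, clay, REAL(par));
  double out[8];
  rhs_ctx(REAL(state), c, out);
  NumericVector res(8);
  for (int i = 0; i < 8; ++i) res[i] = out[i];
  res.attr("names") = CharacterVector::create("lit_m", "lit_s", "mic_r",
                                              "mic_k", "som_p", "som_c",
                                              "som_a", "respiration");
  return res;
}

// Gaussian elimination with partial pivoting for a 7x7 system; returns false
// if singular to working precision
static bool solve7(double A[7][7], double b[7], double xout[7]) {
  for (int c = 0; c < 7; ++c) {
    int best = c;
    double bestv = std::fabs(A[c][c]);
    for (int r = c + 1; r < 7; ++r)
      if (std::fabs(A[r][c]) > bestv) { bestv = std::fabs(A[r][c]); best = r; }
    if (bestv < 1e-300) return false;
    if (best != c) {
      for (int j = 0; j < 7; ++j) std::swap(A[c][j], A[best][j]);
      std::swap(b[c], b[best]);
    }
    for (int r = c + 1; r < 7; ++r) {
      const double f = A[r][c] / A[c][c];
      for (int j = c; j < 7; ++j) A[r][j] -= f * A[c][j];
      b[r] -= f * b[c];
    }
  }
  for (int r = 6; r >= 0; --r) {
    double s = b[r];
    for (int j = r + 1; j < 7; ++j) s -= A[r][j] * xout[j];
    xout[r] = s / A[r][r];
  }
  return true;
}

static double resid_norm(const double* f) {
  double m = 0.0;
  for (int i = 0; i < 7; ++i) m = std::max(m, std::fabs(f[i]));
  return m;
}

// Damped Newton on log-pools (guarantees positivity). tol is relative to the
// total input flux. Returns state, converged flag, residual.
// [[Rcpp::export(name = ".mimicsSteadyNewtonCpp")]]
List mimics_steady_newton_cpp(NumericVector init, double temp, double moisture,
                              double input, double fmet, double clay,
                              NumericVector par, double tol = 1e-8,
                              int maxit = 200) {
  Ctx c = make_ctx(temp, moisture, input, fmet, clay, REAL(par));
  double u[7];
  for (int i = 0; i < 7; ++i) {
    double x0 = init[i];
    if (!(x0 > 0)) x0 = 1e-8;
    u[i] = std::log(x0);
  }
  const double scale = std::max(input, 1e-300);
  double f[8];
  double x[7];
  bool converged = false;
  double rn = R_PosInf;

  for (int it = 0; it < maxit; ++it) {
    for (int i = 0; i < 7; ++i) x[i] = std::exp(u[i]);
    rhs_ctx(x, c, f);
    rn = resid_norm(f);
    if (rn / scale < tol) { converged = true; break; }

    // numeric Jacobian in u
    double J[7][7];
    const double h = 1e-7;
    double xp[7], fp[8];
    for (int j = 0; j < 7; ++j) {
      for (int i = 0; i < 7; ++i) xp[i] = x[i];
      xp[j] = std::exp(u[j] + h);
      rhs_ctx(xp, c, fp);
      for (int i = 0; i < 7; ++i) J[i][j] = (fp[i] - f[i]) / h;
    }
    double rhs[7], du[7];
    for (int i = 0; i < 7; ++i) rhs[i] = -f[i];
    if (!solve7(J, rhs, du)) break;

    // cap the step in log space, then backtrack until the residual shrinks
    double dmax = 0.0;
    for (int i = 0; i < 7; ++i) dmax = std::max(dmax, std::fabs(du[i]));
    double lam = dmax > 4.0 ? 4.0 / dmax : 1.0;
    bool accepted = false;
    for (int half = 0; half < 40; ++half) {
      double ut[7], xt[7], ft[8];
      for (int i = 0; i < 7; ++i) { ut[i] = u[i] + lam * du[i]; xt[i] = std::exp(ut[i]); }
      rhs_ctx(xt, c, ft);
      if (resid_norm(ft) < rn || half == 39) {
        for (int i = 0; i < 7; ++i) u[i] = ut[i];
        accepted = true;
        break;
      }
      lam *= 0.5;
    }
    if (!accepted) break;
  }

  NumericVector st(7);
  for (int i = 0; i < 7; ++i) st[i] = std::exp(u[i]);
  st.attr("names") = CharacterVector::create("lit_m", "lit_s", "mic_r", "mic_k",
                                             "som_p", "som_c", "som_a");
  return List::create(_["state"] = st, _["converged"] = converged,
                      _["residual"] = rn, _["residual_rel"] = rn / scale);
}

// Forward integration of the seven pools with fixed forcing (RK4 with fixed
// step). Used to spin the pools onto the attracting branch before the Newton
// polish, and as a long-run fallback.
// [[Rcpp::export(name = ".mimicsIntegrateCpp")]]
NumericVector mimics_integrate_cpp(NumericVector init, double temp,
                                   double moisture, double input, double fmet,
                                   double clay, NumericVector par,
                                   double hours, double dt = 24.0) {
  Ctx c = make_ctx(temp, moisture, input, fmet, clay, REAL(par));
  double x[7];
  for (int i = 0; i < 7; ++i) x[i] = std::max((double)init[i], 0.0);
  const long n = (long)std::ceil(hours / dt);
  double k1[8], k2[8], k3[8], k4[8], xt[7];
  for (long s = 0; s < n; ++s) {
    rhs_ctx(x, c, k1);
    for (int i = 0; i < 7; ++i) xt[i] = std::max(x[i] + 0.5 * dt * k1[i], 0.0);
    rhs_ctx(xt, c, k2);
    for (int i = 0; i < 7; ++i) xt[i] = std::max(x[i] + 0.5 * dt * k2[i], 0.0);
    rhs_ctx(xt, c, k3);
    for (int i = 0; i < 7; ++i) xt[i] = std::max(x[i] + dt * k3[i], 0.0);
    rhs_ctx(xt, c, k4);
    for (int i = 0; i < 7; ++i)
      x[i] = std::max(
          x[i] + dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]), 0.0);
  }
  NumericVector out(7);
  for (int i = 0; i < 7; ++i) out[i] = x[i];
  out.attr("names") = CharacterVector::create("lit_m", "lit_s", "mic_r",
                                              "mic_k", "som_p", "som_c",
                                              "som_a");
  return out;
}

// Litterbag overlay: two bag pools decomposed by the (fixed) background
// microbial pools under a daily climatology; all decomposed carbon leaves the
// system. Daily RK4 with optional substeps; returns total bag carbon per day
// (day 0 = deployment) plus the cumulative respired / assimilated split.
// [[Rcpp::export(name = ".litterbagRunCpp")]]
List litterbag_run_cpp(double bag_m0, double bag_s0, double mic_r, double mic_k,
                       NumericVector temp_daily, NumericVector moist_daily,
                       NumericVector par, int substeps = 1) {
  const double* p = REAL(par);
  const int ndays = temp_daily.size();
  if (moist_daily.size() != ndays) stop("forcing series length mismatch");
  NumericVector mass(ndays + 1), bm(ndays + 1), bs(ndays + 1);
  double bag_m = bag_m0, bag_s = bag_s0;
  double respired = 0.0, assimilated = 0.0;
  mass[0] = bag_m + bag_s; bm[0] = bag_m; bs[0] = bag_s;
  const double dt = 24.0 / substeps;

  double vmax[6], km[6];
  for (int d = 0; d < ndays; ++d) {
    const double temp = temp_daily[d], moist = moist_daily[d];
    resolve_kinetics(temp, 0.0, p, vmax, km);  // clay only affects SOM fluxes
    for (int s = 0; s < substeps; ++s) {
      // rate (per hour) of bag-pool loss; Michaelis-Menten in the bag pool
      auto rate_m = [&](double b) {
        return moist * (mic_r * vmax[0] * b / (km[0] + b) +
                        mic_k * vmax[3] * b / (km[3] + b));
      };
      auto rate_s = [&](double b) {
        return moist * (mic_r * vmax[1] * b / (km[1] + b) +
                        mic_k * vmax[4] * b / (km[4] + b));
      };
      const double m1 = rate_m(bag_m), s1 = rate_s(bag_s);
      const double m2 = rate_m(std::max(bag_m - 0.5 * dt * m1, 0.0));
      const double s2 = rate_s(std::max(bag_s - 0.5 * dt * s1, 0.0));
      const double m3 = rate_m(std::max(bag_m - 0.5 * dt * m2, 0.0));
      const double s3 = rate_s(std::max(bag_s - 0.5 * dt * s2, 0.0));
      const double m4 = rate_m(std::max(bag_m - dt * m3, 0.0));
      const double s4 = rate_s(std::max(bag_s - dt * s3, 0.0));
      const double dm = dt / 6.0 * (m1 + 2 * m2 + 2 * m3 + m4);
      const double ds = dt / 6.0 * (s1 + 2 * s2 + 2 * s3 + s4);
      const double lost_m = std::min(dm, bag_m), lost_s = std::min(ds, bag_s);
      bag_m -= lost_m;
      bag_s -= lost_s;
      // diagnostics: the respired vs would-be-assimilated split of the loss,
      // using the mean CUE of the two consumers weighted by their share
      const double wtot_m = mic_r * vmax[0] / (km[0] + bag_m) +
                            mic_k * vmax[3] / (km[3] + bag_m);
      const double cue_m = wtot_m > 0
          ? (p[28] * mic_r * vmax[0] / (km[0] + bag_m) +
             p[30] * mic_k * vmax[3] / (km[3] + bag_m)) / wtot_m
          : 0.0;
      const double wtot_s = mic_r * vmax[1] / (km[1] + bag_s) +
                            mic_k * vmax[4] / (km[4] + bag_s);
      const double cue_s = wtot_s > 0
          ? (p[29] * mic_r * vmax[1] / (km[1] + bag_s) +
             p[31] * mic_k * vmax[4] / (km[4] + bag_s)) / wtot_s
          : 0.0;
      assimilated += cue_m * lost_m + cue_s * lost_s;
      respired += (1.0 - cue_m) * lost_m + (1.0 - cue_s) * lost_s;
    }
    mass[d + 1] = bag_m + bag_s; bm[d + 1] = bag_m; bs[d + 1] = bag_s;
  }
  return List::create(_["mass"] = mass, _["bag_m"] = bm, _["bag_s"] = bs,
                      _["respired"] = respired,
                      _["assimilated"] = assimilated);
}
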