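// Compiled derivative of the coupled modified-A2O plant
// (7 ASM2d bioreactors + 10-layer Takacs settler).
// Mirrors the reference R implementation plant_derivs_r(); the two are
// held equivalent by tests.

#include <Rcpp.h>
using namespace Rcpp;

// component indices (canonical ASM2d order)
enum comp {
  SO2 = 0, SF, SA, SNH4, SNO3, SPO4, SI, SALK, SN2,
  XI, XS, XH, XPAO, XPP, XPHA, XAUT, XTSS, XMeOH, XMeP
};

// kinetic parameter indices (order of the 42-entry kinetic table)
enum kin {
  K_h = 0, eta_NO3_hyd, eta_fe, K_O2_hyd, K_NO3_hyd, K_X,
  mu_H, q_fe, eta_NO3_H, b_H, K_O2_H, K_F, K_fe, K_A_H, K_NO3_H,
  K_NH4_H, K_P_H, K_ALK_H,
  q_PHA, q_PP, mu_PAO, eta_NO3_PAO, b_PAO, b_PP, b_PHA, K_O2_PAO,
  K_NO3_PAO, K_A_PAO, K_NH4_PAO, K_PS, K_P_PAO, K_ALK_PAO, K_PP,
  K_MAX, K_IPP, K_PHA,
  mu_AUT, b_AUT, K_O2_AUT, K_NH4_AUT, K_ALK_AUT, K_P_AUT
};

static inline double mon(double S, double K) { return S / (K + S); }
static inline double off(double S, double K) { return K / (K + S); }

// the 21 ASM2d process rates; st points at 19 non-negative concentrations
static void asm2d_rates(const double* st, const double* k,
                        const double* chem, double* r) {
  const double so2 = st[SO2], sf = st[SF], sa = st[SA], snh4 = st[SNH4],
               sno3 = st[SNO3], spo4 = st[SPO4], salk = st[SALK],
               xs = st[XS], xh = st[XH], xpao = st[XPAO], xpp = st[XPP],
               xpha = st[XPHA], xaut = st[XAUT];
  const double rXS = xh > 0 ? xs / xh : 0.0;
  const double fXSXH = xh > 0 ? rXS / (k[K_X] + rXS) : 0.0;
  const double rPP = xpao > 0 ? xpp / xpao : 0.0;
  const double rPHA = xpao > 0 ? xpha / xpao : 0.0;
  const double fPP = rPP / (k[K_PP] + rPP);
  const double fPHA = rPHA / (k[K_PHA] + rPHA);
  double fPPmax = (k[K_MAX] - rPP) / (k[K_IPP] + k[K_MAX] - rPP);
  if (fPPmax < 0) fPPmax = 0;
  const double sfsa = (sf + sa) > 0 ? sf / (sf + sa) : 0.0;
  const double nutH = mon(snh4, k[K_NH4_H]) * mon(spo4, k[K_P_H]) *
                      mon(salk, k[K_ALK_H]);
  const double nutP = mon(salk, k[K_ALK_PAO]);

  r[0] = k[K_h] * mon(so2, k[K_O2_hyd]) * fXSXH * xh;
  r[1] = k[K_h] * k[eta_NO3_hyd] * off(so2, k[K_O2_hyd]) *
         mon(sno3, k[K_NO3_hyd]) * fXSXH * xh;
  r[2] = k[K_h] * k[eta_fe] * off(so2, k[K_O2_hyd]) *
         off(sno3, k[K_NO3_hyd]) * fXSXH * xh;
  r[3] = k[mu_H] * mon(so2, k[K_O2_H]) * mon(sf, k[K_F]) * sfsa * nutH * xh;
  r[4] = k[mu_H] * mon(so2, k[K_O2_H]) * mon(sa, k[K_A_H]) * (1 - sfsa) *
         nutH * xh;
  r[5] = k[mu_H] * k[eta_NO3_H] * off(so2, k[K_O2_H]) *
         mon(sno3, k[K_NO3_H]) * mon(sf, k[K_F]) * sfsa * nutH * xh;
  r[6] = k[mu_H] * k[eta_NO3_H] * off(so2, k[K_O2_H]) *
         mon(sno3, k[K_NO3_H]) * mon(sa, k[K_A_H]) * (1 - sfsa) * nutH * xh;
  r[7] = k[q_fe] * off(so2, k[K_O2_H]) * off(sno3, k[K_NO3_H]) *
         mon(sf, k[K_fe]) * mon(salk, k[K_ALK_H]) * xh;
  r[8] = k[b_H] * xh;
  r[9] = k[q_PHA] * mon(sa, k[K_A_PAO]) * nutP * fPP * xpao;
  const double store = k[q_PP] * mon(spo4, k[K_PS]) * nutP * fPHA *
                       fPPmax * xpao;
  r[10] = store * mon(so2, k[K_O2_PAO]);
  r[11] = store * k[eta_NO3_PAO] * off(so2, k[K_O2_PAO]) *
          mon(sno3, k[K_NO3_PAO]);
  const double grow = k[mu_PAO] * mon(snh4, k[K_NH4_PAO]) *
                      mon(spo4, k[K_P_PAO]) * nutP * fPHA * xpao;
  r[12] = grow * mon(so2, k[K_O2_PAO]);
  r[13] = grow * k[eta_NO3_PAO] * off(so2, k[K_O2_PAO]) *
          mon(sno3, k[K_NO3_PAO]);
  r[14] = k[b_PAO] * nutP * xpao;
  r[15] = k[b_PP] * nutP * xpp;
  r[16] = k[b_PHA] * nutP * xpha;
  r[17] = k[mu_AUT] * mon(so2, k[K_O2_AUT]) * mon(snh4, k[K_NH4_AUT]) *
          mon(spo4, k[K_P_AUT]) * mon(salk, k[K_ALK_AUT]) * xaut;
  r[18] = k[b_AUT] * xaut;
  if (chem[3] > 0.5) {  // chemical P enabled
    r[19] = chem[0] * spo4 * st[XMeOH];
    r[20] = chem[1] * st[XMeP] * mon(salk, chem[2]);
  } else {
    r[19] = 0.0;
    r[20] = 0.0;
  }
}

// plant context: copied once per integration so the per-step derivative
// has no R-object traffic
struct PlantCtx {
  std::vector<double> nu;        // 21*19, process-major: nu[p*19+j]
  std::vector<double> kin, chem, V, kla;
  double so_sat, Ql, Qs, Qw;
  int i_from, i_to;
  double A, hlay, v0, v0max, rh, rp, fns, Xt;
  int m, nlay;
  std::vector<double> tg, qg, Z;  // Z row-major: Z[i*19+j]
  int ngrid;
  bool valid = false;
};
static PlantCtx ctx;

// [[Rcpp::export]]
void plant_ctx_set(List parms) {
  NumericMatrix nu = parms["nu"];
  ctx.nu.assign(21 * 19, 0.0);
  for (int p = 0; p < 21; ++p)
    for (int j = 0; j < 19; ++j) ctx.nu[p * 19 + j] = nu(p, j);
  ctx.kin = as<std::vector<double> >(parms["kin"]);
  ctx.chem = as<std::vector<double> >(parms["chem"]);
  ctx.V = as<std::vector<double> >(parms["volumes"]);
  ctx.kla = as<std::vector<double> >(parms["kla"]);
  ctx.so_sat = as<double>(parms["so_sat"]);
  ctx.Ql = as<double>(parms["Ql"]);
  ctx.Qs = as<double>(parms["Qs"]);
  ctx.Qw = as<double>(parms["Qw"]);
  ctx.i_from = as<int>(parms["i_from"]) - 1;
  ctx.i_to = as<int>(parms["i_to"]) - 1;
  NumericVector set = parms["settler"];
  ctx.A = set[0]; ctx.hlay = set[1]; ctx.m = (int)set[2] - 1;
  ctx.v0 = set[3]; ctx.v0max = set[4]; ctx.rh = set[5]; ctx.rp = set[6];
  ctx.fns = set[7]; ctx.Xt = set[8]; ctx.nlay = (int)set[9];
  ctx.tg = as<std::vector<double> >(parms["tgrid"]);
  ctx.qg = as<std::vector<double> >(parms["qgrid"]);
  NumericMatrix Z = parms["zgrid"];
  ctx.ngrid = Z.nrow();
  ctx.Z.assign(ctx.ngrid * 19, 0.0);
  for (int i = 0; i < ctx.ngrid; ++i)
    for (int j = 0; j < 19; ++j) ctx.Z[i * 19 + j] = Z(i, j);
  ctx.valid = true;
}

static void plant_deriv_core(double t, const double* y, double* dy) {
  const int nsol = 9, ncomp = 19, ntank = 7;
  const int nlay = ctx.nlay;
  const int nstate = ntank * ncomp + nlay * (1 + nsol);
  const double A = ctx.A, hlay = ctx.hlay;
  const int m = ctx.m;

  static std::vector<double> yc;
  yc.resize(nstate);
  for (int i = 0; i < nstate; ++i) yc[i] = y[i] > 0 ? y[i] : 0.0;

  // influent at t (linear interpolation on the shared grid)
  double Qin, zin[19];
  {
    const int n = ctx.ngrid;
    int lo = 0, hi = n - 1;
    double w = 0.0;
    if (n == 1 || t <= ctx.tg[0]) { hi = 0; lo = 0; }
    else if (t >= ctx.tg[n - 1]) { lo = n - 1; hi = n - 1; }
    else {
      while (hi - lo > 1) {
        int mid = (lo + hi) / 2;
        if (ctx.tg[mid] <= t) lo = mid; else hi = mid;
      }
      w = (t - ctx.tg[lo]) / (ctx.tg[hi] - ctx.tg[lo]);
    }
    Qin = ctx.qg[lo] + w * (ctx.qg[hi] - ctx.qg[lo]);
    for (int j = 0; j < ncomp; ++j)
      zin[j] = ctx.Z[lo * 19 + j] + w * (ctx.Z[hi * 19 + j] -
                                         ctx.Z[lo * 19 + j]);
  }

  const double* kin = &ctx.kin[0];
  const double* chem = &ctx.chem[0];
  const double* V = &ctx.V[0];
  const double* kla = &ctx.kla[0];
  const double so_sat = ctx.so_sat;
  const int i_from = ctx.i_from, i_to = ctx.i_to;
  const double v0 = ctx.v0, v0max = ctx.v0max, rh = ctx.rh, rp = ctx.rp,
               fns = ctx.fns, Xt = ctx.Xt;

  // flows
  const double Q_int = ctx.Ql * Qin, Q_ret = ctx.Qs * Qin,
               Q_was = ctx.Qw * Qin;
  const double Q_base = Qin + Q_ret;
  std::vector<double> Q_tank(ntank, Q_base);
  for (int i = i_to; i <= i_from; ++i) Q_tank[i] = Q_base + Q_int;
  const double Q_feed = Q_base;
  const double Q_under = Q_ret + Q_was;
  const double Q_eff = Q_feed - Q_under;

  const double* tanks = &yc[0];                  // tank i: tanks[i*19 + j]
  const double* Xl = &yc[ntank * ncomp];         // settler TSS layers
  const double* Sl = &yc[ntank * ncomp + nlay];  // solubles, comp-major

  // settler feed solids: 0.75 * particulate COD groups of T6
  const double* feed = &tanks[6 * ncomp];
  const double X_feed = 0.75 * (feed[XI] + feed[XS] + feed[XPP] +
                                feed[XPHA] + feed[XH] + feed[XPAO] +
                                feed[XAUT]);
  const double r_under = X_feed > 1e-12 ? Xl[nlay - 1] / X_feed : 0.0;

  // underflow composition (sludge return)
  std::vector<double> under(ncomp);
  for (int j = 0; j < nsol; ++j) under[j] = Sl[j * nlay + (nlay - 1)];
  for (int j = nsol; j < ncomp; ++j) under[j] = feed[j] * r_under;

  // tank balances
  double rates[21];
  std::vector<double> cin(ncomp);
  for (int i = 0; i < ntank; ++i) {
    const double* st = &tanks[i * ncomp];
    double Qin_i;
    if (i == 0) {
      Qin_i = Qin + Q_ret;
      for (int j = 0; j < ncomp; ++j)
        cin[j] = (Qin * zin[j] + Q_ret * under[j]) / Qin_i;
    } else {
      const double Q_up = Q_tank[i - 1];
      const double* up = &tanks[(i - 1) * ncomp];
      if (i == i_to) {
        const double* rec = &tanks[i_from * ncomp];
        Qin_i = Q_up + Q_int;
        for (int j = 0; j < ncomp; ++j)
          cin[j] = (Q_up * up[j] + Q_int * rec[j]) / Qin_i;
      } else {
        Qin_i = (i == i_from + 1) ? Q_tank[i] : Q_up;
        for (int j = 0; j < ncomp; ++j) cin[j] = up[j];
      }
    }
    asm2d_rates(st, &kin[0], &chem[0], rates);
    double* d = &dy[i * ncomp];
    const double dil = Qin_i / V[i];
    for (int j = 0; j < ncomp; ++j) {
      double rsum = 0.0;
      for (int p = 0; p < 21; ++p) rsum += rates[p] * ctx.nu[p * 19 + j];
      d[j] = dil * (cin[j] - st[j]) + rsum;
    }
    if (kla[i] > 0) d[SO2] += kla[i] * (so_sat - st[SO2]);
  }

  // settler solids
  const double v_up = Q_eff / A, v_dn = Q_under / A;
  std::vector<double> vs(nlay), J(nlay), Js(nlay - 1);
  for (int i = 0; i < nlay; ++i) {
    double Xs = Xl[i] - fns * X_feed;
    double v = v0 * (std::exp(-rh * Xs) - std::exp(-rp * Xs));
    if (v > v0max) v = v0max;
    if (v < 0) v = 0;
    vs[i] = v;
    J[i] = v * Xl[i];
  }
  for (int i = 0; i < nlay - 1; ++i) {
    if (i < m)
      Js[i] = (Xl[i + 1] <= Xt) ? J[i] : std::min(J[i], J[i + 1]);
    else
      Js[i] = std::min(J[i], J[i + 1]);
  }
  double* dX = &dy[ntank * ncomp];
  for (int i = 0; i < nlay; ++i) {
    double adv;
    if (i < m) adv = v_up * (Xl[i + 1] - Xl[i]);
    else if (i == m) adv = Q_feed * X_feed / A - (v_up + v_dn) * Xl[i];
    else adv = v_dn * (Xl[i - 1] - Xl[i]);
    const double setl = (i > 0 ? Js[i - 1] : 0.0) -
                        (i < nlay - 1 ? Js[i] : 0.0);
    dX[i] = (adv + setl) / hlay;
  }

  // settler solubles (ideal advection), component-major storage
  double* dS = &dy[ntank * ncomp + nlay];
  for (int s = 0; s < nsol; ++s) {
    const double* Sc = &Sl[s * nlay];
    double* dSc = &dS[s * nlay];
    const double Sf = feed[s];
    for (int i = 0; i < nlay; ++i) {
      if (i < m) dSc[i] = v_up * (Sc[i + 1] - Sc[i]) / hlay;
      else if (i == m)
        dSc[i] = (Q_feed * Sf / A - (v_up + v_dn) * Sc[i]) / hlay;
      else dSc[i] = v_dn * (Sc[i - 1] - Sc[i]) / hlay;
    }
  }
}

// fast path used by the simulator: context must have been set by
// plant_ctx_set() for the current model/influent
// [[Rcpp::export]]
NumericVector plant_deriv_fast(double t, NumericVector y) {
  if (!ctx.valid) stop("plant context not set; call plant_ctx_set() first");
  NumericVector dy(y.size());
  plant_deriv_core(t, REAL(y), REAL(dy));
  return dy;
}

// self-contained variant (sets the context from `parms` on every call);
// kept as the plain functional interface used in equivalence tests
// [[Rcpp::export]]
NumericVector plant_deriv_cpp(double t, NumericVector y, List parms) {
  plant_ctx_set(parms);
  NumericVector dy(y.size());
  plant_deriv_core(t, REAL(y), REAL(dy));
  return dy;
}
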