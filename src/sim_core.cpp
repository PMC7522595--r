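#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lumped-parameter LV + systemic Windkessel + microaxial pump + dissected
// coronary branch. Fixed-step RK4 keeps trajectories bit-reproducible for a
// given parameter set; the flap resistance is an algebraic constraint solved
// by damped fixed-point iteration at every derivative evaluation.

struct Params {
  double T, emin, emax, v0, sys_frac, relax_frac;
  double r_mitral, r_aortic, r_systemic, c_aorta, p_atrium, p_venous;
  double qnom, kp;               // ml/s, (ml/s)/mmHg; qnom = 0 when pump off
  double gamma_flap, r_cor, r_micro_sys, r_micro_dia, tau_false;
};

static inline double activation(double tp, const Params &pp) {
  double T1 = pp.sys_frac * pp.T, T2 = pp.relax_frac * pp.T;
  if (tp < T1) return 0.5 * (1.0 - std::cos(M_PI * tp / T1));
  if (tp < T1 + T2) return 0.5 * (1.0 + std::cos(M_PI * (tp - T1) / T2));
  return 0.0;
}

struct Derived {
  double plv, ptrue, qcor, qimp, qin, qout, act, rtrue;
};

static inline void deriv(double t, const double y[3], const Params &pp,
                         double dy[3], Derived &d) {
  double tp = t - pp.T * std::floor(t / pp.T);  // cycle phase; avoids fmod
  double a = activation(tp, pp);
  double E = pp.emin + (pp.emax - pp.emin) * a;
  double vlv = y[0], pao = y[1], pfalse = y[2];
  double plv = E * (vlv - pp.v0);
  double qin = (pp.p_atrium > plv) ? (pp.p_atrium - plv) / pp.r_mitral : 0.0;
  double qout = (plv > pao) ? (plv - pao) / pp.r_aortic : 0.0;
  double qimp = pp.qnom - pp.kp * (pao - plv);
  if (qimp < 0.0) qimp = 0.0;
  double rmicro = pp.r_micro_dia + (pp.r_micro_sys - pp.r_micro_dia) * a;
  // flap: true-lumen inlet resistance inflates with false-over-true pressure
  // excess (10 mmHg scale); solve P_true = P_ao - Q_cor * R_true by damped
  // fixed point (contractive for the parameter ranges used here)
  double ptrue = pao, rtrue = pp.r_cor, qcor = 0.0;
  for (int it = 0; it < 30; ++it) {
    double excess = pfalse - ptrue;
    if (excess < 0.0) excess = 0.0;
    rtrue = pp.r_cor * (1.0 + pp.gamma_flap * excess / 10.0);
    qcor = (pao - pp.p_venous) / (rtrue + rmicro);
    if (qcor < 0.0) qcor = 0.0;
    double pnew = pao - qcor * rtrue;
    if (std::fabs(pnew - ptrue) < 1e-10) { ptrue = pnew; break; }
    ptrue = 0.5 * (ptrue + pnew);
  }
  dy[0] = qin - qout - qimp;
  dy[1] = (qout + qimp - (pao - pp.p_venous) / pp.r_systemic - qcor) / pp.c_aorta;
  dy[2] = (pao - pfalse) / pp.tau_false;
  d.plv = plv; d.ptrue = ptrue; d.qcor = qcor; d.qimp = qimp;
  d.qin = qin; d.qout = qout; d.act = a; d.rtrue = rtrue;
}

// [[Rcpp::export(name = ".sim_core")]]
NumericMatrix sim_core(List par, int n_steps, double dt,
                       double vlv0, double pao0, double pfalse0) {
  Params pp;
  pp.T = as<double>(par["T"]);
  pp.emin = as<double>(par["e_min"]);
  pp.emax = as<double>(par["e_max"]);
  pp.v0 = as<double>(par["v0"]);
  pp.sys_frac = as<double>(par["sys_frac"]);
  pp.relax_frac = as<double>(par["relax_frac"]);
  pp.r_mitral = as<double>(par["r_mitral"]);
  pp.r_aortic = as<double>(par["r_aortic"]);
  pp.r_systemic = as<double>(par["r_systemic"]);
  pp.c_aorta = as<double>(par["c_aorta"]);
  pp.p_atrium = as<double>(par["p_atrium"]);
  pp.p_venous = as<double>(par["p_venous"]);
  pp.qnom = as<double>(par["qnom_ml_s"]);
  pp.kp = as<double>(par["kp_ml_s_mmhg"]);
  pp.gamma_flap = as<double>(par["flap_gamma"]);
  pp.r_cor = as<double>(par["r_coronary_base"]);
  pp.r_micro_sys = as<double>(par["r_micro_sys"]);
  pp.r_micro_dia = as<double>(par["r_micro_dia"]);
  pp.tau_false = as<double>(par["tau_false"]);

  NumericMatrix out(n_steps, 11);
  double y[3] = {vlv0, pao0, pfalse0};
  double k1[3], k2[3], k3[3], k4[3], yt[3];
  Derived d1, dtmp;

  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;
    deriv(t, y, pp, k1, d1);
    out(i, 0) = y[0];        // V_lv (ml)
    out(i, 1) = d1.plv;      // P_lv (mmHg)
    out(i, 2) = y[1];        // P_ao (mmHg)
    out(i, 3) = y[2];        // P_false (mmHg)
    out(i, 4) = d1.ptrue;    // P_true (mmHg)
    out(i, 5) = d1.qcor;     // Q_cor (ml/s)
    out(i, 6) = d1.qimp;     // Q_imp (ml/s)
    out(i, 7) = d1.qin;      // Q_in (ml/s)
    out(i, 8) = d1.qout;     // Q_out (ml/s)
    out(i, 9) = d1.act;      // activation a(t)
    out(i, 10) = d1.rtrue;   // R_true (mmHg*s/ml)
    for (int j = 0; j < 3; ++j) yt[j] = y[j] + 0.5 * dt * k1[j];
    deriv(t + 0.5 * dt, yt, pp, k2, dtmp);
    for (int j = 0; j < 3; ++j) yt[j] = y[j] + 0.5 * dt * k2[j];
    deriv(t + 0.5 * dt, yt, pp, k3, dtmp);
    for (int j = 0; j < 3; ++j) yt[j] = y[j] + dt * k3[j];
    deriv(t + dt, yt, pp, k4, dtmp);
    for (int j = 0; j < 3; ++j) {
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (!std::isfinite(y[j])) {
        stop("unstable integration: non-finite state at step %d (t = %.4f s)",
             i + 1, t + dt);
      }
    }
  }
  colnames(out) = CharacterVector::create(
    "v_lv", "p_lv", "p_ao", "p_false", "p_true", "q_cor", "q_imp",
    "q_in", "q_out", "activation", "r_true");
  return out;
}
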