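#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step explicit Euler core for the compartment/connector network.
//
// Per step, in order: elastances -> pressures -> flows -> (record) ->
// controller update (writes the afferent resistance used from the NEXT step,
// an explicit one-step lag) -> volume update.  Units: mmHg, L, s.
//
// Boundary compartments have their pressure prescribed per step and their
// volume is not integrated (used by the renal perfusion-pressure clamp).
//
// [[Rcpp::export]]
List sim_core_cpp(NumericVector E_const,
                  IntegerVector tv_idx,      // 0-based compartment indices
                  NumericMatrix tv_act,      // steps_per_beat x n_tv, in [0,1]
                  NumericVector tv_ees,
                  NumericVector tv_ed,
                  NumericVector V0,
                  NumericVector V_init,
                  IntegerVector bnd_idx,     // 0-based, prescribed pressure
                  NumericMatrix bnd_P,       // n_steps x n_bnd
                  IntegerVector src,         // 0-based
                  IntegerVector tgt,
                  NumericVector R,
                  LogicalVector valve,
                  double dt,
                  int n_steps,
                  int steps_per_beat,
                  int record_every,
                  int phase0,                // beat phase index at t = 0
                  List ctrl,
                  CharacterVector comp_names)
{
  const int n = E_const.size();
  const int m = src.size();
  const int n_tv = tv_idx.size();
  const int n_bnd = bnd_idx.size();

  std::vector<double> V(V_init.begin(), V_init.end());
  std::vector<double> P(n), E(n), Q(m), Rw(R.begin(), R.end());
  std::vector<bool> is_bnd(n, false);
  for (int b = 0; b < n_bnd; ++b) is_bnd[bnd_idx[b]] = true;

  // per-compartment inflow/outflow bookkeeping handled via src/tgt sweeps

  // ---- controller setup -------------------------------------------------
  const bool mr_on  = as<bool>(ctrl["mr_active"]);
  const bool tgf_on = as<bool>(ctrl["tgf_active"]);
  const bool any_ctrl = mr_on || tgf_on;
  const int aff = as<int>(ctrl["afferent"]);      // connector index, 0-based
  const int ar_comp = as<int>(ctrl["ar_comp"]);
  const int vc_comp = as<int>(ctrl["vc_comp"]);
  const int gfr_conn = as<int>(ctrl["gfr_conn"]);
  const double p0 = as<double>(ctrl["p0"]), p1 = as<double>(ctrl["p1"]);
  const double q0 = as<double>(ctrl["q0"]), kk = as<double>(ctrl["k"]);
  const double tau1 = as<double>(ctrl["tau1"]), tau2 = as<double>(ctrl["tau2"]);
  const double g_mr = as<double>(ctrl["g_mr"]);
  const double r_base = as<double>(ctrl["r_base"]);
  const double floor_frac = as<double>(ctrl["floor_frac"]);
  const bool tau_literal = as<bool>(ctrl["tau_literal"]);
  const double r_gl_vr = as<double>(ctrl["r_gl_vr"]);
  const double r_gl_tu = as<double>(ctrl["r_gl_tu"]);
  const double r_tu_vr = as<double>(ctrl["r_tu_vr"]);
  const double r_vr_vc = as<double>(ctrl["r_vr_vc"]);
  const double op_gfr = as<double>(ctrl["op_gfr"]);   // ml/min
  const double th_gfr = as<double>(ctrl["th_gfr"]);
  const double sa_gfr = as<double>(ctrl["sa_gfr"]);
  const double tau3 = as<double>(ctrl["tau3"]), tau4 = as<double>(ctrl["tau4"]);
  const double g_tgf = as<double>(ctrl["g_tgf"]);
  const int a1 = as<int>(ctrl["a1"]);   // round(delta1/dt)
  const int a2 = as<int>(ctrl["a2"]);   // round(delta2/dt)
  const int a3 = as<int>(ctrl["a3"]);   // round(delta3/dt)
  const int gavg = as<int>(ctrl["gfr_avg_steps"]);  // 0 = instantaneous

  double dr_mr = as<double>(ctrl["dr_mr"]);
  double dr_tgf = as<double>(ctrl["dr_tgf"]);
  NumericVector p_buf_in = ctrl["p_buf"];     // length a2 + 1
  NumericVector g_buf_in = ctrl["gfr_buf"];   // length a3 + 1
  std::vector<double> p_buf(p_buf_in.begin(), p_buf_in.end());
  std::vector<double> g_buf(g_buf_in.begin(), g_buf_in.end());
  int p_head = as<int>(ctrl["p_head"]);
  int g_head = as<int>(ctrl["g_head"]);
  const int pL = (int)p_buf.size();
  const int gL = (int)g_buf.size();
  const double r_floor = floor_frac * r_base;
  // downstream of the afferent arteriole: GL_VR parallel (GL_TU + TU_VR),
  // in series with VR_VC
  const double r_down = 1.0 / (1.0 / r_gl_vr + 1.0 / (r_gl_tu + r_tu_vr)) +
    r_vr_vc;
  double r_aff = as<double>(ctrl["r_aff"]);
  if (!any_ctrl) r_aff = Rw[aff];
  Rw[aff] = r_aff;

  // ---- recording --------------------------------------------------------
  const int n_rec = (n_steps - 1) / record_every + 1;
  NumericMatrix recP(n_rec, n), recV(n_rec, n), recQ(n_rec, m);
  NumericVector rec_t(n_rec), rec_raff(n_rec), rec_drmr(n_rec),
    rec_drtgf(n_rec), rec_sensed(n_rec);
  int irec = 0;

  for (int s = 0; s < n_steps; ++s) {
    const int ph = (phase0 + s) % steps_per_beat;
    // elastances and pressures
    for (int i = 0; i < n; ++i) E[i] = E_const[i];
    for (int j = 0; j < n_tv; ++j) {
      const int i = tv_idx[j];
      E[i] = tv_ed[j] + tv_act(ph, j) * (tv_ees[j] - tv_ed[j]);
    }
    for (int i = 0; i < n; ++i) P[i] = E[i] * (V[i] - V0[i]);
    for (int b = 0; b < n_bnd; ++b) P[bnd_idx[b]] = bnd_P(s, b);

    // flows (valves: exactly zero backward flow)
    for (int j = 0; j < m; ++j) {
      double q = (P[src[j]] - P[tgt[j]]) / Rw[j];
      if (valve[j] && q < 0.0) q = 0.0;
      Q[j] = q;
    }

    if (s % record_every == 0) {
      rec_t[irec] = s * dt;
      for (int i = 0; i < n; ++i) { recP(irec, i) = P[i]; recV(irec, i) = V[i]; }
      for (int j = 0; j < m; ++j) recQ(irec, j) = Q[j];
      rec_raff[irec] = Rw[aff];
      rec_drmr[irec] = dr_mr;
      rec_drtgf[irec] = dr_tgf;
      ++irec;
    }

    // ---- controller: sense now, act on the next step --------------------
    if (any_ctrl) {
      p_head = (p_head + 1) % pL;
      p_buf[p_head] = P[ar_comp];
      g_head = (g_head + 1) % gL;
      g_buf[g_head] = Q[gfr_conn];

      if (mr_on) {
        // sensed pressure: max over ages [delta1, delta2]
        double pmax = -1e300;
        for (int a = a1; a <= a2; ++a) {
          const double v = p_buf[(p_head - a % pL + pL) % pL];
          if (v > pmax) pmax = v;
        }
        const double p_vc = P[vc_comp];
        // piecewise target conductance
        double c_t;
        if (pmax < p0) {
          c_t = q0 / (p0 - p_vc);
        } else if (pmax <= p1) {
          c_t = q0 * (1.0 + kk * (pmax - p0) / p0) / (pmax - p_vc);
        } else {
          c_t = q0 * (1.0 + kk * (p1 - p0) / p0) / (p1 - p_vc);
        }
        double r_t = 1.0 / c_t - r_down;   // afferent share of the target
        if (r_t < r_floor) r_t = r_floor;
        const double dR = r_t - r_base;
        const bool constrict = tau_literal ? (Rw[aff] > r_t) : (r_t > Rw[aff]);
        const double tau = constrict ? tau1 : tau2;
        dr_mr += dt * (dR - dr_mr) / tau;
      }
      if (tgf_on) {
        double gd;
        if (gavg > 0) {
          // beat-averaged sensing: mean over the cycle ending delta3 ago
          double acc = 0.0;
          for (int a = a3; a < a3 + gavg; ++a)
            acc += g_buf[(g_head - a % gL + gL) % gL];
          gd = acc / gavg;
        } else {
          gd = g_buf[(g_head - a3 % gL + gL) % gL];       // L/s, delayed
        }
        gd *= 60000.0;                                    // -> ml/min
        double a_tgf = gd;
        if (a_tgf >= sa_gfr) a_tgf = sa_gfr;
        if (a_tgf <= th_gfr) a_tgf = th_gfr;
        a_tgf -= op_gfr;
        const double tau = (a_tgf > 0.0) ? tau3 : tau4;
        dr_tgf += dt * (a_tgf - dr_tgf) / tau;
      }
      double r_new = r_base;
      if (mr_on) r_new += g_mr * dr_mr;
      if (tgf_on) r_new += g_tgf * dr_tgf;
      if (r_new < r_floor) r_new = r_floor;
      Rw[aff] = r_new;
    }

    // volume update
    for (int j = 0; j < m; ++j) {
      if (!is_bnd[tgt[j]]) V[tgt[j]] += dt * Q[j];
      if (!is_bnd[src[j]]) V[src[j]] -= dt * Q[j];
    }

    if ((s & 1023) == 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(V[i])) {
          stop("numerical failure: non-finite volume in compartment '%s' at t = %.3f s",
               std::string(comp_names[i]).c_str(), s * dt);
        }
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(V[i])) {
      stop("numerical failure: non-finite volume in compartment '%s' at end of run",
           std::string(comp_names[i]).c_str());
    }
  }

  return List::create(
    _["time"] = rec_t, _["P"] = recP, _["V"] = recV, _["Q"] = recQ,
    _["r_aff"] = rec_raff, _["dr_mr"] = rec_drmr, _["dr_tgf"] = rec_drtgf,
    _["V_final"] = NumericVector(V.begin(), V.end()),
    _["state"] = List::create(
      _["dr_mr"] = dr_mr, _["dr_tgf"] = dr_tgf,
      _["p_buf"] = NumericVector(p_buf.begin(), p_buf.end()),
      _["gfr_buf"] = NumericVector(g_buf.begin(), g_buf.end()),
      _["p_head"] = p_head, _["g_head"] = g_head,
      _["r_aff"] = Rw[aff],
      _["phase"] = (phase0 + n_steps) % steps_per_beat));
}
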