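// Multicompartment cable integrator.
//
// Backward-Euler voltage step on the tree (Hines elimination: compartments
// ordered parent-before-child, one up sweep + one down sweep), gating
// variables advanced by exact exponential (Rush-Larsen) updates at the
// start-of-step voltage.  Gate steady states and per-step decay factors are
// supplied as lookup tables on a voltage grid, built in R from the same
// rate functions the tests exercise, so the engine has no second copy of
// the kinetics.
//
// Units: mV, ms, nA, uS, nF, mM.  Channel current I = g*(E - V);
// calcium current reported with the inward-negative convention g*(V - E).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct GateTab {
  int exponent;
  std::vector<double> inf, edt, tau;
};

struct Clamp {
  int gate, comp;                  // comp == -1: all active compartments
  double val;                      // value for the current step
  const std::vector<double>* trace;
};

struct Mech {
  std::vector<double> gbar;        // uS per compartment
  double erev;                     // ignored if is_ca
  bool is_ca;
  bool shift_tau;
  std::vector<double> dv, tau_scale;
  std::vector<int> active;         // compartments with gbar > 0
  std::vector<GateTab> gates;
  std::vector<std::vector<double>> state;  // gate x compartment
  std::vector<Clamp> clamps;
};

struct ExpSyn {
  int comp; double decay, gmax, erev, s; std::vector<double> times; size_t ptr;
};

struct NmdaSyn {
  int comp; double tau_x, tau_s, alpha_s, mg, gmax, erev, s, x;
  std::vector<double> times; size_t ptr;
};

inline double interp(const std::vector<double>& tab, double pos) {
  int i = (int)pos;
  double f = pos - i;
  return tab[i] + f * (tab[i + 1] - tab[i]);
}

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List model, List stim, List cfg) {
  const int ncomp = as<int>(model["ncomp"]);
  const IntegerVector parent = model["parent"];
  const NumericVector cap = model["cap_nF"];
  const NumericVector gax = model["gax_uS"];
  const NumericVector gleak = model["gleak_uS"];
  const double eleak = as<double>(model["eleak"]);

  // voltage grid for the gate tables
  const List vg = model["vgrid"];
  const double v0 = as<double>(vg["v0"]);
  const double vstep = as<double>(vg["step"]);
  const int nv = as<int>(vg["n"]);

  // mechanisms
  List mlist = model["mechs"];
  std::vector<Mech> mechs(mlist.size());
  for (int m = 0; m < (int)mlist.size(); ++m) {
    List ml = mlist[m];
    Mech& M = mechs[m];
    NumericVector gb = ml["gbar_uS"];
    M.gbar.assign(gb.begin(), gb.end());
    M.erev = as<double>(ml["erev"]);
    M.is_ca = as<bool>(ml["is_ca"]);
    M.shift_tau = as<bool>(ml["shift_tau"]);
    NumericVector dv = ml["dv"], ts = ml["tau_scale"];
    M.dv.assign(dv.begin(), dv.end());
    M.tau_scale.assign(ts.begin(), ts.end());
    for (int i = 0; i < ncomp; ++i) if (M.gbar[i] > 0) M.active.push_back(i);
    List gl = ml["gates"];
    for (int g = 0; g < (int)gl.size(); ++g) {
      List gg = gl[g];
      GateTab gt;
      gt.exponent = as<int>(gg["exponent"]);
      NumericVector inf = gg["inf"], edt = gg["edt"], tau = gg["tau"];
      gt.inf.assign(inf.begin(), inf.end());
      gt.edt.assign(edt.begin(), edt.end());
      gt.tau.assign(tau.begin(), tau.end());
      M.gates.push_back(gt);
    }
    M.state.assign(M.gates.size(), std::vector<double>(ncomp, 0.0));
  }

  // calcium pool
  List ca = model["ca"];
  const NumericVector ca_gamma = ca["gamma"];       // mM per nA*ms, per comp
  const double ca_tau = as<double>(ca["tau_decay"]);
  const double ca_rest = as<double>(ca["ca_rest"]);
  const double ca_o = as<double>(ca["ca_out"]);
  const double rt2f_mV = as<double>(ca["rt2f_mV"]); // (RT/2F) in mV
  std::vector<int> ca_comps;
  for (auto& M : mechs) if (M.is_ca)
    for (int i : M.active)
      if (std::find(ca_comps.begin(), ca_comps.end(), i) == ca_comps.end())
        ca_comps.push_back(i);
  std::vector<double> cai(ncomp, ca_rest), eca(ncomp, 0.0);
  for (int i : ca_comps) eca[i] = rt2f_mV * std::log(ca_o / cai[i]);

  // stimuli
  NumericMatrix pulses = stim["pulses"];   // comp onset dur amp
  NumericMatrix alphas = stim["alphas"];   // comp onset tau gmax erev
  const double dt = as<double>(cfg["dt"]);

  List el = stim["expsyn"];
  std::vector<ExpSyn> esyn(el.size());
  for (int i = 0; i < (int)el.size(); ++i) {
    List s = el[i];
    esyn[i].comp = as<int>(s["comp"]);
    esyn[i].decay = std::exp(-dt / as<double>(s["tau_s"]));
    esyn[i].gmax = as<double>(s["gmax_uS"]);
    esyn[i].erev = as<double>(s["erev"]);
    esyn[i].s = 0.0; esyn[i].ptr = 0;
    NumericVector tt = s["times"];
    esyn[i].times.assign(tt.begin(), tt.end());
  }
  List nl = stim["nmda"];
  std::vector<NmdaSyn> nsyn(nl.size());
  for (int i = 0; i < (int)nl.size(); ++i) {
    List s = nl[i];
    nsyn[i].comp = as<int>(s["comp"]);
    nsyn[i].tau_x = as<double>(s["tau_x"]);
    nsyn[i].tau_s = as<double>(s["tau_s"]);
    nsyn[i].alpha_s = as<double>(s["alpha_s"]);
    nsyn[i].mg = as<double>(s["mg"]);
    nsyn[i].gmax = as<double>(s["gmax_uS"]);
    nsyn[i].erev = as<double>(s["erev"]);
    nsyn[i].s = 0.0; nsyn[i].x = 0.0; nsyn[i].ptr = 0;
    NumericVector tt = s["times"];
    nsyn[i].times.assign(tt.begin(), tt.end());
  }

  // config
  const double t_stop = as<double>(cfg["t_stop"]);
  const double settle = as<double>(cfg["settle"]);
  const double v_init = as<double>(cfg["v_init"]);
  const int stride = as<int>(cfg["record_stride"]);
  const IntegerVector probes = cfg["probes"];
  const IntegerVector ca_probes = cfg["ca_probes"];
  const IntegerMatrix gate_probes = cfg["gate_probes"]; // mech gate comp
  const int spike_comp = as<int>(cfg["spike_comp"]);
  const double spike_thresh = as<double>(cfg["spike_thresh"]);
  const double spike_refrac = as<double>(cfg["spike_refrac"]);

  // replay clamps: gate values forced to a recorded time course
  List rl = cfg["replay"];
  std::vector<std::vector<double>> replay_traces(rl.size());
  for (int i = 0; i < (int)rl.size(); ++i) {
    List r = rl[i];
    NumericVector vv = r["values"];
    replay_traces[i].assign(vv.begin(), vv.end());
    Clamp c;
    c.gate = as<int>(r["gate"]);
    c.comp = as<int>(r["comp"]);
    c.trace = &replay_traces[i];
    c.val = replay_traces[i].front();
    mechs[as<int>(r["mech"])].clamps.push_back(c);
  }

  const int nsettle = (int)std::lround(settle / dt);
  const int nmain = (int)std::lround(t_stop / dt);
  const int nrec = nmain / stride + 1;

  // state
  std::vector<double> V(ncomp, v_init);
  auto vindex = [&](double v) {
    double pos = (v - v0) / vstep;
    if (pos < 0) pos = 0;
    if (pos > nv - 1.000001) pos = nv - 1.000001;
    return pos;
  };
  // init gates to steady state at v_init
  for (auto& M : mechs)
    for (size_t g = 0; g < M.gates.size(); ++g)
      for (int i : M.active)
        M.state[g][i] = interp(M.gates[g].inf, vindex(v_init - M.dv[i]));

  // recording buffers
  NumericVector t_out(nrec);
  NumericMatrix v_out(nrec, probes.size());
  NumericMatrix ca_out(nrec, ca_probes.size());
  NumericMatrix g_out(nrec, gate_probes.nrow());
  std::vector<double> spikes;
  std::vector<double> vmax(ncomp, v_init);
  std::vector<double> G(ncomp), RHS(ncomp), D(ncomp);
  std::vector<double> gca(ncomp), gcaE(ncomp);
  double last_spike = -1e18, v_soma_prev = v_init;

  auto record = [&](int rec_idx, double t) {
    t_out[rec_idx] = t;
    for (int p = 0; p < probes.size(); ++p) v_out(rec_idx, p) = V[probes[p]];
    for (int p = 0; p < ca_probes.size(); ++p)
      ca_out(rec_idx, p) = cai[ca_probes[p]];
    for (int p = 0; p < gate_probes.nrow(); ++p)
      g_out(rec_idx, p) =
        mechs[gate_probes(p, 0)].state[gate_probes(p, 1)][gate_probes(p, 2)];
  };

  // refresh clamp values for step index k (0..nmain; during settle use 0)
  auto set_clamp_values = [&](int k) {
    for (auto& M : mechs)
      for (auto& C : M.clamps) {
        int kk = k < 0 ? 0 : k;
        if (kk >= (int)C.trace->size()) kk = (int)C.trace->size() - 1;
        C.val = (*C.trace)[kk];
        if (C.comp >= 0) M.state[C.gate][C.comp] = C.val;
        else for (int i : M.active) M.state[C.gate][i] = C.val;
      }
  };
  set_clamp_values(0);

  int rec_idx = 0;
  const bool any_clamps = rl.size() > 0;
  for (int k = -nsettle; k < nmain; ++k) {
    const double t = k * dt, tn = t + dt;
    if (k == 0) record(0, 0.0);          // state after the settle phase
    if (any_clamps) set_clamp_values(k + 1);
    for (int i = 0; i < ncomp; ++i) { G[i] = 0; RHS[i] = 0; gca[i] = 0; gcaE[i] = 0; }

    // --- gates (Rush-Larsen at V_t), channel conductances
    for (auto& M : mechs) {
      const size_t ng = M.gates.size();
      const bool has_clamp = !M.clamps.empty();
      for (int i : M.active) {
        const double vi = V[i] - M.dv[i];
        const double pos_inf = vindex(vi);
        const double pos_tau = M.shift_tau ? pos_inf : vindex(V[i]);
        double open = 1.0;
        for (size_t g = 0; g < ng; ++g) {
          GateTab& gt = M.gates[g];
          double& st = M.state[g][i];
          bool clamped = false;
          if (has_clamp)
            for (auto& C : M.clamps)
              if (C.gate == (int)g && (C.comp == -1 || C.comp == i)) {
                st = C.val; clamped = true; break;
              }
          if (!clamped) {
            double e = interp(gt.edt, pos_tau);
            const double sc = M.tau_scale[i];
            if (sc != 1.0) e = std::pow(e, 1.0 / sc);
            const double inf = interp(gt.inf, pos_inf);
            st = inf + (st - inf) * e;
          }
          double sg = st;
          for (int q = 1; q < gt.exponent; ++q) sg *= st;
          open *= sg;
        }
        const double gch = M.gbar[i] * open;
        const double E = M.is_ca ? eca[i] : M.erev;
        G[i] += gch;
        RHS[i] += gch * E;
        if (M.is_ca) { gca[i] += gch; gcaE[i] += gch * E; }
      }
    }

    // --- synapses
    for (auto& S : esyn) {
      S.s *= S.decay;
      while (S.ptr < S.times.size() && S.times[S.ptr] <= tn && S.times[S.ptr] > t) {
        S.s += 1.0; ++S.ptr;
      }
      if (S.s > 0) { G[S.comp] += S.gmax * S.s; RHS[S.comp] += S.gmax * S.s * S.erev; }
    }
    for (auto& S : nsyn) {
      const double decay = std::exp(-dt / S.tau_x);
      const double xbar = S.x * S.tau_x * (1.0 - decay) / dt;
      const double a = S.alpha_s * xbar, b = 1.0 / S.tau_s + a;
      const double sss = a / b;
      S.s = sss + (S.s - sss) * std::exp(-b * dt);
      if (S.s > 1.0) S.s = 1.0;
      S.x *= decay;
      while (S.ptr < S.times.size() && S.times[S.ptr] <= tn && S.times[S.ptr] > t) {
        S.x += 1.0; ++S.ptr;
      }
      if (S.s > 0) {
        const double B = 1.0 / (1.0 + S.mg * std::exp(-0.062 * V[S.comp]) / 3.57);
        const double g = S.gmax * S.s * B;
        G[S.comp] += g; RHS[S.comp] += g * S.erev;
      }
    }
    for (int r = 0; r < alphas.nrow(); ++r) {
      const double u = (tn - alphas(r, 1)) / alphas(r, 2);
      if (u >= 0) {
        const double g = alphas(r, 3) * u * std::exp(1.0 - u);
        const int c = (int)alphas(r, 0);
        G[c] += g; RHS[c] += g * alphas(r, 4);
      }
    }
    for (int r = 0; r < pulses.nrow(); ++r)
      if (tn >= pulses(r, 1) && tn < pulses(r, 1) + pulses(r, 2))
        RHS[(int)pulses(r, 0)] += pulses(r, 3);

    // --- assemble and solve (Hines)
    for (int i = 0; i < ncomp; ++i) {
      const double cdt = cap[i] / dt;
      D[i] = cdt + G[i] + gleak[i];
      RHS[i] += cdt * V[i] + gleak[i] * eleak;
    }
    for (int i = 0; i < ncomp; ++i) {
      const int p = parent[i];
      if (p >= 0) { D[i] += gax[i]; D[p] += gax[i]; }
    }
    for (int i = ncomp - 1; i >= 1; --i) {
      const int p = parent[i];
      const double f = gax[i] / D[i];
      D[p] -= gax[i] * f;
      RHS[p] += RHS[i] * f;
    }
    V[0] = RHS[0] / D[0];
    for (int i = 1; i < ncomp; ++i)
      V[i] = (RHS[i] + gax[i] * V[parent[i]]) / D[i];

    if (!std::isfinite(V[0]))
      stop("integration failure at t = %f ms (compartment 1)", tn);

    // --- calcium pool (exact exponential step at the new voltage)
    for (int i : ca_comps) {
      const double ica = gca[i] * V[i] - gcaE[i];     // nA, inward < 0
      const double css = ca_rest - ca_gamma[i] * ica * ca_tau;
      cai[i] = css + (cai[i] - css) * std::exp(-dt / ca_tau);
      if (cai[i] < 1e-10) cai[i] = 1e-10;
      eca[i] = rt2f_mV * std::log(ca_o / cai[i]);
    }

    if (k >= 0) {
      for (int i = 0; i < ncomp; ++i) if (V[i] > vmax[i]) vmax[i] = V[i];
      // spike detection: upward threshold crossing with refractory gap
      const double vs = V[spike_comp];
      if (vs >= spike_thresh && v_soma_prev < spike_thresh &&
          tn - last_spike >= spike_refrac) {
        spikes.push_back(tn);
        last_spike = tn;
      }
      v_soma_prev = vs;
      if ((k + 1) % stride == 0) record(++rec_idx, tn);
    } else {
      v_soma_prev = V[spike_comp];
    }
    if (k % 40000 == 0) Rcpp::checkUserInterrupt();
  }

  // final gate states (per mechanism, gate x comp)
  List gstates(mechs.size());
  for (size_t m = 0; m < mechs.size(); ++m) {
    NumericMatrix gm(mechs[m].state.size(), ncomp);
    for (size_t g = 0; g < mechs[m].state.size(); ++g)
      for (int i = 0; i < ncomp; ++i) gm(g, i) = mechs[m].state[g][i];
    gstates[m] = gm;
  }

  return List::create(
    _["t"] = t_out, _["v"] = v_out, _["ca"] = ca_out, _["gates"] = g_out,
    _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
    _["vmax"] = NumericVector(vmax.begin(), vmax.end()),
    _["v_end"] = NumericVector(V.begin(), V.end()),
    _["cai_end"] = NumericVector(cai.begin(), cai.end()),
    _["gate_states"] = gstates);
}
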