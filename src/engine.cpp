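// Implicit (backward-Euler) integrator for a branched cable with
// conductance-based membranes, double-exponential synapses and time-windowed
// parameter interventions. Units: mV, ms, uS, nA, nF, mM; compartment areas
// in cm^2. The tree system is solved exactly each step with the usual
// Hines elimination (compartments ordered so parent index < child index).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double FARADAY = 96485.309; // C/mol

// x/(1-exp(-x/q)) with the x->0 limit q
static inline double trap(double x, double q) {
  if (std::fabs(x / q) < 1e-6) return q * (1.0 + x / (2.0 * q));
  return x / (1.0 - std::exp(-x / q));
}

// Gate layout per compartment (11 gates):
// 0 na.m 1 na.h 2 kdr.n 3 km.n 4 ka.m 5 ka.h 6 cat.m 7 cat.h
// 8 cahva.m 9 cahva.h 10 kca.n
// kca.n depends on [Ca], all others on V only.
static void gate_inf_tau(double v, double ca, double* inf, double* tau) {
  double a, b;
  // Na: Boltzmann steady states with bell-shaped time constants; inactivation
  // is slow near its midpoint and fast at spike voltages, so the low channel
  // densities of this model still regenerate a full (if small-amplitude) AP.
  inf[0] = 1.0 / (1.0 + std::exp(-(v + 30.0) / 5.0));
  tau[0] = 0.04 + 0.2 / std::cosh((v + 30.0) / 12.0);
  inf[1] = 1.0 / (1.0 + std::exp((v + 48.0) / 6.0));
  tau[1] = 0.25 + 4.0 / std::cosh((v + 48.0) / 10.0);
  // Kdr: high-threshold delayed rectifier
  inf[2] = 1.0 / (1.0 + std::exp(-(v + 25.0) / 9.0));
  tau[2] = 0.5 + 3.0 / std::cosh((v + 25.0) / 20.0);
  // Km: slow non-inactivating muscarinic
  inf[3] = 1.0 / (1.0 + std::exp(-(v + 35.0) / 9.0));
  tau[3] = 10.0 + 30.0 / std::cosh((v + 35.0) / 20.0);
  // KA: transient A-type, depolarised activation with subthreshold
  // inactivation (fully available from rest, inactivated by slow
  // depolarisation)
  inf[4] = 1.0 / (1.0 + std::exp(-(v + 10.0) / 19.0));
  tau[4] = 0.2 + 1.0 / std::cosh((v + 10.0) / 30.0);
  inf[5] = 1.0 / (1.0 + std::exp((v + 56.0) / 6.0));
  tau[5] = 5.0 + 20.0 / std::cosh((v + 56.0) / 15.0);
  // CaT (low-threshold transient)
  inf[6] = 1.0 / (1.0 + std::exp(-(v + 57.0) / 6.2));
  tau[6] = 0.612 + 1.0 / (std::exp(-(v + 132.0) / 16.7) + std::exp((v + 16.8) / 18.2));
  inf[7] = 1.0 / (1.0 + std::exp((v + 81.0) / 4.0));
  tau[7] = (v < -80.0) ? std::exp((v + 467.0) / 66.6)
                       : 28.0 + std::exp(-(v + 22.0) / 10.5);
  // CaHVA (high-voltage activated)
  a = 0.055 * trap(-27.0 - v, 3.8);
  b = 0.94 * std::exp((-75.0 - v) / 17.0);
  inf[8] = a / (a + b); tau[8] = 1.0 / (a + b);
  a = 0.000457 * std::exp((-13.0 - v) / 50.0);
  b = 0.0065 / (std::exp((-v - 15.0) / 28.0) + 1.0);
  inf[9] = a / (a + b); tau[9] = 1.0 / (a + b);
  // KCa (calcium-dependent)
  a = 0.01 * ca; // per ms per mM
  b = 0.02;
  inf[10] = a / (a + b); tau[10] = 1.0 / (a + b);
}

// [[Rcpp::export]]
NumericMatrix cpp_gate_tables(double v, double ca) {
  double inf[11], tau[11];
  gate_inf_tau(v, ca, inf, tau);
  NumericMatrix out(11, 2);
  for (int i = 0; i < 11; ++i) { out(i, 0) = inf[i]; out(i, 1) = tau[i]; }
  colnames(out) = CharacterVector::create("inf", "tau");
  return out;
}

struct CaDyn { double depth, taur, cainf; };

// [[Rcpp::export]]
List cpp_run(IntegerVector parent,        // 0-based, -1 for root; parent[i] < i
             NumericVector cm_nF,
             NumericVector g_ax_uS,       // coupling to parent (root: 0)
             NumericVector g_pas_uS,
             double e_pas,
             NumericMatrix gbar_uS,       // ncomp x 7: na kdr km ka cat cahva kca
             IntegerVector tree,          // 0 soma 1 apical 2 basal
             NumericVector area_cm2,
             double e_na, double e_k, double e_ca,
             double ca_depth_um, double ca_taur_ms, double ca_inf_mM,
             double mg_mM,
             IntegerVector syn_comp,      // 0-based compartment index
             IntegerVector syn_kind,      // 0 AMPA 1 NMDA 2 GABAA
             IntegerVector syn_role,      // 0 background 1 stimulus
             NumericVector syn_gmax_uS,
             NumericVector syn_tau1, NumericVector syn_tau2,
             NumericVector syn_e,
             NumericVector evt_time,      // sorted ascending delivery times
             IntegerVector evt_syn,       // 0-based synapse index
             NumericVector evt_w,         // event weight (weight_scale)
             IntegerVector ic_comp, NumericVector ic_amp_nA,
             NumericVector ic_start, NumericVector ic_end,
             IntegerVector ivn_tree,      // 1 apical 2 basal
             IntegerVector ivn_param,     // 0 g_Na 1 stim_syn_weight
             NumericVector ivn_scale,
             NumericVector ivn_t0, NumericVector ivn_t1,
             double dt, double duration, double v_init,
             IntegerVector record_idx,    // 0-based
             int record_every) {
  const int nc = parent.size();
  const int ns = syn_comp.size();
  const int nevt = evt_time.size();
  const int nic = ic_comp.size();
  const int nivn = ivn_tree.size();
  const int nsteps = (int)std::lround(duration / dt);
  const int nrec = record_idx.size();
  const int nsamp = nsteps / record_every + 1;

  NumericMatrix traces(nsamp, nrec);
  NumericVector tout(nsamp);

  std::vector<double> v(nc, v_init), vnew(nc), ca(nc, ca_inf_mM);
  std::vector<double> gates(nc * 11);
  {
    double inf[11], tau[11];
    gate_inf_tau(v_init, ca_inf_mM, inf, tau);
    for (int i = 0; i < nc; ++i)
      for (int g = 0; g < 11; ++g) gates[i * 11 + g] = inf[g];
  }

  // synapse states and per-synapse decay factors / normalisation; only
  // synapses with non-negligible state are visited each step
  std::vector<double> sA(ns, 0.0), sB(ns, 0.0), sdA(ns), sdB(ns), snorm(ns);
  std::vector<double> v_gmax(ns), v_e(ns);
  std::vector<int> v_comp(ns), v_kind(ns), v_role(ns);
  std::vector<char> is_active(ns, 0);
  std::vector<int> active;
  active.reserve(ns);
  for (int s = 0; s < ns; ++s) {
    sdA[s] = std::exp(-dt / syn_tau1[s]);
    sdB[s] = std::exp(-dt / syn_tau2[s]);
    double tp = syn_tau1[s] * syn_tau2[s] / (syn_tau2[s] - syn_tau1[s]) *
                std::log(syn_tau2[s] / syn_tau1[s]);
    snorm[s] = 1.0 / (std::exp(-tp / syn_tau2[s]) - std::exp(-tp / syn_tau1[s]));
    v_gmax[s] = syn_gmax_uS[s]; v_e[s] = syn_e[s];
    v_comp[s] = syn_comp[s]; v_kind[s] = syn_kind[s]; v_role[s] = syn_role[s];
  }

  std::vector<double> diag(nc), rhs(nc), bvec(nc);
  std::vector<double> Gsum(nc), Ssum(nc), Iinj(nc), gca_uS(nc);
  const double ca_drive_scale = 10000.0 / (2.0 * FARADAY * ca_depth_um); // mM cm^2 / (ms mA)

  int evt_ptr = 0;
  // record t = 0
  for (int r = 0; r < nrec; ++r) traces(0, r) = v[record_idx[r]];
  tout[0] = 0.0;
  int samp = 1;

  for (int step = 1; step <= nsteps; ++step) {
    double tn = step * dt; // time being solved for

    // intervention factors for this step
    double f_gna[3] = {1.0, 1.0, 1.0};
    double f_syn[3] = {1.0, 1.0, 1.0};
    for (int k = 0; k < nivn; ++k) {
      if (tn >= ivn_t0[k] - 1e-9 && tn <= ivn_t1[k] + 1e-9) {
        if (ivn_param[k] == 0) f_gna[ivn_tree[k]] *= ivn_scale[k];
        else f_syn[ivn_tree[k]] *= ivn_scale[k];
      }
    }

    // deliver events in (tn - dt, tn]
    while (evt_ptr < nevt && evt_time[evt_ptr] <= tn) {
      int s = evt_syn[evt_ptr];
      sA[s] += evt_w[evt_ptr];
      sB[s] += evt_w[evt_ptr];
      if (!is_active[s]) { is_active[s] = 1; active.push_back(s); }
      ++evt_ptr;
    }

    // membrane: advance gates (exact exponential) and accumulate conductances
    for (int i = 0; i < nc; ++i) {
      double inf[11], tau[11];
      gate_inf_tau(v[i], ca[i], inf, tau);
      double* g = &gates[i * 11];
      for (int k = 0; k < 11; ++k)
        g[k] = inf[k] + (g[k] - inf[k]) * std::exp(-dt / tau[k]);

      double gna = gbar_uS(i, 0) * f_gna[tree[i]] * g[0] * g[0] * g[0] * g[1];
      double gkdr = gbar_uS(i, 1) * g[2];
      double gkm = gbar_uS(i, 2) * g[3];
      double gka = gbar_uS(i, 3) * g[4] * g[4] * g[4] * g[4] * g[5];
      double gcat = gbar_uS(i, 4) * g[6] * g[6] * g[7];
      double gcahva = gbar_uS(i, 5) * g[8] * g[8] * g[9];
      double gkca = gbar_uS(i, 6) * g[10];
      gca_uS[i] = gcat + gcahva;
      double gk = gkdr + gkm + gka + gkca;
      Gsum[i] = g_pas_uS[i] + gna + gk + gca_uS[i];
      Ssum[i] = g_pas_uS[i] * e_pas + gna * e_na + gk * e_k + gca_uS[i] * e_ca;
      Iinj[i] = 0.0;
    }

    // synapses: decay active states, add conductance at their compartments
    for (size_t k = 0; k < active.size(); ) {
      int s = active[k];
      sA[s] *= sdA[s];
      sB[s] *= sdB[s];
      if (sB[s] < 1e-10) { // fully decayed: retire from the active set
        sA[s] = 0.0; sB[s] = 0.0; is_active[s] = 0;
        active[k] = active.back();
        active.pop_back();
        continue;
      }
      double g = v_gmax[s] * snorm[s] * (sB[s] - sA[s]);
      if (g > 0.0) {
        int i = v_comp[s];
        if (v_kind[s] == 1) { // NMDA magnesium block, evaluated at V(t)
          g *= 1.0 / (1.0 + (mg_mM / 3.57) * std::exp(-0.062 * v[i]));
        }
        if (v_role[s] == 1 && v_kind[s] != 2) g *= f_syn[tree[i]];
        Gsum[i] += g;
        Ssum[i] += g * v_e[s];
      }
      ++k;
    }

    // current clamps active if tn within [start, end]
    for (int k = 0; k < nic; ++k)
      if (tn >= ic_start[k] - 1e-9 && tn <= ic_end[k] + 1e-9)
        Iinj[ic_comp[k]] += ic_amp_nA[k];

    // assemble and solve the tree system (symmetric, Hines ordering)
    for (int i = 0; i < nc; ++i) {
      double cdt = cm_nF[i] / dt;
      diag[i] = cdt + Gsum[i];
      rhs[i] = cdt * v[i] + Ssum[i] + Iinj[i];
      bvec[i] = -g_ax_uS[i];
      if (parent[i] >= 0) {
        diag[i] += g_ax_uS[i];
        diag[parent[i]] += g_ax_uS[i];
      }
    }
    for (int i = nc - 1; i > 0; --i) {
      int p = parent[i];
      double f = bvec[i] / diag[i];
      diag[p] -= f * bvec[i];
      rhs[p] -= f * rhs[i];
    }
    vnew[0] = rhs[0] / diag[0];
    for (int i = 1; i < nc; ++i)
      vnew[i] = (rhs[i] - bvec[i] * vnew[parent[i]]) / diag[i];

    // calcium dynamics driven by the Ca currents at the new voltage
    for (int i = 0; i < nc; ++i) {
      if (gca_uS[i] > 0.0 || ca[i] != ca_inf_mM) {
        double ica_mAcm2 = gca_uS[i] * (vnew[i] - e_ca) * 1e-6 / area_cm2[i];
        double drive = -ca_drive_scale * ica_mAcm2; // mM/ms, inward current raises [Ca]
        if (drive < 0.0) drive = 0.0;
        double target = ca_inf_mM + drive * ca_taur_ms;
        ca[i] = target + (ca[i] - target) * std::exp(-dt / ca_taur_ms);
      }
      v[i] = vnew[i];
    }

    if (step % 200 == 0) {
      for (int i = 0; i < nc; ++i)
        if (!std::isfinite(v[i]))
          stop("numerical-state error: non-finite voltage at t = %f ms, compartment %d",
               tn, i + 1);
    }

    if (step % record_every == 0) {
      for (int r = 0; r < nrec; ++r) traces(samp, r) = v[record_idx[r]];
      tout[samp] = tn;
      ++samp;
    }
  }

  for (int i = 0; i < nc; ++i)
    if (!std::isfinite(v[i]))
      stop("numerical-state error: non-finite voltage at end of run, compartment %d", i + 1);

  return List::create(_["time"] = tout, _["traces"] = traces);
}
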