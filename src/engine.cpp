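// Forward-Euler engine for the coupled Izhikevich network.
//
// Conventions: time ms, voltage mV, current pA, conductance nS,
// capacitance pF, distance um. Receptor currents follow the driving-force
// form I = s * g * (V - E); they enter the membrane equation with a minus
// sign (excitatory reversal at 0 mV depolarises) and enter the LFP sum as
// written. Spike detection is a post-update threshold test; the reset is
// applied immediately and the spike time recorded at the end of the step.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double mg_block(double v, double mg) {
  return 1.0 + mg * std::exp(-0.062 * v) / 3.57;
}

struct IzhPop {
  int n;
  std::vector<double> C, k, a, b, c, d, vr, vt, vc, v, u;
  void init(const NumericMatrix& par) {
    n = par.nrow();
    C.resize(n); k.resize(n); a.resize(n); b.resize(n); c.resize(n);
    d.resize(n); vr.resize(n); vt.resize(n); vc.resize(n);
    v.resize(n); u.resize(n);
    for (int i = 0; i < n; ++i) {
      C[i] = par(i, 0); k[i] = par(i, 1); a[i] = par(i, 2); b[i] = par(i, 3);
      c[i] = par(i, 4); d[i] = par(i, 5); vr[i] = par(i, 6); vt[i] = par(i, 7);
      vc[i] = par(i, 8); v[i] = par(i, 6); u[i] = 0.0;
    }
  }
  // returns true if the cell spiked on this step
  inline bool step(int i, double I, double dt) {
    double dv = (k[i] * (v[i] - vr[i]) * (v[i] - vt[i]) - u[i] + I) / C[i];
    double du = a[i] * (b[i] * (v[i] - vr[i]) - u[i]);
    v[i] += dt * dv;
    u[i] += dt * du;
    if (v[i] >= vc[i]) {
      v[i] = c[i];
      u[i] += d[i];
      return true;
    }
    return false;
  }
};

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix mc_par, NumericMatrix gc_par,
                  IntegerVector syn_mc, IntegerVector syn_gc,
                  NumericVector syn_dist, NumericVector syn_lfpw,
                  NumericVector ddr,   // gA,gN,gG,tauA,tauNr,tauNd,tauG,alphaN,kappa,W,lambda,Ee,Ei,Mg
                  NumericVector osnp,  // gA,gN,tauA,tauNr,tauNd,alphaN,W
                  bool use_osn, int n_osn,
                  NumericVector osn_rate, NumericVector osn_phase,
                  double f_sniff, NumericVector osn_lfpw,
                  NumericVector mc_dc, NumericVector gc_dc,
                  NumericVector mc_sin_amp, NumericVector mc_sin_phase,
                  LogicalVector gc_active, double gaba_scale,
                  double duration, double dt,
                  bool record_lfp, bool lfp_include_osn,
                  IntegerVector rec_mc, IntegerVector rec_gc,
                  bool kappa_self = true) {
  IzhPop mc, gc;
  mc.init(mc_par);
  gc.init(gc_par);
  const int nmc = mc.n, ngc = gc.n, nsyn = syn_mc.size();
  const double gA = ddr[0], gN = ddr[1], gG = ddr[2], tauA = ddr[3],
               tauNr = ddr[4], tauNd = ddr[5], tauG = ddr[6], alphaN = ddr[7],
               kappa = ddr[8], W = ddr[9], lam_len = ddr[10], Ee = ddr[11],
               Ei = ddr[12], Mg = ddr[13];
  const double ogA = osnp[0], ogN = osnp[1], otauA = osnp[2], otauNr = osnp[3],
               otauNd = osnp[4], oalpha = osnp[5], oW = osnp[6];

  // gating state per dendrodendritic synapse
  std::vector<double> sA(nsyn, 0.0), sN(nsyn, 0.0), nN(nsyn, 0.0),
      sG(nsyn, 0.0), atten(nsyn);
  std::vector<char> act(nsyn);
  for (int s = 0; s < nsyn; ++s) {
    atten[s] = std::exp(-syn_dist[s] / lam_len);
    act[s] = gc_active[syn_gc[s] - 1] ? 1 : 0;
  }
  // CSR adjacency
  std::vector<int> mc_off(nmc + 1, 0), gc_off(ngc + 1, 0), mc_adj(nsyn),
      gc_adj(nsyn);
  {
    for (int s = 0; s < nsyn; ++s) {
      ++mc_off[syn_mc[s]];
      ++gc_off[syn_gc[s]];
    }
    for (int i = 0; i < nmc; ++i) mc_off[i + 1] += mc_off[i];
    for (int g = 0; g < ngc; ++g) gc_off[g + 1] += gc_off[g];
    std::vector<int> pm(mc_off.begin(), mc_off.end() - 1),
        pg(gc_off.begin(), gc_off.end() - 1);
    for (int s = 0; s < nsyn; ++s) {
      mc_adj[pm[syn_mc[s] - 1]++] = s;
      gc_adj[pg[syn_gc[s] - 1]++] = s;
    }
  }
  // OSN gating per (MC, input fiber)
  std::vector<double> oA, oN, on_;
  if (use_osn) {
    oA.assign((size_t)nmc * n_osn, 0.0);
    oN.assign((size_t)nmc * n_osn, 0.0);
    on_.assign((size_t)nmc * n_osn, 0.0);
  }

  const int nsteps = (int)std::lround(duration / dt);
  std::vector<int> spike_cell;
  std::vector<double> spike_t;
  NumericVector lfp(record_lfp ? nsteps : 0);
  NumericMatrix vtr_mc(rec_mc.size() > 0 ? nsteps : 0, rec_mc.size());
  NumericMatrix vtr_gc(rec_gc.size() > 0 ? nsteps : 0, rec_gc.size());
  std::vector<double> Imc(nmc), Igc(ngc);

  const double w2pi = 2.0 * M_PI * f_sniff / 1000.0; // rad per ms

  for (int st = 0; st < nsteps; ++st) {
    double t = st * dt;
    double lfp_t = 0.0;
    std::fill(Imc.begin(), Imc.end(), 0.0);
    std::fill(Igc.begin(), Igc.end(), 0.0);

    // dendrodendritic receptor currents + gating decay
    for (int s = 0; s < nsyn; ++s) {
      if (!act[s]) continue;
      int i = syn_mc[s] - 1, g = syn_gc[s] - 1;
      double vg = gc.v[g], vm = mc.v[i];
      double Ia = sA[s] * gA * (vg - Ee);
      double In = sN[s] * gN * (vg - Ee) / mg_block(vg, Mg);
      double Ig = sG[s] * gG * gaba_scale * (vm - Ei) * atten[s];
      Igc[g] -= Ia + In;
      Imc[i] -= Ig;
      if (record_lfp) lfp_t += (Ia + In + Ig) * syn_lfpw[s];
      sA[s] -= dt * sA[s] / tauA;
      sG[s] -= dt * sG[s] / tauG;
      sN[s] += dt * (-sN[s] / tauNd + alphaN * nN[s] * (1.0 - sN[s]));
      nN[s] -= dt * nN[s] / tauNr;
    }

    // sensory (OSN) synapses onto MCs
    if (use_osn) {
      for (int i = 0; i < nmc; ++i) {
        double vm = mc.v[i];
        double r = osn_rate[i] / 2.0 +
                   osn_rate[i] / 4.0 *
                       (std::sin(w2pi * t - osn_phase[i]) + 1.0);
        double p = r * dt / 1000.0;
        double blk = mg_block(vm, Mg);
        size_t base = (size_t)i * n_osn;
        double Isum = 0.0;
        for (int j = 0; j < n_osn; ++j) {
          size_t s = base + j;
          double Ia = oA[s] * ogA * vm;          // Ee = 0
          double In = oN[s] * ogN * vm / blk;
          Isum += Ia + In;
          oA[s] -= dt * oA[s] / otauA;
          oN[s] += dt * (-oN[s] / otauNd + oalpha * on_[s] * (1.0 - oN[s]));
          on_[s] -= dt * on_[s] / otauNr;
          if (p > 0 && unif_rand() < p) {
            oA[s] += oW * (1.0 - oA[s]);
            on_[s] += oW * (1.0 - on_[s]);
          }
        }
        Imc[i] -= Isum;
        if (record_lfp && lfp_include_osn) lfp_t += Isum * osn_lfpw[i];
      }
    }

    // injected currents
    for (int i = 0; i < nmc; ++i) {
      double I = mc_dc[i];
      double amp = mc_sin_amp[i];
      if (amp != 0.0)
        I += amp / 2.0 +
             amp / 4.0 * (std::sin(w2pi * t - mc_sin_phase[i]) + 1.0);
      Imc[i] += I;
    }
    for (int g = 0; g < ngc; ++g) Igc[g] += gc_dc[g];

    // advance cells; collect spikes
    for (int i = 0; i < nmc; ++i) {
      if (mc.step(i, Imc[i], dt)) {
        spike_cell.push_back(i + 1);
        spike_t.push_back(t + dt);
        // excite all connected GC spines; second-order GABA via shared GCs
        for (int a = mc_off[i]; a < mc_off[i + 1]; ++a) {
          int s = mc_adj[a];
          if (!act[s]) continue;
          sA[s] += W * (1.0 - sA[s]);
          nN[s] += W * (1.0 - nN[s]);
          int g = syn_gc[s] - 1;
          for (int b = gc_off[g]; b < gc_off[g + 1]; ++b) {
            int s2 = gc_adj[b];
            if (!kappa_self && syn_mc[s2] - 1 == i) continue;
            sG[s2] += kappa * W * (1.0 - sG[s2]);
          }
        }
      }
    }
    for (int g = 0; g < ngc; ++g) {
      if (!gc_active[g]) continue;
      if (gc.step(g, Igc[g], dt)) {
        spike_cell.push_back(nmc + g + 1);
        spike_t.push_back(t + dt);
        for (int a = gc_off[g]; a < gc_off[g + 1]; ++a) {
          int s = gc_adj[a];
          sG[s] += W * (1.0 - sG[s]);
        }
      }
    }

    if (record_lfp) lfp[st] = lfp_t;
    for (int r = 0; r < rec_mc.size(); ++r)
      vtr_mc(st, r) = mc.v[rec_mc[r] - 1];
    for (int r = 0; r < rec_gc.size(); ++r)
      vtr_gc(st, r) = gc.v[rec_gc[r] - 1];

    if (st % 2000 == 0) {
      bool bad = false;
      for (int i = 0; i < nmc && !bad; ++i)
        if (!std::isfinite(mc.v[i])) bad = true;
      if (bad) stop("integration failure: non-finite membrane potential");
    }
  }

  return List::create(_["spike_cell"] = wrap(spike_cell),
                      _["spike_t"] = wrap(spike_t), _["lfp"] = lfp,
                      _["v_mc"] = vtr_mc, _["v_gc"] = vtr_gc,
                      _["n_steps"] = nsteps);
}

// Single Izhikevich cell under direct current; returns spike count within
// the recorded window plus spike times and (optionally) the voltage trace.
// [[Rcpp::export]]
List cpp_single_cell(NumericVector par, double I, double duration, double dt,
                     double pad, bool trace = false) {
  double C = par[0], k = par[1], a = par[2], b = par[3], c = par[4],
         d = par[5], vr = par[6], vt = par[7], vc = par[8];
  double v = vr, u = 0.0;
  int nsteps = (int)std::lround((duration + pad) / dt);
  int nsp = 0;
  std::vector<double> tt, vv;
  if (trace) vv.reserve(nsteps);
  for (int st = 0; st < nsteps; ++st) {
    double te = (st + 1) * dt;
    double dv = (k * (v - vr) * (v - vt) - u + I) / C;
    double du = a * (b * (v - vr) - u);
    v += dt * dv;
    u += dt * du;
    if (v >= vc) {
      v = c;
      u += d;
      if (te > pad) {
        ++nsp;
        tt.push_back(te - pad);
      }
    }
    if (trace) vv.push_back(v);
  }
  return List::create(_["n_spikes"] = nsp, _["spike_t"] = wrap(tt),
                      _["v"] = wrap(vv));
}
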