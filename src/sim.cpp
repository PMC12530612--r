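// Integrator core for the toroidal E/I spiking network.
//
// Conventions (shared with the R layer):
//   units: time ms, voltage mV, capacitance pF, conductance nS, current pA
//   neurons: global ids 0..(NE-1) excitatory, NE..(NE+NI-1) inhibitory,
//            each population laid out row-major on a side x side grid
//   synapses: alpha conductance implemented as the exact two-state filter
//       dx/dt = -x/tau,  dg/dt = (x - g)/tau,   spike: x += w * e
//     so a single spike gives g(t) = w * (t/tau) * exp(1 - t/tau), peaking
//     at exactly w one time constant after delivery.
//   channels per neuron: 0 recurrent exc, 1 recurrent inh,
//                        2 external exc, 3 external inh
//
// All randomness goes through R's RNG (unif_rand / R::rpois) so set.seed()
// on the R side makes every run bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double E_CONST = 2.718281828459045235360287471352662498;

// Sample one connection class on the torus.  The Gaussian kernel is
// translation invariant, so probabilities are precomputed over the
// side x side offset grid and looked up per ordered pair.
// [[Rcpp::export]]
List cpp_build_class_adjacency(int side, double sigma, double scale,
                               bool exclude_self) {
  const int N = side * side;
  std::vector<double> kern((size_t)N);
  for (int dr = 0; dr < side; ++dr) {
    int wr = dr < side - dr ? dr : side - dr;
    for (int dc = 0; dc < side; ++dc) {
      int wc = dc < side - dc ? dc : side - dc;
      double d2 = (double)wr * wr + (double)wc * wc;
      double p = scale * std::exp(-d2 / (2.0 * sigma * sigma));
      kern[(size_t)dr * side + dc] = p > 1.0 ? 1.0 : p;
    }
  }
  std::vector<int> targets;
  double guess = scale * 2.0 * M_PI * sigma * sigma * N * 1.15 + 1024;
  double cap = (double)N * (double)N;
  targets.reserve((size_t)(guess < cap ? guess : cap));
  IntegerVector row_ptr(N + 1);
  row_ptr[0] = 0;
  for (int pre = 0; pre < N; ++pre) {
    const int pr = pre / side, pc = pre % side;
    for (int r2 = 0; r2 < side; ++r2) {
      const int dr = r2 - pr < 0 ? r2 - pr + side : r2 - pr;
      const double *krow = &kern[(size_t)dr * side];
      const int base = r2 * side;
      for (int c2 = 0; c2 < side; ++c2) {
        const int post = base + c2;
        if (exclude_self && post == pre) continue;
        const int dc = c2 - pc < 0 ? c2 - pc + side : c2 - pc;
        if (unif_rand() < krow[dc]) targets.push_back(post);
      }
    }
    row_ptr[pre + 1] = (int)targets.size();
  }
  return List::create(_["row_ptr"] = row_ptr,
                      _["targets"] = IntegerVector(targets.begin(), targets.end()));
}

struct Csr {
  const int *row_ptr;
  const int *targets;
};

static Csr as_csr(const List &adj) {
  Csr c;
  c.row_ptr = INTEGER(as<IntegerVector>(adj["row_ptr"]));
  c.targets = INTEGER(as<IntegerVector>(adj["targets"]));
  return c;
}

// Full-network simulation.
//
// tau / delay_steps / w are ordered [ee, ei, ie, ii, ex, ix]; recurrent
// weights w[0..3] are peak conductances in nS.  External stimulus events
// (stim_*) arrive on channel 2 at the given step with the given peak
// conductance; the R layer folds the external synaptic delay into the step.
// Background drive is homogeneous-Poisson per neuron; it is sampled as a
// population-total Poisson count scattered uniformly, which is exactly
// equivalent in distribution to independent per-neuron sampling.
// [[Rcpp::export]]
List cpp_simulate(int n_steps, double dt,
                  double Cm, double gL, double EL, double Vth, int tref_steps,
                  int NE, int NI,
                  List adj_ee, List adj_ei, List adj_ie, List adj_ii,
                  NumericVector tau, IntegerVector delay_steps,
                  NumericVector w, double w_bg_ex, double w_bg_ix,
                  double Eexc, double Einh,
                  NumericVector bg_rate_ex, NumericVector bg_rate_ix,
                  IntegerVector stim_step, IntegerVector stim_id,
                  NumericVector stim_amt,
                  int record_id, bool record_traces) {
  const int N = NE + NI;
  Csr ee = as_csr(adj_ee), ei = as_csr(adj_ei), ie = as_csr(adj_ie),
      ii = as_csr(adj_ii);

  std::vector<double> V((size_t)N, EL);
  std::vector<int> refrac((size_t)N, 0);
  std::vector<double> g0((size_t)N, 0.0), g1((size_t)N, 0.0),
      g2((size_t)N, 0.0), g3((size_t)N, 0.0);
  std::vector<double> x0((size_t)N, 0.0), x1((size_t)N, 0.0),
      x2((size_t)N, 0.0), x3((size_t)N, 0.0);

  // per-population filter constants; channel tau by (population, channel)
  // E neurons: ch0 <- ee, ch1 <- ie; I neurons: ch0 <- ei, ch1 <- ii
  double tauE[4] = {tau[0], tau[2], tau[4], tau[5]};
  double tauI[4] = {tau[1], tau[3], tau[4], tau[5]};
  double decE[4], dtauE[4], decI[4], dtauI[4];
  for (int c = 0; c < 4; ++c) {
    decE[c] = std::exp(-dt / tauE[c]);
    dtauE[c] = dt / tauE[c];
    decI[c] = std::exp(-dt / tauI[c]);
    dtauI[c] = dt / tauI[c];
  }

  const double wee = w[0] * E_CONST, wei = w[1] * E_CONST,
               wie = w[2] * E_CONST, wii = w[3] * E_CONST;
  const double wbex = w_bg_ex * E_CONST, wbix = w_bg_ix * E_CONST;

  // spike rings per recurrent class, holding presynaptic local indices
  const int Lee = delay_steps[0] + 1, Lei = delay_steps[1] + 1,
            Lie = delay_steps[2] + 1, Lii = delay_steps[3] + 1;
  std::vector<std::vector<int> > ring_ee(Lee), ring_ei(Lei), ring_ie(Lie),
      ring_ii(Lii);

  std::vector<int> sp_id, sp_step;
  sp_id.reserve(1 << 16);
  sp_step.reserve(1 << 16);

  NumericVector V_rec(record_traces ? n_steps : 0),
      ge_rec(record_traces ? n_steps : 0),
      gi_rec(record_traces ? n_steps : 0);

  const double lamE_ex = NE * bg_rate_ex[0] * dt * 1e-3;
  const double lamI_ex = NI * bg_rate_ex[1] * dt * 1e-3;
  const double lamE_ix = NE * bg_rate_ix[0] * dt * 1e-3;
  const double lamI_ix = NI * bg_rate_ix[1] * dt * 1e-3;

  R_xlen_t ev = 0;
  const R_xlen_t n_ev = stim_step.size();

  for (int s = 0; s < n_steps; ++s) {
    // 1. deliver recurrent spikes due this step
    {
      std::vector<int> &q = ring_ee[s % Lee];
      for (size_t k = 0; k < q.size(); ++k) {
        const int pre = q[k];
        for (int j = ee.row_ptr[pre]; j < ee.row_ptr[pre + 1]; ++j)
          x0[ee.targets[j]] += wee;
      }
      q.clear();
    }
    {
      std::vector<int> &q = ring_ei[s % Lei];
      for (size_t k = 0; k < q.size(); ++k) {
        const int pre = q[k];
        for (int j = ei.row_ptr[pre]; j < ei.row_ptr[pre + 1]; ++j)
          x0[NE + ei.targets[j]] += wei;
      }
      q.clear();
    }
    {
      std::vector<int> &q = ring_ie[s % Lie];
      for (size_t k = 0; k < q.size(); ++k) {
        const int pre = q[k];
        for (int j = ie.row_ptr[pre]; j < ie.row_ptr[pre + 1]; ++j)
          x1[ie.targets[j]] += wie;
      }
      q.clear();
    }
    {
      std::vector<int> &q = ring_ii[s % Lii];
      for (size_t k = 0; k < q.size(); ++k) {
        const int pre = q[k];
        for (int j = ii.row_ptr[pre]; j < ii.row_ptr[pre + 1]; ++j)
          x1[NE + ii.targets[j]] += wii;
      }
      q.clear();
    }

    // 2. external stimulus events (sorted by step)
    while (ev < n_ev && stim_step[ev] == s) {
      x2[stim_id[ev]] += stim_amt[ev] * E_CONST;
      ++ev;
    }

    // 3. background Poisson drive
    if (lamE_ex > 0) {
      int n = (int)R::rpois(lamE_ex);
      for (int k = 0; k < n; ++k) {
        int i = (int)(unif_rand() * NE);
        if (i >= NE) i = NE - 1;
        x2[i] += wbex;
      }
    }
    if (lamI_ex > 0) {
      int n = (int)R::rpois(lamI_ex);
      for (int k = 0; k < n; ++k) {
        int i = (int)(unif_rand() * NI);
        if (i >= NI) i = NI - 1;
        x2[NE + i] += wbex;
      }
    }
    if (lamE_ix > 0) {
      int n = (int)R::rpois(lamE_ix);
      for (int k = 0; k < n; ++k) {
        int i = (int)(unif_rand() * NE);
        if (i >= NE) i = NE - 1;
        x3[i] += wbix;
      }
    }
    if (lamI_ix > 0) {
      int n = (int)R::rpois(lamI_ix);
      for (int k = 0; k < n; ++k) {
        int i = (int)(unif_rand() * NI);
        if (i >= NI) i = NI - 1;
        x3[NE + i] += wbix;
      }
    }

    // 4. advance states: exact filter update, Heun step for V
    for (int pop = 0; pop < 2; ++pop) {
      const int lo = pop == 0 ? 0 : NE;
      const int hi = pop == 0 ? NE : N;
      const double *dec = pop == 0 ? decE : decI;
      const double *dta = pop == 0 ? dtauE : dtauI;
      for (int i = lo; i < hi; ++i) {
        const double ge_old = g0[i] + g2[i];
        const double gi_old = g1[i] + g3[i];
        g0[i] = dec[0] * (g0[i] + dta[0] * x0[i]);
        x0[i] *= dec[0];
        g1[i] = dec[1] * (g1[i] + dta[1] * x1[i]);
        x1[i] *= dec[1];
        g2[i] = dec[2] * (g2[i] + dta[2] * x2[i]);
        x2[i] *= dec[2];
        g3[i] = dec[3] * (g3[i] + dta[3] * x3[i]);
        x3[i] *= dec[3];
        if (refrac[i] > 0) {
          --refrac[i];
          V[i] = EL;
          continue;
        }
        const double ge_new = g0[i] + g2[i];
        const double gi_new = g1[i] + g3[i];
        double v = V[i];
        const double k1 =
            (-gL * (v - EL) + ge_old * (Eexc - v) + gi_old * (Einh - v)) / Cm;
        const double v1 = v + dt * k1;
        const double k2 =
            (-gL * (v1 - EL) + ge_new * (Eexc - v1) + gi_new * (Einh - v1)) /
            Cm;
        v += 0.5 * dt * (k1 + k2);
        if (v >= Vth) {
          sp_id.push_back(i);
          sp_step.push_back(s + 1);
          v = EL;
          refrac[i] = tref_steps;
          if (i < NE) {
            ring_ee[(s + delay_steps[0]) % Lee].push_back(i);
            ring_ei[(s + delay_steps[1]) % Lei].push_back(i);
          } else {
            ring_ie[(s + delay_steps[2]) % Lie].push_back(i - NE);
            ring_ii[(s + delay_steps[3]) % Lii].push_back(i - NE);
          }
        }
        V[i] = v;
      }
    }
    if (!std::isfinite(V[0]))
      stop("non-finite membrane potential at step %d", s);

    if (record_traces) {
      V_rec[s] = V[record_id];
      ge_rec[s] = g0[record_id] + g2[record_id];
      gi_rec[s] = g1[record_id] + g3[record_id];
    }
  }

  return List::create(
      _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
      _["spike_step"] = IntegerVector(sp_step.begin(), sp_step.end()),
      _["V"] = V_rec, _["ge"] = ge_rec, _["gi"] = gi_rec);
}

// Single isolated neuron driven by a list of external events on one
// alpha-conductance channel.  No threshold/reset: this is the subthreshold
// probe used for PSP-amplitude weight calibration and integrator checks.
// [[Rcpp::export]]
List cpp_single_trace(int n_steps, double dt, double Cm, double gL, double EL,
                      double V0, IntegerVector ev_step, NumericVector ev_amt,
                      double tau, double Erev) {
  const double dec = std::exp(-dt / tau), dta = dt / tau;
  double g = 0.0, x = 0.0, v = V0;
  NumericVector V(n_steps), G(n_steps);
  R_xlen_t ev = 0;
  const R_xlen_t n_ev = ev_step.size();
  for (int s = 0; s < n_steps; ++s) {
    while (ev < n_ev && ev_step[ev] == s) {
      x += ev_amt[ev] * E_CONST;
      ++ev;
    }
    const double g_old = g;
    g = dec * (g + dta * x);
    x *= dec;
    const double k1 = (-gL * (v - EL) + g_old * (Erev - v)) / Cm;
    const double v1 = v + dt * k1;
    const double k2 = (-gL * (v1 - EL) + g * (Erev - v1)) / Cm;
    v += 0.5 * dt * (k1 + k2);
    V[s] = v;
    G[s] = g;
  }
  return List::create(_["V"] = V, _["g"] = G);
}
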