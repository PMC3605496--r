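#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Time-stepped leaky integrate-and-fire network core.
//
// Conventions shared with the R layer:
//  * step t (0-based) covers (t*dt, (t+1)*dt]; a spike emitted in step t is
//    stamped at the step end, time (t+1)*dt.
//  * within a step: leak decay first, then all excitatory jumps, then all
//    inhibitory jumps; threshold is tested once after all jumps.
//  * n same-type conductance jumps compose exactly:
//    V <- V_X + (V - V_X) * (1 - g_X)^n.
//  * a neuron that spikes in step t holds V = V_R and discards all input for
//    the following ref_steps steps.
//  * a synapse with delay d (steps, >= 1) from a spike in step t delivers
//    input that participates in step t + d.
//
// Background input is a per-step Poisson count drawn from R's RNG, so runs
// are bit-reproducible for a fixed seed. External (stimulus) events arrive as
// precomputed (step, neuron, kind) triples, sorted by step.

// [[Rcpp::export]]
List engine_run(int n_neurons,
                IntegerVector syn_ptr,     // length n_neurons + 1, 0-based CSR
                IntegerVector syn_post,    // 0-based target ids
                IntegerVector syn_delay,   // delay in steps, >= 1
                IntegerVector syn_inh,     // 1 if inhibitory synapse
                int n_steps, double dt,
                NumericVector mu_exc,      // per-step Poisson mean (counts)
                NumericVector mu_inh,
                IntegerVector ext_step,    // sorted ascending, 0-based
                IntegerVector ext_neuron,  // 0-based
                IntegerVector ext_inh,
                List par,
                bool record_v, int record_neuron) {
  const int kind = as<int>(par["kind"]); // 0 conductance, 1 current
  const double V_P = as<double>(par["V_P"]);
  const double V_E = as<double>(par["V_E"]);
  const double V_I = as<double>(par["V_I"]);
  const double V_R = as<double>(par["V_R"]);
  const double V_Theta = as<double>(par["V_Theta"]);
  const double tau_P = as<double>(par["tau_P"]);
  const double g_E = as<double>(par["g_E"]);
  const double g_I = as<double>(par["g_I"]);
  const double a_E = as<double>(par["a_E"]);
  const double a_I = as<double>(par["a_I"]);
  const int ref_steps = as<int>(par["ref_steps"]);

  // (1-g)^k via std::pow so the composition is bit-identical to the pure-R
  // reference integrator (R's ^ also calls pow)
  const double decay = std::exp(-dt / tau_P);

  int max_d = 1;
  for (int s = 0; s < syn_delay.size(); ++s)
    if (syn_delay[s] > max_d) max_d = syn_delay[s];
  const int depth = max_d + 1;

  std::vector<int> bufE((size_t)depth * n_neurons, 0);
  std::vector<int> bufI((size_t)depth * n_neurons, 0);
  std::vector<double> V(n_neurons, V_P);
  std::vector<int> refr(n_neurons, 0);

  std::vector<int> sp_neuron, sp_step;
  sp_neuron.reserve(1024);
  sp_step.reserve(1024);
  NumericVector vtrace(record_v ? n_steps : 0);

  double n_deliveries = 0.0;
  const int n_ext = ext_step.size();
  int ep = 0;

  RNGScope scope;

  for (int t = 0; t < n_steps; ++t) {
    const int row = t % depth;
    int *rowE = bufE.data() + (size_t)row * n_neurons;
    int *rowI = bufI.data() + (size_t)row * n_neurons;

    // pour external events arriving this step
    while (ep < n_ext && ext_step[ep] == t) {
      if (ext_inh[ep]) rowI[ext_neuron[ep]]++; else rowE[ext_neuron[ep]]++;
      ++ep;
    }

    const double muE = mu_exc[t], muI = mu_inh[t];

    for (int i = 0; i < n_neurons; ++i) {
      int kE = rowE[i], kI = rowI[i];
      if (muE > 0) kE += (int)R::rpois(muE);
      if (muI > 0) kI += (int)R::rpois(muI);

      if (refr[i] > 0) { // refractory: clamp at V_R, discard input
        refr[i]--;
        continue;
      }

      double v = V_P + (V[i] - V_P) * decay;
      if (kind == 0) {
        // mirrors R's `^` exactly, including its y == 2 special case
        if (kE > 0) {
          double f = (kE == 2) ? (1.0 - g_E) * (1.0 - g_E)
                               : std::pow(1.0 - g_E, (double)kE);
          v = V_E + (v - V_E) * f;
        }
        if (kI > 0) {
          double f = (kI == 2) ? (1.0 - g_I) * (1.0 - g_I)
                               : std::pow(1.0 - g_I, (double)kI);
          v = V_I + (v - V_I) * f;
        }
      } else {
        v += kE * a_E + kI * a_I;
      }

      if (v >= V_Theta) {
        sp_neuron.push_back(i);
        sp_step.push_back(t);
        v = V_R;
        refr[i] = ref_steps;
        const int s0 = syn_ptr[i], s1 = syn_ptr[i + 1];
        for (int s = s0; s < s1; ++s) {
          const int slot = (t + syn_delay[s]) % depth;
          int *buf = syn_inh[s] ? bufI.data() : bufE.data();
          buf[(size_t)slot * n_neurons + syn_post[s]]++;
        }
        n_deliveries += (double)(s1 - s0);
      }
      V[i] = v;
    }

    std::memset(rowE, 0, sizeof(int) * n_neurons);
    std::memset(rowI, 0, sizeof(int) * n_neurons);

    if (record_v) vtrace[t] = V[record_neuron];
  }

  return List::create(
    _["neuron"] = IntegerVector(sp_neuron.begin(), sp_neuron.end()),
    _["step"] = IntegerVector(sp_step.begin(), sp_step.end()),
    _["v_trace"] = vtrace,
    _["n_deliveries"] = n_deliveries);
}
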