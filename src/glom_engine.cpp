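#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step engine for the glomerular-layer network.
//
// Every stimulus column is an independent exposure: fresh initial
// conditions (v = v_r, u = 0, synaptic currents 0) and no coupling
// across columns.  Within a column, each step is one classical RK4
// step of the two-variable quadratic neuron model with the per-neuron
// input current (external + synaptic) held constant over the step,
// followed by the after-spike reset (v >= v_peak -> v = c, u += d).
// All synapses share one decay constant, so the synaptic state is a
// single aggregated exponentially decaying current per neuron,
// multiplied by exp(-dt/tau) each step and incremented by the
// weights of the neurons that spiked (W[post, pre], in ascending
// presynaptic order, which keeps a lattice of zero weights exactly
// neutral).

// [[Rcpp::export]]
List simulate_network_core(NumericVector Cm, NumericVector k,
                           NumericVector vr, NumericVector vt,
                           NumericVector a, NumericVector b,
                           NumericVector vpeak, NumericVector creset,
                           NumericVector d, NumericMatrix W,
                           NumericMatrix Iext, double dt, int n_steps,
                           double decay, bool record) {
  const int n = Iext.nrow();
  const int ns = Iext.ncol();
  IntegerMatrix counts(n, ns);
  std::vector<double> sp_time;
  std::vector<int> sp_neuron, sp_stim;
  std::vector<double> v(n), u(n), Isyn(n), vnew(n), unew(n);
  std::vector<int> spikers;
  spikers.reserve(n);
  const double *w = W.begin();

  for (int col = 0; col < ns; ++col) {
    for (int i = 0; i < n; ++i) {
      v[i] = vr[i];
      u[i] = 0.0;
      Isyn[i] = 0.0;
    }
    const double *Ix = &Iext(0, col);
    for (int step = 1; step <= n_steps; ++step) {
      spikers.clear();
      for (int i = 0; i < n; ++i) {
        const double I = Ix[i] + Isyn[i];
        const double ci = Cm[i], ki = k[i], vri = vr[i], vti = vt[i];
        const double ai = a[i], bi = b[i];
        const double h = dt / 2.0;
        const double v0 = v[i], u0 = u[i];
        double k1v = (ki * (v0 - vri) * (v0 - vti) - u0 + I) / ci;
        double k1u = ai * (bi * (v0 - vri) - u0);
        double v2 = v0 + h * k1v, u2 = u0 + h * k1u;
        double k2v = (ki * (v2 - vri) * (v2 - vti) - u2 + I) / ci;
        double k2u = ai * (bi * (v2 - vri) - u2);
        double v3 = v0 + h * k2v, u3 = u0 + h * k2u;
        double k3v = (ki * (v3 - vri) * (v3 - vti) - u3 + I) / ci;
        double k3u = ai * (bi * (v3 - vri) - u3);
        double v4 = v0 + dt * k3v, u4 = u0 + dt * k3u;
        double k4v = (ki * (v4 - vri) * (v4 - vti) - u4 + I) / ci;
        double k4u = ai * (bi * (v4 - vri) - u4);
        double vn = v0 + dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
        double un = u0 + dt / 6.0 * (k1u + 2.0 * k2u + 2.0 * k3u + k4u);
        if (!R_finite(vn) || !R_finite(un)) {
          stop("NaN emerged at integration step %d (stimulus %d)", step,
               col + 1);
        }
        if (vn >= vpeak[i]) {
          vn = creset[i];
          un += d[i];
          spikers.push_back(i);
          counts(i, col) += 1;
          if (record) {
            sp_time.push_back(step * dt);
            sp_neuron.push_back(i + 1);
            sp_stim.push_back(col + 1);
          }
        }
        vnew[i] = vn;
        unew[i] = un;
      }
      for (int i = 0; i < n; ++i) {
        v[i] = vnew[i];
        u[i] = unew[i];
        Isyn[i] *= decay;
      }
      for (size_t sj = 0; sj < spikers.size(); ++sj) {
        const double *wcol = w + (size_t)spikers[sj] * n;
        for (int i = 0; i < n; ++i) Isyn[i] += wcol[i];
      }
    }
  }
  return List::create(
    _["counts"] = counts,
    _["spike_time"] = NumericVector(sp_time.begin(), sp_time.end()),
    _["spike_neuron"] = IntegerVector(sp_neuron.begin(), sp_neuron.end()),
    _["spike_stimulus"] = IntegerVector(sp_stim.begin(), sp_stim.end())
  );
}
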