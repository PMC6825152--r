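#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step integrator for a single-compartment conductance-based membrane.
//
// Gates use the Rush-Larsen analytic exponential update against
// voltage-tabulated steady states and per-step decay factors
// exp(-dt / tau(V)); the voltage uses an exponential (semi-implicit) update
// against the instantaneous total conductance. Units: V in mV, time in ms,
// conductances in mS/cm^2, capacitance in uF/cm^2, injected current already
// converted to uA/cm^2. Tables are sampled on a uniform voltage grid and
// linearly interpolated; V is clamped to the grid for lookups.
//
// channels: list of lists with elements
//   gbar   : double, mS/cm^2
//   e      : double, reversal, mV
//   powers : numeric vector, one exponent per gate
//   xinf   : matrix [n_grid x n_gates], steady state per grid voltage
//   efac   : matrix [n_grid x n_gates], exp(-dt/tau) per grid voltage
//   x0     : numeric vector, initial gate values

// [[Rcpp::export]]
List hh_run_cpp(double v0, double dt, int n_steps, NumericVector i_density,
                double cm, double g_leak, double e_leak, List channels,
                double grid_min, double grid_step, int record_every) {
  int n_chan = channels.size();
  std::vector<double> gbar(n_chan), erev(n_chan);
  std::vector<std::vector<double>> powers(n_chan);
  std::vector<NumericMatrix> xinf(n_chan), efac(n_chan);
  std::vector<std::vector<double>> x(n_chan);
  int n_grid = 0;
  for (int c = 0; c < n_chan; ++c) {
    List ch = channels[c];
    gbar[c] = as<double>(ch["gbar"]);
    erev[c] = as<double>(ch["e"]);
    NumericVector pw = ch["powers"];
    powers[c] = std::vector<double>(pw.begin(), pw.end());
    xinf[c] = as<NumericMatrix>(ch["xinf"]);
    efac[c] = as<NumericMatrix>(ch["efac"]);
    NumericVector x0 = ch["x0"];
    x[c] = std::vector<double>(x0.begin(), x0.end());
    n_grid = xinf[c].nrow();
  }
  double grid_max = grid_min + (n_grid - 1) * grid_step;

  int n_rec = n_steps / record_every + 1;
  NumericVector v_out(n_rec);
  double v = v0;
  v_out[0] = v;
  int i_rec = 1;
  bool stim_scalar = (i_density.size() == 1);

  for (int s = 0; s < n_steps; ++s) {
    // table lookup position for the current voltage
    double vc = v;
    if (vc < grid_min) vc = grid_min;
    if (vc > grid_max) vc = grid_max;
    double pos = (vc - grid_min) / grid_step;
    int i0 = (int)pos;
    if (i0 >= n_grid - 1) i0 = n_grid - 2;
    double fr = pos - i0;

    double gsum = g_leak, gesum = g_leak * e_leak;
    for (int c = 0; c < n_chan; ++c) {
      int ng = powers[c].size();
      double open = 1.0;
      for (int g = 0; g < ng; ++g) {
        double xi = xinf[c](i0, g) + fr * (xinf[c](i0 + 1, g) - xinf[c](i0, g));
        double ef = efac[c](i0, g) + fr * (efac[c](i0 + 1, g) - efac[c](i0, g));
        double xn = xi + (x[c][g] - xi) * ef;  // Rush-Larsen update
        x[c][g] = xn;
        double p = powers[c][g];
        if (p == 1.0) open *= xn;
        else if (p == 2.0) open *= xn * xn;
        else if (p == 3.0) open *= xn * xn * xn;
        else if (p == 4.0) { double x2 = xn * xn; open *= x2 * x2; }
        else open *= std::pow(xn, p);
      }
      double g_now = gbar[c] * open;
      gsum += g_now;
      gesum += g_now * erev[c];
    }
    double i_inj = stim_scalar ? i_density[0] : i_density[s];
    double a = gsum / cm;                     // 1/ms
    double b = (gesum + i_inj) / cm;          // mV/ms
    double vinf = b / a;
    v = vinf + (v - vinf) * std::exp(-a * dt);

    if (!std::isfinite(v) || std::fabs(v) > 200.0) {
      return List::create(_["ok"] = false, _["step"] = s + 1,
                          _["v"] = v_out, _["v_last"] = v);
    }
    if ((s + 1) % record_every == 0 && i_rec < n_rec) v_out[i_rec++] = v;
  }
  // final gate state, for settle continuation
  List xs(n_chan);
  for (int c = 0; c < n_chan; ++c) xs[c] = NumericVector(x[c].begin(), x[c].end());
  return List::create(_["ok"] = true, _["v"] = v_out, _["v_last"] = v,
                      _["gates"] = xs);
}
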