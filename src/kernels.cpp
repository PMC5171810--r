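#include <Rcpp.h>
using namespace Rcpp;

// Subthreshold integration uses the exact exponential update for the linear
// part, treating the input as constant over one sample step (exponential
// Euler). All times are in ms; returned spike times are in ms.

// Threshold-based (level-crossing) neuron: V is the low-pass filtered input,
// a spike is emitted at every upward crossing of v_th, no reset. The crossing
// instant is linearly interpolated between samples.
// [[Rcpp::export]]
NumericVector sim_tb_cpp(NumericVector x, double dt, double tau_mem,
                         double v_th) {
  int n = x.size();
  double a = std::exp(-dt / tau_mem), b = 1.0 - a;
  double v = 0.0;
  std::vector<double> sp;
  for (int k = 0; k < n; ++k) {
    double v_new = a * v + b * x[k];
    if (v < v_th && v_new >= v_th) {
      double frac = (v_th - v) / (v_new - v);
      sp.push_back((k + frac) * dt);
    }
    v = v_new;
  }
  return wrap(sp);
}

// Leaky integrate-and-fire: threshold-and-reset on top of the same leaky
// integration. Spike time recorded at the sample of threshold passage.
// [[Rcpp::export]]
NumericVector sim_lif_cpp(NumericVector x, double dt, double tau_mem,
                          double v_th, double v_reset) {
  int n = x.size();
  double a = std::exp(-dt / tau_mem), b = 1.0 - a;
  double v = 0.0;
  std::vector<double> sp;
  for (int k = 0; k < n; ++k) {
    v = a * v + b * x[k];
    if (v >= v_th) {
      sp.push_back((k + 1) * dt);
      v = v_reset;
    }
  }
  return wrap(sp);
}

// Adaptive leaky integrate-and-fire with linear subthreshold dynamics
//   tau_mem dV/dt = -V + alpha * w + X(t)
//   tau_w  dw/dt  =  beta * V - w
// Spike-and-reset on V; the adaptation variable w is continuous through the
// spike. The exact one-step propagator of the coupled linear system (with
// the input held constant over the step) is precomputed at the R level and
// passed in as the 2x2 matrix A and input vector b, so the integration is
// exact up to the piecewise-constant input and reduces bit-for-bit to the
// leaky integrate-and-fire update when alpha = beta = 0.
// [[Rcpp::export]]
NumericVector sim_alif_cpp(NumericVector x, double dt, NumericVector A,
                           NumericVector b, double v_th, double v_reset) {
  int n = x.size();
  double v = 0.0, w = 0.0;
  std::vector<double> sp;
  for (int k = 0; k < n; ++k) {
    double vn = A[0] * v + A[2] * w + b[0] * x[k];
    double wn = A[1] * v + A[3] * w + b[1] * x[k];
    v = vn;
    w = wn;
    if (v >= v_th) {
      sp.push_back((k + 1) * dt);
      v = v_reset;
    }
  }
  return wrap(sp);
}

// Exponential integrate-and-fire:
//   tau_mem dV/dt = -V + Delta_T * exp((V - v_th)/Delta_T) + X(t)
// A spike is registered when V reaches v_th (the exponential term then equals
// Delta_T), after which V is reset; capping the voltage at v_th bounds the
// nonlinearity so the explicit step cannot diverge between samples.
// [[Rcpp::export]]
NumericVector sim_eif_cpp(NumericVector x, double dt, double tau_mem,
                          double v_th, double v_reset, double delta_t) {
  int n = x.size();
  double v = 0.0;
  std::vector<double> sp;
  for (int k = 0; k < n; ++k) {
    double dv = (-v + delta_t * std::exp((v - v_th) / delta_t) + x[k]) / tau_mem;
    v += dt * dv;
    if (v >= v_th) {
      sp.push_back((k + 1) * dt);
      v = v_reset;
    }
  }
  return wrap(sp);
}

// Filtered voltage trace of the threshold-based model (diagnostic use:
// Rice-formula oracle needs the voltage itself).
// [[Rcpp::export]]
NumericVector filter_voltage_cpp(NumericVector x, double dt, double tau_mem) {
  int n = x.size();
  double a = std::exp(-dt / tau_mem), b = 1.0 - a;
  NumericVector v(n);
  double vk = 0.0;
  for (int k = 0; k < n; ++k) {
    vk = a * vk + b * x[k];
    v[k] = vk;
  }
  return v;
}
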