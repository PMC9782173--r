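#include <Rcpp.h>
using namespace Rcpp;

// Asymmetric first-order lag, exact discrete update for a zero-order-hold
// input: y[i] = y[i-1] + (1 - exp(-dt/tau)) * (x[i] - y[i-1]); tau switches
// between the rise and fall constants on the sign of the tracking error.
// [[Rcpp::export]]
NumericVector asym_lowpass_cpp(NumericVector x, double dt,
                               double tau_rise, double tau_fall,
                               double y0) {
  int n = x.size();
  NumericVector y(n);
  if (n == 0) return y;
  double a_rise = 1.0 - std::exp(-dt / tau_rise);
  double a_fall = 1.0 - std::exp(-dt / tau_fall);
  double prev = y0;
  for (int i = 0; i < n; ++i) {
    double err = x[i] - prev;
    double a = (err >= 0.0) ? a_rise : a_fall;
    prev += a * err;
    y[i] = prev;
  }
  return y;
}

// Hysteretic static transduction with branch tracking. Loading branch is
// linear S*P; once the pressure turns downward the unloading branch
// S*P + alpha*P*(p_turn - P) is followed, with p_turn the turning-point
// pressure of the current cycle. Pressures in MPa.
// [[Rcpp::export]]
NumericVector hysteresis_transduce_cpp(NumericVector p, double S, double alpha) {
  int n = p.size();
  NumericVector r(n);
  bool unloading = false;
  double p_turn = 0.0;
  for (int i = 0; i < n; ++i) {
    double pi = p[i];
    if (i > 0) {
      double prev = p[i - 1];
      if (pi > prev) {
        unloading = false;
      } else if (pi < prev && !unloading) {
        unloading = true;
        p_turn = prev;
      }
    }
    if (unloading && pi < p_turn) {
      r[i] = S * pi + alpha * pi * (p_turn - pi);
    } else {
      r[i] = S * pi;
    }
  }
  return r;
}
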