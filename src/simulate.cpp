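#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial recursion of the two-process state-space learner.
//
// kind codes: 0 = field, 1 = clamp, 2 = null.
// Recorded states are pre-update: row i holds the state that produced
// trial i's motor output, so a naive learner starts at exactly 0.
// The post-update state after the last trial is returned separately so
// callers can build "adaptation after k trials" curves.
//
// state_noise (optional, length n) is added to the net motor output
// before the error is computed, which is how trial-to-trial variability
// enters the synthetic cohorts; pass a zero vector for the noise-free
// model. clamp_mode: 0 = error clamped to zero, states decay by their
// retention factors; 1 = clamp trials leave the states untouched.
// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(double a_fast, double b_fast, double a_slow, double b_slow,
                  NumericVector disturbance, IntegerVector kind,
                  double xf0, double xs0,
                  NumericVector state_noise,
                  int clamp_mode, double bound) {
  int n = disturbance.size();
  bool noisy = state_noise.size() == n;
  NumericVector xf(n), xs(n), xnet(n), err(n), output(n);
  double f = xf0, s = xs0;
  for (int i = 0; i < n; ++i) {
    xf[i] = f; xs[i] = s; xnet[i] = f + s;
    double y = xnet[i] + (noisy ? state_noise[i] : 0.0);
    output[i] = y;
    double e;
    if (kind[i] == 1) {              // error clamp
      e = 0.0;
      if (clamp_mode == 0) { f = a_fast * f; s = a_slow * s; }
    } else {                         // field (d) or null (d = 0)
      double d = (kind[i] == 2) ? 0.0 : disturbance[i];
      e = d - y;
      double f2 = a_fast * f + b_fast * e;
      double s2 = a_slow * s + b_slow * e;
      f = f2; s = s2;
    }
    err[i] = e;
    if (fabs(f + s) > bound)
      stop("trajectory diverged at trial %d (|x_net| > %g)", i + 1, bound);
  }
  return List::create(_["x_fast"] = xf, _["x_slow"] = xs,
                      _["x_net"] = xnet, _["error"] = err,
                      _["output"] = output,
                      _["x_fast_end"] = f, _["x_slow_end"] = s);
}
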