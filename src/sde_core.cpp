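#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double logaddexp(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log1p(std::exp(-std::fabs(a - b)));
}

// [[Rcpp::export]]
NumericVector em_path_cpp(double alpha, double beta, double noise_amp,
                          double p_init, double dt, int n_steps,
                          Nullable<NumericVector> dW_ = R_NilValue,
                          int thin = 1) {
  bool given = dW_.isNotNull();
  NumericVector dW;
  if (given) {
    dW = NumericVector(dW_);
    if (dW.size() < n_steps) stop("dW has fewer increments than steps");
  }
  int n_out = n_steps / thin + 1;
  NumericVector out(n_out);
  out[0] = p_init;
  double p = p_init, sdt = std::sqrt(dt);
  int j = 1;
  for (int k = 0; k < n_steps; ++k) {
    double dw = given ? dW[k] : norm_rand() * sdt;
    p = p + (alpha * p - beta * p * p) * dt + noise_amp * p * dw;
    if (p <= 0.0) {
      stop("positivity breach in Euler-Maruyama scheme at step %d (p = %g)",
           k + 1, p);
    }
    if ((k + 1) % thin == 0 && j < n_out) out[j++] = p;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector log_euler_path_cpp(double alpha, double beta, double noise_amp,
                                 double p_init, double dt, int n_steps,
                                 Nullable<NumericVector> dW_ = R_NilValue,
                                 int thin = 1) {
  bool given = dW_.isNotNull();
  NumericVector dW;
  if (given) {
    dW = NumericVector(dW_);
    if (dW.size() < n_steps) stop("dW has fewer increments than steps");
  }
  int n_out = n_steps / thin + 1;
  NumericVector out(n_out);
  out[0] = p_init;
  double y = std::log(p_init), sdt = std::sqrt(dt);
  double na2h = 0.5 * noise_amp * noise_amp;
  int j = 1;
  for (int k = 0; k < n_steps; ++k) {
    double dw = given ? dW[k] : norm_rand() * sdt;
    y += (alpha - beta * std::exp(y) - na2h) * dt + noise_amp * dw;
    if ((k + 1) % thin == 0 && j < n_out) out[j++] = std::exp(y);
  }
  return out;
}

// Closed-form path solution p(t) = N(t) / D(t) with
//   N(t) = exp(g(t)),  g(t) = (alpha - noise_amp^2/2) t + noise_amp W(t)
//   D(t) = 1/p_init + beta * int_0^t exp(g(s)) ds
// The integral is computed per interval assuming g linear on the interval
// (exponential trapezoid: exact for exp(linear)), entirely in log space.
// [[Rcpp::export]]
NumericVector exact_path_cpp(double alpha, double beta, double noise_amp,
                             double p_init, NumericVector t, NumericVector W) {
  int n = t.size();
  if (W.size() != n) stop("time grid and Brownian path have different lengths");
  NumericVector p(n);
  p[0] = p_init;
  double mu = alpha - 0.5 * noise_amp * noise_amp;
  double log_int = R_NegInf;           // log of int_0^t exp(g) ds
  double neg_log_p0 = -std::log(p_init);
  double g_prev = 0.0;                 // g(0) = 0
  for (int k = 1; k < n; ++k) {
    double dtk = t[k] - t[k - 1];
    if (dtk <= 0) stop("time grid must be strictly increasing");
    double g = mu * t[k] + noise_amp * W[k];
    double d = g - g_prev;
    // log of int over the interval: dt * exp((g+g_prev)/2) * 2 sinh(d/2)/d
    double log_piece;
    double ad = std::fabs(d);
    if (ad < 1e-5) {
      log_piece = std::log(dtk) + 0.5 * (g + g_prev) + std::log1p(ad * ad / 24.0);
    } else {
      // 2 sinh(d/2)/d = (1 - exp(-|d|)) * exp(|d|/2) / |d|
      log_piece = std::log(dtk) + 0.5 * (g + g_prev)
                  + 0.5 * ad + std::log1p(-std::exp(-ad)) - std::log(ad);
    }
    log_int = logaddexp(log_int, log_piece);
    double log_D = logaddexp(neg_log_p0, std::log(beta) + log_int);
    p[k] = std::exp(g - log_D);
    g_prev = g;
  }
  return p;
}

// Two-barrier first-passage Monte Carlo with the positivity-preserving
// log-Euler scheme. Returns counts of paths hitting b first, a first, and
// censored at the horizon.
// [[Rcpp::export]]
IntegerVector mc_first_passage_cpp(double alpha, double beta, double noise_amp,
                                   double x, double a, double b,
                                   int n_paths, double dt, double t_max) {
  int n_steps = (int)std::ceil(t_max / dt);
  double sdt = std::sqrt(dt);
  double na2h = 0.5 * noise_amp * noise_amp;
  double log_a = std::log(a), log_b = std::log(b), y0 = std::log(x);
  int hit_b = 0, hit_a = 0, censored = 0;
  for (int i = 0; i < n_paths; ++i) {
    double y = y0;
    bool done = false;
    for (int k = 0; k < n_steps; ++k) {
      y += (alpha - beta * std::exp(y) - na2h) * dt + noise_amp * norm_rand() * sdt;
      if (y >= log_b) { ++hit_b; done = true; break; }
      if (y <= log_a) { ++hit_a; done = true; break; }
    }
    if (!done) ++censored;
  }
  return IntegerVector::create(hit_b, hit_a, censored);
}
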