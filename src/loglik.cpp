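// Compiled inner loop for the racing-diffusion likelihoods.
// drace() in R/likelihood.R is the reference implementation; the two
// are held equal by tests.
#include <Rcpp.h>
using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.9189385332046727;

// log Wald first-passage density at tau > 0
static inline double wald_logpdf(double tau, double rho, double sigma,
                                 double alpha) {
  double d = alpha - rho * tau;
  return std::log(alpha) - LOG_SQRT_2PI - std::log(sigma) -
         1.5 * std::log(tau) - d * d / (2.0 * sigma * sigma * tau);
}

// Wald first-passage CDF at tau > 0; second term in log space
static inline double wald_cdf(double tau, double rho, double sigma,
                              double alpha) {
  double sq = sigma * std::sqrt(tau);
  double t1 = R::pnorm((rho * tau - alpha) / sq, 0.0, 1.0, 1, 0);
  double t2 = std::exp(2.0 * alpha * rho / (sigma * sigma) +
                       R::pnorm(-(rho * tau + alpha) / sq, 0.0, 1.0, 1, 1));
  double f = t1 + t2;
  return f > 1.0 ? 1.0 : f;
}

// [[Rcpp::export]]
double race_loglik_cpp(NumericVector rt, LogicalVector is_left,
                       NumericVector s_l, NumericVector s_r,
                       NumericVector par, bool trdm,
                       bool printed_variance, bool shared_timer_t0) {
  const double omega = par[0], t0 = par[1], v0 = par[2], vd = par[3],
               vs = par[4], eta_c = par[5];
  const double rho_t = trdm ? par[6] : 0.0;
  const double eta_t = trdm ? par[7] : 1.0;
  const double gamma = trdm ? par[8] : 0.0;
  const double al = 2.0 * omega, ar = 2.0 * (1.0 - omega);
  const int n = rt.size();
  const double floor_d = 1e-300;
  double ll = 0.0;

  for (int i = 0; i < n; ++i) {
    double tau = rt[i] - t0;
    double dens = 0.0;
    if (tau > 0.0) {
      double diff = s_l[i] - s_r[i], sum = s_l[i] + s_r[i];
      double rl = v0 + vd * diff + vs * sum;
      double rr = v0 - vd * diff + vs * sum;
      bool left = is_left[i];
      double f_win = left ? std::exp(wald_logpdf(tau, rl, eta_c, al))
                          : std::exp(wald_logpdf(tau, rr, eta_c, ar));
      double S_lose = left ? 1.0 - wald_cdf(tau, rr, eta_c, ar)
                           : 1.0 - wald_cdf(tau, rl, eta_c, al);
      if (!trdm) {
        dens = f_win * S_lose;
      } else {
        double tau_T = shared_timer_t0 ? tau : rt[i];
        double F_T = wald_cdf(tau_T, rho_t, eta_t, 1.0);
        double f_T = std::exp(wald_logpdf(tau_T, rho_t, eta_t, 1.0));
        double z = printed_variance
                       ? (rl - rr) / (M_SQRT2 * eta_c)
                       : (rl - rr) * std::sqrt(tau) / (M_SQRT2 * eta_c);
        double p_left = gamma * R::pnorm(z, 0.0, 1.0, 1, 0) +
                        0.5 * (1.0 - gamma);
        double P_T = left ? p_left : 1.0 - p_left;
        double S_l = 1.0 - wald_cdf(tau, rl, eta_c, al);
        double S_r = 1.0 - wald_cdf(tau, rr, eta_c, ar);
        dens = f_win * S_lose * (1.0 - F_T) + P_T * f_T * S_l * S_r;
      }
    }
    if (!(dens > floor_d)) dens = floor_d;
    ll += std::log(dens);
  }
  return ll;
}
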