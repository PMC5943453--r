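#include <Rcpp.h>
using namespace Rcpp;

static inline double inv_logit(double x) {
  if (x > 30.0) x = 30.0;
  if (x < -30.0) x = -30.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Transient-CJS log-likelihood, summed per station.
//
// y:       n x T detection matrix (0/1), conditioned on first capture
// first:   1-based occasion of first capture
// last:    1-based occasion of last detection
// pred:    1 if the individual was pre-determined a resident (within-season
//          repeat capture), else 0
// sex:     0 = female, 1 = male
// station: 1-based station index per individual
// region:  1-based region index per station
// hf:      standardized footprint per station
// tc:      centered year covariate per occasion (length T); survival over
//          the interval t -> t+1 is evaluated at tc[t]
//
// Mixture per individual i with first capture f, last detection l:
//   resident CJS term  L = prod_{t=f}^{l-1} phi_t * pr^{y_{t+1}}
//                          * (1-pr)^{1-y_{t+1}}  *  chi_l
//   chi_T = 1,  chi_t = (1-phi_t) + phi_t (1-pr) chi_{t+1}
//   pred = 1:  pi * rho * L
//   pred = 0:  pi * (1-rho) * L + (1-pi) * I[l == f]
// [[Rcpp::export]]
NumericVector cjs_loglik_by_station(IntegerMatrix y,
                                    IntegerVector first,
                                    IntegerVector last,
                                    IntegerVector pred,
                                    NumericVector sex,
                                    IntegerVector station,
                                    IntegerVector region,
                                    NumericVector hf,
                                    NumericVector tc,
                                    double mu_phi,
                                    NumericVector bphi_region,
                                    double bphi_sex,
                                    double bphi_hf,
                                    NumericVector bphi_trend,
                                    double alpha_pi,
                                    NumericVector bpi_region,
                                    double bpi_sex,
                                    double bpi_hf,
                                    double pr_int,
                                    double pr_sex,
                                    double rho_int,
                                    double rho_sex,
                                    NumericVector omega_phi,
                                    NumericVector omega_pi,
                                    NumericVector omega_pr,
                                    NumericVector omega_rho,
                                    int n_station) {
  const int n = y.nrow(), T = y.ncol();
  NumericVector ll(n_station);
  std::vector<double> phi(T > 1 ? T - 1 : 1);
  for (int i = 0; i < n; ++i) {
    const int s = station[i] - 1;
    const int k = region[s] - 1;
    const double sx = sex[i];
    const double h = hf[s];
    const double phi_base = mu_phi + bphi_region[k] + bphi_sex * sx +
      bphi_hf * h + omega_phi[s];
    const double pi_i = inv_logit(alpha_pi + bpi_region[k] + bpi_sex * sx +
                                  bpi_hf * h + omega_pi[s]);
    const double pr_i = inv_logit(pr_int + pr_sex * sx + omega_pr[s]);
    const double rho_i = inv_logit(rho_int + rho_sex * sx + omega_rho[s]);
    const int f = first[i], l = last[i];
    for (int t = f - 1; t < T - 1; ++t) {
      phi[t] = inv_logit(phi_base + bphi_trend[k] * tc[t]);
    }
    double logL = 0.0;  // log resident-CJS term
    bool zero = false;
    for (int t = f - 1; t < l - 1; ++t) {
      const double step = phi[t] * (y(i, t + 1) ? pr_i : (1.0 - pr_i));
      if (step <= 0.0) { zero = true; break; }
      logL += std::log(step);
    }
    double chi = 1.0;
    for (int t = T - 2; t >= l - 1; --t) {
      chi = (1.0 - phi[t]) + phi[t] * (1.0 - pr_i) * chi;
    }
    double L = zero ? 0.0 : std::exp(logL) * chi;
    double lik;
    if (pred[i] == 1) {
      lik = pi_i * rho_i * L;
    } else {
      lik = pi_i * (1.0 - rho_i) * L;
      if (l == f) lik += 1.0 - pi_i;
    }
    ll[s] += std::log(lik);
  }
  return ll;
}
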