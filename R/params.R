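#' Parameter containers for the demographic models
#'
#' Constructors for the three parameter sets used both as simulation truths
#' and as containers for likelihood evaluation. All covariate effects are on
#' the link scale (log for abundance, logit for productivity, survival,
#' residency, recapture and pre-determination) and are interpreted against
#' standardized covariates: human footprint z-scored across stations, effort
#' z-scored across station-years, and the year covariate centered at the
#' study midpoint in units of one year, so that trend coefficients are
#' per-year on the link scale.
#'
#' Region-structured effects are indexed `(west, central, east)`. For
#' survival and residency, which carry a common intercept, the first
#' (western) region is the reference and its offset must be 0.
#'
#' Defaults are a realistic parameterization for a declining boreal-breeding
#' songbird: low apparent survival in the west and east, male-biased recapture
#' (0.56 vs 0.27), residency near 0.6 in the west and near 0.3 elsewhere, an
#' eastern abundance decline of about -4.6%/yr, and productivity (juvenile
#' proportion) near 0.32-0.43 by region.
#'
#' @param alpha_lambda region log-scale intercepts (expected adults per
#'   station-year at covariate means).
#' @param beta_trend region log-linear trends per year.
#' @param beta_hf common human-footprint effect (per SD of footprint).
#' @param beta_effort effort effect (per SD of net-hours).
#' @param sigma_station SD of station random effects (log scale).
#' @param sigma_noise SD of observation-level lognormal noise.
#' @param omega_lambda optional station random effects (one per station; 0s
#'   if omitted).
#' @return a list with class `"abundance_params"`, `"productivity_params"`
#'   or `"survival_params"`.
#' @export
abundance_params <- function(alpha_lambda = log(c(3, 3, 3)),
                             beta_trend = log(c(1 - 0.0148, 1 + 0.0121, 1 - 0.0464)),
                             beta_hf = -0.66,
                             beta_effort = 0.2,
                             sigma_station = 0.5,
                             sigma_noise = 0.3,
                             omega_lambda = NULL) {
  p <- list(alpha_lambda = alpha_lambda, beta_trend = beta_trend,
            beta_hf = beta_hf, beta_effort = beta_effort,
            sigma_station = sigma_station, sigma_noise = sigma_noise,
            omega_lambda = omega_lambda)
  stopifnot(length(alpha_lambda) == length(beta_trend))
  .check_finite(p, c("alpha_lambda", "beta_trend", "beta_hf", "beta_effort"))
  .check_sd(p, c("sigma_station", "sigma_noise"))
  structure(p, class = "abundance_params")
}

#' @rdname abundance_params
#' @param alpha_p region logit intercepts for the juvenile proportion.
#' @param beta_p_trend region logit-linear trends per year.
#' @param beta_p_hf common footprint effect on productivity.
#' @param sigma_p SD of station random effects (logit scale).
#' @param omega_p optional station random effects.
#' @export
productivity_params <- function(alpha_p = logit(c(0.35, 0.43, 0.32)),
                                beta_p_trend = c(0.01, 0.01, 0.01),
                                beta_p_hf = 0.16,
                                sigma_p = 0.3,
                                omega_p = NULL) {
  p <- list(alpha_p = alpha_p, beta_p_trend = beta_p_trend,
            beta_p_hf = beta_p_hf, sigma_p = sigma_p, omega_p = omega_p)
  stopifnot(length(alpha_p) == length(beta_p_trend))
  .check_finite(p, c("alpha_p", "beta_p_trend", "beta_p_hf"))
  .check_sd(p, "sigma_p")
  structure(p, class = "productivity_params")
}

#' @rdname abundance_params
#' @param mu_phi survival intercept (logit; reference region, female, mean
#'   covariates).
#' @param beta_phi_region,beta_pi_region region offsets; element 1 (the
#'   reference region) must be 0.
#' @param beta_phi_sex,beta_pi_sex,pr_sex,rho_sex male effects (sex coded
#'   female = 0, male = 1).
#' @param beta_phi_hf,beta_pi_hf footprint effects.
#' @param beta_phi_trend region-specific survival trends per year (logit).
#' @param alpha_pi residency intercept (logit).
#' @param pr_intercept,rho_intercept logit intercepts for recapture and
#'   pre-determination probability.
#' @param sigma_phi,sigma_pi,sigma_pr,sigma_rho station random-effect SDs.
#' @param omega_phi,omega_pi,omega_pr,omega_rho optional station random
#'   effects (one per station; 0s if omitted).
#' @export
survival_params <- function(mu_phi = logit(0.31),
                            beta_phi_region = c(0, logit(0.46) - logit(0.31),
                                                logit(0.30) - logit(0.31)),
                            beta_phi_sex = 0.58,
                            beta_phi_hf = 0.03,
                            beta_phi_trend = c(0, log(1.0635), log(0.9726)),
                            alpha_pi = logit(0.58),
                            beta_pi_region = c(0, logit(0.28) - logit(0.58),
                                               logit(0.23) - logit(0.58)),
                            beta_pi_sex = 0.42,
                            beta_pi_hf = -0.46,
                            pr_intercept = logit(0.27),
                            pr_sex = 1.25,
                            rho_intercept = logit(0.4),
                            rho_sex = 0,
                            sigma_phi = 0.2, sigma_pi = 0.2,
                            sigma_pr = 0.2, sigma_rho = 0.2,
                            omega_phi = NULL, omega_pi = NULL,
                            omega_pr = NULL, omega_rho = NULL) {
  p <- list(mu_phi = mu_phi, beta_phi_region = beta_phi_region,
            beta_phi_sex = beta_phi_sex, beta_phi_hf = beta_phi_hf,
            beta_phi_trend = beta_phi_trend,
            alpha_pi = alpha_pi, beta_pi_region = beta_pi_region,
            beta_pi_sex = beta_pi_sex, beta_pi_hf = beta_pi_hf,
            pr_intercept = pr_intercept, pr_sex = pr_sex,
            rho_intercept = rho_intercept, rho_sex = rho_sex,
            sigma_phi = sigma_phi, sigma_pi = sigma_pi,
            sigma_pr = sigma_pr, sigma_rho = sigma_rho,
            omega_phi = omega_phi, omega_pi = omega_pi,
            omega_pr = omega_pr, omega_rho = omega_rho)
  stopifnot(length(beta_phi_region) == length(beta_phi_trend),
            length(beta_phi_region) == length(beta_pi_region))
  if (beta_phi_region[1] != 0 || beta_pi_region[1] != 0) {
    .stopf("reference-region offsets (element 1) must be 0 for identifiability")
  }
  .check_finite(p, c("mu_phi", "beta_phi_region", "beta_phi_sex",
                     "beta_phi_hf", "beta_phi_trend", "alpha_pi",
                     "beta_pi_region", "beta_pi_sex", "beta_pi_hf",
                     "pr_intercept", "pr_sex", "rho_intercept", "rho_sex"))
  .check_sd(p, c("sigma_phi", "sigma_pi", "sigma_pr", "sigma_rho"))
  structure(p, class = "survival_params")
}

.check_finite <- function(p, fields) {
  for (f in fields) {
    if (!all(is.finite(p[[f]]))) .stopf("'%s' must be finite", f)
  }
}

.check_sd <- function(p, fields) {
  for (f in fields) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) .stopf("'%s' must be > 0", f)
  }
}

# station random effect lookup: NULL means all zero
.omega <- function(x, s) if (is.null(x)) rep(0, length(s)) else x[s]
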