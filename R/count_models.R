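#' Poisson abundance model: pointwise mean and log-likelihood
#'
#' The annual count of adults at a station is modelled as Poisson with a
#' log-linear mean: region intercept, region trend per year, footprint and
#' effort effects (standardized covariates), a station random effect, and
#' an observation-level normal deviate on the log scale (lognormal-Poisson
#' overdispersion).
#'
#' @param params an [abundance_params()].
#' @param station list or one-row data.frame with `region`, and optionally
#'   `hf_z` and `s` (station index for the random effect).
#' @param t_c centered year covariate.
#' @param effort_z standardized effort.
#' @param eps observation-level noise value (0 for the expected-count
#'   surface).
#' @return `abundance_mean()`: the positive Poisson mean.
#' @export
abundance_mean <- function(params, station, t_c = 0, effort_z = 0, eps = 0) {
  k <- .region_index(station$region)
  if (length(params$alpha_lambda) < k) .stopf("region index out of range")
  hf <- if (is.null(station$hf_z)) 0 else station$hf_z
  om <- if (is.null(station$s) || is.null(params$omega_lambda)) 0 else
    params$omega_lambda[station$s]
  eta <- params$alpha_lambda[k] + params$beta_trend[k] * t_c +
    params$beta_hf * hf + params$beta_effort * effort_z + om + eps
  if (!is.finite(eta)) .stopf("non-finite abundance linear predictor")
  exp(.clamp(eta))
}

#' @rdname abundance_mean
#' @param counts data.frame with `adult_count`, `region`, `t_c`,
#'   `effort_z`, optionally `hf_z`, `s` (station index) and `eps`.
#' @return `abundance_loglik()`: the Poisson log-likelihood summed over
#'   station-years.
#' @export
abundance_loglik <- function(params, counts) {
  if (nrow(counts) == 0) return(0)
  if (!.is_count(counts$adult_count)) .stopf("adult counts must be non-negative integers")
  k <- .region_index(counts$region)
  hf <- counts$hf_z %||% rep(0, nrow(counts))
  om <- if (is.null(counts$s) || is.null(params$omega_lambda)) 0 else
    params$omega_lambda[counts$s]
  eps <- counts$eps %||% 0
  eta <- params$alpha_lambda[k] + params$beta_trend[k] * counts$t_c +
    params$beta_hf * hf + params$beta_effort * counts$effort_z + om + eps
  if (any(eta > 300)) .stopf("Poisson mean overflow (linear predictor > 300)")
  sum(dpois(counts$adult_count, exp(eta), log = TRUE))
}

#' Binomial productivity model: juvenile probability and log-likelihood
#'
#' The number of juveniles among all individuals captured in a station-year
#' is binomial; the juvenile probability (an index of relative breeding
#' productivity) follows a logit-linear predictor with region intercept,
#' region trend, footprint effect and station random effect.
#'
#' @param params a [productivity_params()].
#' @param station,t_c as in [abundance_mean()].
#' @return `productivity_prob()`: the juvenile probability in (0, 1).
#' @export
productivity_prob <- function(params, station, t_c = 0) {
  k <- .region_index(station$region)
  if (length(params$alpha_p) < k) .stopf("region index out of range")
  hf <- if (is.null(station$hf_z)) 0 else station$hf_z
  om <- if (is.null(station$s) || is.null(params$omega_p)) 0 else
    params$omega_p[station$s]
  invlogit(params$alpha_p[k] + params$beta_p_trend[k] * t_c +
             params$beta_p_hf * hf + om)
}

#' @rdname productivity_prob
#' @param observations data.frame with `juveniles`, `total`, `region`,
#'   `t_c`, optionally `hf_z` and `s`.
#' @return `productivity_loglik()`: the binomial log-likelihood.
#' @export
productivity_loglik <- function(params, observations) {
  if (nrow(observations) == 0) return(0)
  if (any(observations$juveniles > observations$total)) {
    .stopf("juveniles exceed total captures")
  }
  if (!.is_count(observations$juveniles) || !.is_count(observations$total)) {
    .stopf("juvenile/total captures must be non-negative integers")
  }
  k <- .region_index(observations$region)
  hf <- observations$hf_z %||% rep(0, nrow(observations))
  om <- if (is.null(observations$s) || is.null(params$omega_p)) 0 else
    params$omega_p[observations$s]
  lp <- params$alpha_p[k] + params$beta_p_trend[k] * observations$t_c +
    params$beta_p_hf * hf + om
  sum(dbinom(observations$juveniles, observations$total,
             invlogit(.clamp(lp)), log = TRUE))
}
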