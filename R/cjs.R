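#' Linear predictors of the transient-CJS model
#'
#' Evaluates the four probabilities of the mark-recapture model for one
#' individual-year: apparent survival `phi` (intercept + region + sex +
#' footprint + region trend x year + station effect), residency `pi`
#' (intercept + region + sex + footprint + station effect, no trend), and
#' the two nuisance probabilities, recapture `pr` and pre-determination
#' `rho` (intercept + sex + station effect each). All covariates are
#' expected standardized; the year covariate `t_c` is centered at the
#' study midpoint in units of one year.
#'
#' @param history list or one-row data.frame with `sex` (0 female, 1 male).
#' @param station list or one-row data.frame with `region` (label), and
#'   optionally `hf_z` (standardized footprint, default 0) and `s` (station
#'   index into the `omega_*` vectors; station effects are 0 when the
#'   parameter object carries none).
#' @param params a [survival_params()].
#' @param t_c centered year covariate at which `phi` is evaluated (the
#'   survival interval's starting year).
#' @return list with elements `phi`, `pi`, `pr`, `rho`.
#' @export
logit_predictors <- function(history, station, params, t_c = 0) {
  k <- .region_index(station$region)
  if (length(params$beta_phi_region) < k) .stopf("region index out of range")
  sex <- history$sex
  hf <- if (is.null(station$hf_z)) 0 else station$hf_z
  s <- if (is.null(station$s)) NULL else station$s
  om <- function(x) if (is.null(x) || is.null(s)) 0 else x[s]
  list(phi = invlogit(params$mu_phi + params$beta_phi_region[k] +
                        params$beta_phi_sex * sex + params$beta_phi_hf * hf +
                        params$beta_phi_trend[k] * t_c + om(params$omega_phi)),
       pi = invlogit(params$alpha_pi + params$beta_pi_region[k] +
                       params$beta_pi_sex * sex + params$beta_pi_hf * hf +
                       om(params$omega_pi)),
       pr = invlogit(params$pr_intercept + params$pr_sex * sex +
                       om(params$omega_pr)),
       rho = invlogit(params$rho_intercept + params$rho_sex * sex +
                        om(params$omega_rho)))
}

#' Probability of never being seen again
#'
#' The standard CJS chi recursion. With survival probabilities
#' `phi[j]` over the remaining intervals and recapture probabilities
#' `pr[j]` at the occasion each interval ends on,
#' `chi_T = 1` and `chi_t = (1 - phi_t) + phi_t (1 - pr_(t+1)) chi_(t+1)`.
#'
#' @param phi_seq survival probabilities for the remaining intervals.
#' @param pr_seq recapture probabilities aligned to `phi_seq` (element `j`
#'   is the recapture probability at the occasion interval `j` ends on).
#' @return numeric vector of length `length(phi_seq) + 1`: chi from the
#'   current occasion through the final occasion (which is 1).
#' @export
chi_never_seen <- function(phi_seq, pr_seq) {
  if (length(phi_seq) != length(pr_seq)) {
    .stopf("phi_seq and pr_seq must have equal length")
  }
  stopifnot(all(phi_seq >= 0 & phi_seq <= 1), all(pr_seq >= 0 & pr_seq <= 1))
  m <- length(phi_seq)
  chi <- numeric(m + 1)
  chi[m + 1] <- 1
  for (j in rev(seq_len(m))) {
    chi[j] <- (1 - phi_seq[j]) + phi_seq[j] * (1 - pr_seq[j]) * chi[j + 1]
  }
  chi
}

# f = first detection, l = last detection of a 0/1 vector
.first_last <- function(y) {
  w <- which(y == 1L)
  if (length(w) == 0) .stopf("history has no detection")
  c(w[1], w[length(w)])
}

#' Likelihood of one capture history under the residency mixture
#'
#' Conditional on first capture. A pre-determined individual (`d = 1`,
#' within-season repeat capture) is a known resident and contributes
#' `pi * rho * P_CJS`; an individual not pre-determined contributes the
#' mixture `pi * (1 - rho) * P_CJS + (1 - pi) * I[never seen after first
#' capture]`, since a transient can never be re-detected. `P_CJS` is the
#' standard product of survival/recapture terms from first capture to last
#' detection times the chi term from the last detection onward.
#'
#' @param history list or one-row data.frame with `detections` (0/1 vector
#'   or string over the full study, first detection marks first capture),
#'   `sex`, and `predetermined` (0/1).
#' @param station as in [logit_predictors()].
#' @param params a [survival_params()].
#' @param t_mid study midpoint used to center the year covariate; defaults
#'   to `(T - 1) / 2` for a T-occasion study.
#' @return the probability of the observed history (in `[0, 1]`).
#' @export
history_likelihood <- function(history, station, params, t_mid = NULL) {
  y <- history$detections
  if (is.character(y)) y <- as.integer(strsplit(y, "")[[1]])
  if (is.list(y)) y <- y[[1]]
  if (!all(y %in% c(0L, 1L))) .stopf("malformed history: detections not 0/1")
  Tn <- length(y)
  if (is.null(t_mid)) t_mid <- (Tn - 1) / 2
  fl <- .first_last(y)
  f <- fl[1]; l <- fl[2]
  d <- history$predetermined
  if (!d %in% c(0L, 1L)) .stopf("malformed history: predetermined not 0/1")
  p1 <- logit_predictors(history, station, params, t_c = 0)
  phi <- if (Tn > 1) {
    vapply(seq_len(Tn - 1),
           function(t) logit_predictors(history, station, params,
                                        t_c = (t - 1) - t_mid)$phi, 0)
  } else numeric(0)
  p_cjs <- 1
  if (l > f) {
    for (t in f:(l - 1)) {
      p_cjs <- p_cjs * phi[t] * (if (y[t + 1] == 1L) p1$pr else 1 - p1$pr)
    }
  }
  if (l < Tn) {
    chi <- chi_never_seen(phi[l:(Tn - 1)], rep(p1$pr, Tn - l))
    p_cjs <- p_cjs * chi[1]
  }
  if (d == 1) {
    p1$pi * p1$rho * p_cjs
  } else {
    p1$pi * (1 - p1$rho) * p_cjs + (1 - p1$pi) * as.numeric(l == f)
  }
}

# map a survival_params object + station table to the compiled likelihood
.cjs_loglik_stations <- function(histories, stations, params, t_mid = NULL) {
  y <- detections_to_matrix(histories$detections)
  Tn <- ncol(y)
  if (is.null(t_mid)) t_mid <- (Tn - 1) / 2
  fl <- t(apply(y, 1, .first_last))
  s <- match(as.character(histories$station_id), stations$station_id)
  if (anyNA(s)) .stopf("history references unknown station")
  hf <- if (is.null(stations$hf_z)) rep(0, nrow(stations)) else stations$hf_z
  K <- length(params$beta_phi_region)
  S <- nrow(stations)
  ze <- function(x) if (is.null(x)) rep(0, S) else x
  cjs_loglik_by_station(y, as.integer(fl[, 1]), as.integer(fl[, 2]),
                        as.integer(histories$predetermined),
                        as.numeric(histories$sex),
                        as.integer(s), as.integer(.region_index(stations$region)),
                        as.numeric(hf),
                        as.numeric((seq_len(Tn) - 1) - t_mid),
                        params$mu_phi, params$beta_phi_region,
                        params$beta_phi_sex, params$beta_phi_hf,
                        params$beta_phi_trend,
                        params$alpha_pi, params$beta_pi_region,
                        params$beta_pi_sex, params$beta_pi_hf,
                        params$pr_intercept, params$pr_sex,
                        params$rho_intercept, params$rho_sex,
                        ze(params$omega_phi), ze(params$omega_pi),
                        ze(params$omega_pr), ze(params$omega_rho), S)
}

#' Dataset log-likelihood of the transient-CJS model
#'
#' Sum of per-history log-likelihoods. The default (vectorized) path runs
#' in compiled code; `method = "loop"` evaluates [history_likelihood()]
#' history by history and exists as an independent consistency check (the
#' two agree to 1e-12).
#'
#' @param histories data.frame with `station_id`, `sex` (0/1),
#'   `detections` (fixed-width 0/1 strings), `predetermined`.
#' @param stations station table with `station_id`, `region`, optional
#'   `hf_z`; row order defines the station index for `omega_*` effects.
#' @param params a [survival_params()].
#' @param t_mid year-covariate centering (default `(T - 1) / 2`).
#' @param method `"vectorized"` (compiled) or `"loop"` (reference).
#' @return the log-likelihood; `-Inf` when some history has probability 0.
#' @export
dataset_loglik <- function(histories, stations, params, t_mid = NULL,
                           method = c("vectorized", "loop")) {
  method <- match.arg(method)
  if (nrow(histories) == 0) return(0)
  if (method == "vectorized") {
    ll <- sum(.cjs_loglik_stations(histories, stations, params, t_mid))
  } else {
    s <- match(as.character(histories$station_id), stations$station_id)
    if (anyNA(s)) .stopf("history references unknown station")
    terms <- vapply(seq_len(nrow(histories)), function(i) {
      st <- stations[s[i], ]
      st$s <- s[i]
      log(history_likelihood(histories[i, ], st, params, t_mid))
    }, 0)
    ll <- sum(terms)
  }
  if (is.nan(ll)) {
    if (method == "vectorized") {
      per <- vapply(seq_len(nrow(histories)), function(i) {
        sum(.cjs_loglik_stations(histories[i, , drop = FALSE], stations,
                                 params, t_mid))
      }, 0)
    } else {
      per <- terms
    }
    bad <- which(is.nan(per))[1]
    id <- if (is.null(histories$individual_id)) as.character(bad) else
      as.character(histories$individual_id[bad])
    .stopf("non-finite likelihood term for individual %s", id)
  }
  ll
}

`%||%` <- function(a, b) if (is.null(a)) b else a
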