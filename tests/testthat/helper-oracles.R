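# Independent oracles and fixture builders. Everything here deliberately
# avoids the package's own likelihood code paths.

# Textbook CJS likelihood by exhaustive enumeration over the latent
# last-alive occasion: P(history | resident, first capture at f) =
#   sum_{a = l..T} P(survive f..a, die in (a, a+1]) *
#                  prod_{t = f+1..a} p^{y_t} (1-p)^{1-y_t}
# with "die in (T, T+1]" meaning survived to the end.
cjs_enum_lik <- function(y, phi, p) {
  Tn <- length(y)
  f <- which(y == 1L)[1]
  l <- max(which(y == 1L))
  if (f == Tn) return(1)
  tot <- 0
  for (a in l:Tn) {
    surv <- if (a > f) prod(phi[f:(a - 1)]) else 1
    death <- if (a < Tn) (1 - phi[a]) else 1
    det <- if (a > f) prod(ifelse(y[(f + 1):a] == 1L, p, 1 - p)) else 1
    tot <- tot + surv * death * det
  }
  tot
}

# Transient-mixture likelihood by enumeration over residency and the
# latent last-alive occasion.
transient_enum_lik <- function(y, d, phi, p, pi, rho) {
  Tn <- length(y)
  f <- which(y == 1L)[1]
  res <- cjs_enum_lik(y, phi, p)
  if (d == 1) {
    pi * rho * res
  } else {
    trans <- if (all(y[-seq_len(f)] == 0L)) 1 else 0
    pi * (1 - rho) * res + (1 - pi) * trans
  }
}

# All post-first-capture detection vectors for a T-occasion study with
# first capture at occasion f.
enumerate_histories <- function(Tn, f) {
  m <- Tn - f
  if (m == 0) {
    y <- integer(Tn); y[f] <- 1L
    return(list(y))
  }
  grids <- expand.grid(rep(list(0:1), m))
  lapply(seq_len(nrow(grids)), function(i) {
    y <- integer(Tn)
    y[f] <- 1L
    y[(f + 1):Tn] <- as.integer(grids[i, ])
    y
  })
}

# flat parameter set: every probability 0.5, single west station
flat_survival_params <- function(...) {
  survival_params(mu_phi = 0, beta_phi_region = c(0, 0, 0), beta_phi_sex = 0,
                  beta_phi_hf = 0, beta_phi_trend = c(0, 0, 0),
                  alpha_pi = 0, beta_pi_region = c(0, 0, 0), beta_pi_sex = 0,
                  beta_pi_hf = 0, pr_intercept = 0, pr_sex = 0,
                  rho_intercept = 0, rho_sex = 0, ...)
}

# constant-probability parameter set on the logit scale
const_survival_params <- function(phi, pr, pi, rho, trend = c(0, 0, 0)) {
  survival_params(mu_phi = qlogis(phi), beta_phi_region = c(0, 0, 0),
                  beta_phi_sex = 0, beta_phi_hf = 0, beta_phi_trend = trend,
                  alpha_pi = qlogis(pi), beta_pi_region = c(0, 0, 0),
                  beta_pi_sex = 0, beta_pi_hf = 0,
                  pr_intercept = qlogis(pr), pr_sex = 0,
                  rho_intercept = qlogis(rho), rho_sex = 0)
}

one_station <- function(region = "west") {
  data.frame(station_id = "S1", region = region, hf_z = 0)
}

history_df <- function(y, d = 0L, sex = 0, station = "S1") {
  data.frame(individual_id = "i1", station_id = station, sex = sex,
             detections = paste(y, collapse = ""), predetermined = d)
}

# random survival params with probabilities away from 0/1
random_survival_params <- function() {
  const_survival_params(phi = runif(1, 0.1, 0.9), pr = runif(1, 0.1, 0.9),
                        pi = runif(1, 0.1, 0.9), rho = runif(1, 0.1, 0.9))
}

# posterior_chains stand-in built from a named draw matrix, for testing the
# chain-summary machinery without running a sampler
fake_fit <- function(draws, meta) {
  obj <- structure(list(chains = list(draws), params = colnames(draws),
                        config = NULL), class = "posterior_chains")
  attr(obj, "meta") <- meta
  obj
}
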