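test_that("abundance mean and log-likelihood match the Poisson form", {
  p0 <- abundance_params(alpha_lambda = c(0, 0, 0), beta_trend = c(0, 0, 0),
                         beta_hf = 0, beta_effort = 0)
  expect_equal(abundance_mean(p0, list(region = "central")), 1)
  p3 <- abundance_params(alpha_lambda = log(c(3, 3, 3)), beta_trend = c(0, 0, 0),
                         beta_hf = 0, beta_effort = 0)
  expect_equal(abundance_mean(p3, list(region = "west")), 3, tolerance = 1e-12)
  # east-like decline: -0.0475/yr over 10 years
  pt <- abundance_params(alpha_lambda = c(0, 0, 0),
                         beta_trend = c(0, 0, -0.0475), beta_hf = 0,
                         beta_effort = 0)
  r <- abundance_mean(pt, list(region = "east"), t_c = 10) /
    abundance_mean(pt, list(region = "east"), t_c = 0)
  expect_equal(r, exp(-0.475), tolerance = 1e-12)

  obs <- data.frame(adult_count = 0L, region = "west", t_c = 0, effort_z = 0)
  expect_equal(abundance_loglik(p0, obs), -1)              # log Pois(0; 1)
  expect_equal(abundance_loglik(p0, obs[0, ]), 0)
  # independent factorial-form oracle on a random table
  set.seed(5)
  tab <- data.frame(adult_count = rpois(40, 3),
                    region = sample(c("west", "central", "east"), 40, TRUE),
                    t_c = runif(40, -5, 5), effort_z = rnorm(40),
                    hf_z = rnorm(40))
  pr <- abundance_params(alpha_lambda = c(0.3, 0.5, 0.1),
                         beta_trend = c(-0.02, 0.01, -0.04),
                         beta_hf = -0.3, beta_effort = 0.2)
  k <- match(tab$region, c("west", "central", "east"))
  lam <- exp(pr$alpha_lambda[k] + pr$beta_trend[k] * tab$t_c -
               0.3 * tab$hf_z + 0.2 * tab$effort_z)
  oracle <- sum(tab$adult_count * log(lam) - lam - lfactorial(tab$adult_count))
  expect_equal(abundance_loglik(pr, tab), oracle, tolerance = 1e-10)
  expect_error(abundance_loglik(p0, transform(obs, adult_count = -1)),
               "non-negative")
})

test_that("productivity probability and log-likelihood match the binomial form", {
  p0 <- productivity_params(alpha_p = c(0, 0, 0), beta_p_trend = c(0, 0, 0),
                            beta_p_hf = 0)
  expect_equal(productivity_prob(p0, list(region = "west")), 0.5)
  p43 <- productivity_params(alpha_p = rep(qlogis(0.43), 3),
                             beta_p_trend = c(0, 0, 0), beta_p_hf = 0)
  expect_equal(productivity_prob(p43, list(region = "central")), 0.43,
               tolerance = 1e-12)
  # footprint effect 0.19 shifts the logit by 0.19 at hf_z = 1
  p19 <- productivity_params(alpha_p = c(0, 0, 0), beta_p_trend = c(0, 0, 0),
                             beta_p_hf = 0.19)
  expect_equal(qlogis(productivity_prob(p19, list(region = "west", hf_z = 1))),
               0.19, tolerance = 1e-12)

  obs1 <- data.frame(juveniles = 1L, total = 2L, region = "west", t_c = 0)
  expect_equal(productivity_loglik(p0, obs1), log(0.5), tolerance = 1e-12)
  expect_equal(productivity_loglik(p0, obs1[0, ]), 0)
  # JUV = N under p -> 1 stays finite under the guarded evaluation
  pbig <- productivity_params(alpha_p = c(50, 50, 50), beta_p_trend = c(0, 0, 0),
                              beta_p_hf = 0)
  obsN <- data.frame(juveniles = 5L, total = 5L, region = "west", t_c = 0)
  expect_equal(productivity_loglik(pbig, obsN), 5 * log(plogis(30)),
               tolerance = 1e-9)
  expect_error(productivity_loglik(p0, transform(obs1, juveniles = 3L)),
               "exceed")
  # independent pmf oracle
  set.seed(6)
  tab <- data.frame(total = rpois(30, 8) + 1L,
                    region = sample(c("west", "central", "east"), 30, TRUE),
                    t_c = runif(30, -5, 5), hf_z = rnorm(30))
  tab$juveniles <- rbinom(30, tab$total, 0.4)
  pp <- productivity_params(alpha_p = c(-0.5, 0.2, 0.1),
                            beta_p_trend = c(0.01, -0.02, 0.03),
                            beta_p_hf = 0.15)
  k <- match(tab$region, c("west", "central", "east"))
  prob <- plogis(pp$alpha_p[k] + pp$beta_p_trend[k] * tab$t_c + 0.15 * tab$hf_z)
  oracle <- sum(lchoose(tab$total, tab$juveniles) + tab$juveniles * log(prob) +
                  (tab$total - tab$juveniles) * log(1 - prob))
  expect_equal(productivity_loglik(pp, tab), oracle, tolerance = 1e-10)
})

test_that("intercept-only likelihoods are maximized at the closed forms", {
  set.seed(8)
  cts <- data.frame(adult_count = rpois(200, 3.7), region = "west",
                    t_c = 0, effort_z = 0)
  f <- function(a) abundance_loglik(abundance_params(alpha_lambda = c(a, 0, 0),
                                                     beta_trend = c(0, 0, 0),
                                                     beta_hf = 0, beta_effort = 0),
                                    cts)
  opt <- optimize(f, c(-3, 3), maximum = TRUE, tol = 1e-9)
  expect_equal(opt$maximum, log(mean(cts$adult_count)), tolerance = 1e-6)

  tab <- data.frame(total = rpois(200, 10) + 1L, region = "west", t_c = 0)
  tab$juveniles <- rbinom(200, tab$total, 0.35)
  g <- function(a) productivity_loglik(productivity_params(alpha_p = c(a, 0, 0),
                                                           beta_p_trend = c(0, 0, 0),
                                                           beta_p_hf = 0),
                                       tab)
  opt2 <- optimize(g, c(-3, 3), maximum = TRUE, tol = 1e-9)
  expect_equal(opt2$maximum, qlogis(sum(tab$juveniles) / sum(tab$total)),
               tolerance = 1e-6)
})

test_that("simulation and likelihood fit round-trip without random effects", {
  # large-n ML recovery of the trend and footprint coefficients
  ab <- abundance_params(alpha_lambda = c(log(4), 0, 0), beta_trend = c(-0.04, 0, 0),
                         beta_hf = -0.4, beta_effort = 0.25, sigma_noise = 1e-9,
                         omega_lambda = rep(0, 40))
  sc <- simulation_scenario(n_stations = c(west = 40, central = 0, east = 0),
                            n_years = 24, mean_active_years = 24,
                            abundance = ab, seed = 91)
  st <- simulate_stations(sc)
  cts <- simulate_counts(st, ab, sc)
  prep <- standardize_covariates(st, cts, first_year = 1993, n_years = 24)
  obs <- prep$counts
  obs$hf_z <- prep$stations$hf_z[match(obs$station_id, prep$stations$station_id)]
  obs$region <- "west"
  nll <- function(v) {
    # overflow guard: the likelihood errors on lambda overflow by contract,
    # so give the optimizer a finite penalty instead
    tryCatch(-abundance_loglik(abundance_params(alpha_lambda = c(v[1], 0, 0),
                                                beta_trend = c(v[2], 0, 0),
                                                beta_hf = v[3], beta_effort = v[4],
                                                sigma_noise = 1e-9), obs),
             error = function(e) 1e10)
  }
  fit <- optim(c(1, 0, 0, 0), nll, method = "BFGS")
  truth <- c(log(4), -0.04, -0.4, 0.25)
  se <- sqrt(diag(solve(optim(fit$par, nll, method = "BFGS",
                              hessian = TRUE)$hessian)))
  expect_true(all(abs(fit$par - truth) < 3 * se + 1e-3))
})
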