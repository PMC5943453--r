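test_that("logit predictors evaluate the four linear predictors", {
  p0 <- flat_survival_params()
  pred <- logit_predictors(list(sex = 0), list(region = "west"), p0)
  expect_equal(unlist(pred), c(phi = 0.5, pi = 0.5, pr = 0.5, rho = 0.5))

  p45 <- flat_survival_params()
  p45$mu_phi <- qlogis(0.45)
  expect_equal(logit_predictors(list(sex = 1), list(region = "west"), p45)$phi,
               0.45, tolerance = 1e-12)  # sex effect is 0 here

  # male effect 0.58 on top of logit(0.31)
  p31 <- flat_survival_params()
  p31$mu_phi <- qlogis(0.31)
  p31$beta_phi_sex <- 0.58
  expect_equal(logit_predictors(list(sex = 1), list(region = "west"), p31)$phi,
               plogis(qlogis(0.31) + 0.58), tolerance = 1e-12)
  expect_equal(round(logit_predictors(list(sex = 1), list(region = "west"),
                                      p31)$phi, 3), 0.445)

  # region, footprint, trend and station effects all enter phi
  pf <- flat_survival_params(omega_phi = c(0.3))
  pf$beta_phi_region <- c(0, 0.2, -0.1)
  pf$beta_phi_hf <- 0.5
  pf$beta_phi_trend <- c(0, 0, 0.05)
  pred <- logit_predictors(list(sex = 1), list(region = "east", hf_z = 1.2, s = 1),
                           pf, t_c = 4)
  expect_equal(pred$phi, plogis(-0.1 + 0.5 * 1.2 + 0.05 * 4 + 0.3),
               tolerance = 1e-12)
  expect_error(logit_predictors(list(sex = 0), list(region = "north"), p0),
               "region")
})

test_that("the chi recursion handles the boundary cases", {
  expect_equal(chi_never_seen(rep(0, 4), rep(0.5, 4)), rep(1, 5))
  expect_equal(chi_never_seen(rep(1, 3), rep(1, 3)), c(0, 0, 0, 1))
  expect_equal(chi_never_seen(c(0.5, 0.5), c(0.5, 0.5))[1], 0.6875)
  expect_error(chi_never_seen(c(0.5), c(0.5, 0.5)), "equal length")
  # monotone non-increasing in phi and pr for constant sequences
  grid <- seq(0.05, 0.95, by = 0.15)
  chis_phi <- vapply(grid, function(f) chi_never_seen(rep(f, 3), rep(0.4, 3))[1], 0)
  chis_pr <- vapply(grid, function(p) chi_never_seen(rep(0.4, 3), rep(p, 3))[1], 0)
  expect_true(all(diff(chis_phi) <= 0))
  expect_true(all(diff(chis_pr) <= 0))
})

test_that("history likelihood implements the residency mixture", {
  st <- one_station()
  # one-occasion study: outcomes over d sum to 1 (pi*rho + pi*(1-rho) + (1-pi))
  p <- const_survival_params(phi = 0.5, pr = 0.5, pi = 0.6, rho = 0.3)
  l1 <- history_likelihood(history_df(1L, d = 1L), st, p)
  l0 <- history_likelihood(history_df(1L, d = 0L), st, p)
  expect_equal(l1, 0.6 * 0.3, tolerance = 1e-12)
  expect_equal(l1 + l0, 1, tolerance = 1e-12)

  # (1,1), d = 1, pi = rho = 1, phi = pr = 0.5 -> phi * pr = 0.25
  pp <- const_survival_params(phi = 0.5, pr = 0.5, pi = 1 - 1e-15, rho = 1 - 1e-15)
  expect_equal(history_likelihood(history_df(c(1L, 1L), d = 1L), st, pp), 0.25,
               tolerance = 1e-9)

  # (1,0,0), d = 0: brute-force enumeration over residency and death time
  pm <- const_survival_params(phi = 0.5, pr = 0.5, pi = 0.6, rho = 0.5)
  got <- history_likelihood(history_df(c(1L, 0L, 0L), d = 0L), st, pm)
  want <- transient_enum_lik(c(1L, 0L, 0L), 0L, phi = rep(0.5, 2), p = 0.5,
                             pi = 0.6, rho = 0.5)
  expect_equal(got, want, tolerance = 1e-12)

  # a detection after first year is impossible for pi = 0
  p0 <- const_survival_params(phi = 0.5, pr = 0.5, pi = 1e-300, rho = 0.5)
  expect_equal(history_likelihood(history_df(c(1L, 1L), d = 0L), st, p0), 0,
               tolerance = 1e-290)
  expect_error(history_likelihood(history_df(c(1L, 2L)), st, p), "malformed")
})

test_that("outcome probabilities sum to one over all histories and flags", {
  set.seed(31)
  st <- one_station()
  for (Tn in 2:5) {
    for (rep in 1:5) {
      p <- random_survival_params()
      for (f in c(1L, Tn)) {
        tot <- 0
        for (y in enumerate_histories(Tn, f)) {
          for (d in 0:1) {
            tot <- tot + history_likelihood(history_df(y, d = d), st, p)
          }
        }
        expect_equal(tot, 1, tolerance = 1e-10)
      }
    }
  }
})

test_that("with pi = 1, rho = 0 the model reduces to textbook CJS", {
  set.seed(47)
  st <- one_station()
  Tn <- 8
  for (rep in 1:200) {
    phi <- runif(1, 0.1, 0.9); pr <- runif(1, 0.1, 0.9)
    p <- const_survival_params(phi = phi, pr = pr, pi = 1 - 1e-15, rho = 1e-15)
    f <- sample.int(Tn, 1)
    y <- integer(Tn); y[f] <- 1L
    if (f < Tn) y[(f + 1):Tn] <- rbinom(Tn - f, 1, 0.4)
    got <- history_likelihood(history_df(y, d = 0L), st, p)
    want <- cjs_enum_lik(y, rep(phi, Tn - 1), pr)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("dataset log-likelihood is additive and matches the per-history loop", {
  sc <- simulation_scenario(n_stations = c(west = 3, central = 2, east = 3),
                            n_years = 7, new_per_station_year = 2, seed = 23)
  d <- simulate_banding_data(sc)
  st <- d$stations
  st$hf_z <- (st$hf_1km - mean(st$hf_1km)) / sd(st$hf_1km)
  p <- survival_params(omega_phi = rnorm(8, 0, 0.2), omega_pi = rnorm(8, 0, 0.2),
                       omega_pr = rnorm(8, 0, 0.2), omega_rho = rnorm(8, 0, 0.2))
  h <- d$captures[seq_len(min(50, nrow(d$captures))), ]
  ll_vec <- dataset_loglik(h, st, p)
  ll_loop <- dataset_loglik(h, st, p, method = "loop")
  expect_equal(ll_vec, ll_loop, tolerance = 1e-12)
  expect_equal(dataset_loglik(h[0, ], st, p), 0)
  expect_equal(dataset_loglik(rbind(h, h), st, p), 2 * ll_vec, tolerance = 1e-10)
  # equals the sum of individually computed history log-likelihoods
  per <- vapply(seq_len(nrow(h)), function(i) {
    s <- match(h$station_id[i], st$station_id)
    row <- st[s, ]; row$s <- s
    log(history_likelihood(h[i, ], row, p))
  }, 0)
  expect_equal(ll_vec, sum(per), tolerance = 1e-10)
})

test_that("likelihood is monotone in pr for all-ones histories", {
  st <- one_station()
  vals <- vapply(seq(0.1, 0.9, by = 0.1), function(pr) {
    p <- const_survival_params(phi = 0.6, pr = pr, pi = 0.8, rho = 0.5)
    history_likelihood(history_df(c(1L, 1L, 1L, 1L), d = 0L), st, p)
  }, 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("average score at the simulation truth is near zero", {
  # score identity: E[d logL / d theta] = 0 at the generating parameters
  sv <- const_survival_params(phi = 0.45, pr = 0.5, pi = 0.6, rho = 0.4)
  sc <- simulation_scenario(n_stations = c(west = 6, central = 0, east = 0),
                            n_years = 8, new_per_station_year = 6,
                            mean_active_years = 8, survival = sv, seed = 77)
  st <- simulate_stations(sc)
  eps <- 1e-4
  grad_names <- c("mu_phi", "alpha_pi", "pr_intercept", "rho_intercept")
  grads <- matrix(0, 40, length(grad_names))
  for (r in 1:40) {
    h <- simulate_capture_histories(st, sv, sc, seed = 1000 + r)
    for (j in seq_along(grad_names)) {
      up <- sv; up[[grad_names[j]]] <- up[[grad_names[j]]] + eps
      dn <- sv; dn[[grad_names[j]]] <- dn[[grad_names[j]]] - eps
      grads[r, j] <- (dataset_loglik(h, st, up) - dataset_loglik(h, st, dn)) /
        (2 * eps)
    }
  }
  z <- colMeans(grads) / (apply(grads, 2, sd) / sqrt(nrow(grads)))
  expect_true(all(abs(z) < 4))
})
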