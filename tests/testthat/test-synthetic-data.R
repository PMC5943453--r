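test_that("station layout matches the scenario and is seed-reproducible", {
  sc <- simulation_scenario(n_stations = c(west = 23, central = 3, east = 33),
                            n_years = 24, seed = 7)
  st <- simulate_stations(sc)
  expect_equal(nrow(st), 59)
  expect_equal(as.vector(table(st$region)[c("west", "central", "east")]),
               c(23, 3, 33))
  hf <- unlist(st[, c("hf_1993_1km", "hf_2009_1km", "hf_1993_10km",
                      "hf_2009_10km", "hf_1km", "hf_10km")])
  expect_true(all(hf >= 0 & hf <= 50))
  expect_true(all(unlist(st$effort_by_year) > 0))
  yrs <- attr(st, "years")
  expect_true(all(unlist(st$active_years) %in% yrs))
  expect_true(all(vapply(st$active_years, length, 0L) >= 2))
  # coordinates agree with the region classifier
  expect_equal(classify_region(st$longitude, st$latitude), st$region)
  expect_identical(st, simulate_stations(sc))

  sc0 <- simulation_scenario(n_stations = c(west = 5, central = 0, east = 2),
                             n_years = 5, seed = 1)
  st0 <- simulate_stations(sc0)
  expect_false("central" %in% st0$region)
  expect_error(simulation_scenario(n_years = 1), "n_years")
})

test_that("simulated counts follow the log-linear Poisson surface", {
  # all coefficients zero -> lambda = 1 at every active station-year
  ab0 <- abundance_params(alpha_lambda = c(0, 0, 0), beta_trend = c(0, 0, 0),
                          beta_hf = 0, beta_effort = 0, sigma_noise = 1e-9,
                          omega_lambda = rep(0, 120))
  sc <- simulation_scenario(n_stations = c(west = 40, central = 40, east = 40),
                            n_years = 24, mean_active_years = 24,
                            abundance = ab0, seed = 3)
  st <- simulate_stations(sc)
  cts <- simulate_counts(st, ab0, sc)
  expect_true(nrow(cts) > 2000)
  expect_lt(abs(mean(cts$adult_count) - 1), 3 / sqrt(nrow(cts)))
  # records exist exactly for active station-years
  key <- paste(cts$station_id, cts$year)
  active <- unlist(lapply(seq_len(nrow(st)),
                          function(i) paste(st$station_id[i], st$active_years[[i]])))
  expect_setequal(key, active)

  # Poisson moments at lambda = 4: mean within 3 SE, var consistent
  ab4 <- abundance_params(alpha_lambda = log(c(4, 4, 4)), beta_trend = c(0, 0, 0),
                          beta_hf = 0, beta_effort = 0, sigma_noise = 1e-9,
                          omega_lambda = rep(0, 120))
  c4 <- simulate_counts(st, ab4, sc, seed = 11)
  n <- nrow(c4)
  expect_lt(abs(mean(c4$adult_count) - 4), 3 * 2 / sqrt(n))
  # lognormal noise inflates variance above the mean
  abn <- abundance_params(alpha_lambda = log(c(4, 4, 4)), beta_trend = c(0, 0, 0),
                          beta_hf = 0, beta_effort = 0, sigma_noise = 0.6,
                          omega_lambda = rep(0, 120))
  cn <- simulate_counts(st, abn, sc, seed = 12)
  expect_gt(var(cn$adult_count), mean(cn$adult_count))

  # trend identity: lambda declines 10%/yr when beta_trend = ln(0.9)
  abt <- abundance_params(alpha_lambda = c(0, 0, 0),
                          beta_trend = log(c(0.9, 0.9, 0.9)),
                          beta_hf = 0, beta_effort = 0, sigma_noise = 1e-9,
                          omega_lambda = rep(0, 120))
  st1 <- data.frame(region = "west")
  lam0 <- abundance_mean(abt, st1, t_c = 0)
  lam10 <- abundance_mean(abt, st1, t_c = 10)
  expect_equal(lam10 / lam0, 0.9^10, tolerance = 1e-12)
})

test_that("simulated productivity is binomial on the logit surface", {
  pd0 <- productivity_params(alpha_p = c(0, 0, 0), beta_p_trend = c(0, 0, 0),
                             beta_p_hf = 0, omega_p = rep(0, 60))
  sc <- simulation_scenario(n_stations = c(west = 20, central = 20, east = 20),
                            n_years = 24, mean_active_years = 24,
                            captures_per_station_year = 8,
                            productivity = pd0, seed = 4)
  st <- simulate_stations(sc)
  pr <- simulate_productivity(st, pd0, sc)
  expect_true(all(pr$juveniles <= pr$total))
  frac <- sum(pr$juveniles) / sum(pr$total)
  expect_lt(abs(frac - 0.5), 3 * 0.5 / sqrt(sum(pr$total)))

  # N = 0 rows give JUV = 0 when totals are supplied
  tot <- data.frame(station_id = st$station_id[1],
                    year = st$active_years[[1]][1], total = 0L)
  pr0 <- simulate_productivity(st, pd0, sc, totals = tot)
  expect_true(all(pr0$juveniles == 0))
  expect_error(simulate_productivity(st, pd0, sc,
                                     totals = transform(tot, total = -1)),
               ">= 0")

  # intercept at logit(0.32): juvenile fraction converges to 0.32
  pd32 <- productivity_params(alpha_p = rep(qlogis(0.32), 3),
                              beta_p_trend = c(0, 0, 0), beta_p_hf = 0,
                              omega_p = rep(0, 60))
  p32 <- simulate_productivity(st, pd32, sc, seed = 5)
  n <- sum(p32$total)
  expect_lt(abs(sum(p32$juveniles) / n - 0.32),
            3 * sqrt(0.32 * 0.68 / n))
})

test_that("capture histories respect the residency mixture", {
  base <- simulation_scenario(n_stations = c(west = 20, central = 0, east = 0),
                              n_years = 8, new_per_station_year = 10,
                              mean_active_years = 8, seed = 6)
  # pi ~ 0: everyone transient, no post-first detections, none pre-determined
  sv0 <- const_survival_params(phi = 0.5, pr = 0.5, pi = 1e-12, rho = 0.5)
  st <- simulate_stations(base)
  h0 <- simulate_capture_histories(st, sv0, base)
  y <- detections_to_matrix(h0$detections)
  expect_true(all(rowSums(y) == 1))
  expect_true(all(h0$predetermined == 0))

  # pi = 1, rho ~ 1: everyone flagged pre-determined
  sv1 <- const_survival_params(phi = 0.5, pr = 0.5, pi = 1 - 1e-12,
                               rho = 1 - 1e-12)
  h1 <- simulate_capture_histories(st, sv1, base)
  expect_true(all(h1$predetermined == 1))

  # pi = 0.67, rho = 0.5: pre-determined fraction ~ 0.335 within 3 SE
  sv2 <- const_survival_params(phi = 0.45, pr = 0.56, pi = 0.67, rho = 0.5)
  h2 <- simulate_capture_histories(st, sv2, base, seed = 8)
  n <- nrow(h2)
  expect_gt(n, 1000)
  expect_lt(abs(mean(h2$predetermined) - 0.335),
            3 * sqrt(0.335 * 0.665 / n))

  # one-step return rate converges to pi * phi * pr
  y2 <- detections_to_matrix(h2$detections)
  f <- apply(y2, 1, function(r) which(r == 1)[1])
  sel <- f < ncol(y2)
  ret <- y2[cbind(which(sel), f[sel] + 1)]
  p_exp <- 0.67 * 0.45 * 0.56
  expect_lt(abs(mean(ret) - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / sum(sel)))

  # every detection vector starts with a 1 at first capture by construction
  expect_true(all(y2[cbind(seq_len(nrow(y2)), f)] == 1))
})

test_that("the full generator is deterministic and internally consistent", {
  sc <- simulation_scenario(n_stations = c(west = 4, central = 2, east = 4),
                            n_years = 8, seed = 42)
  d1 <- simulate_banding_data(sc)
  d2 <- simulate_banding_data(sc)
  expect_identical(d1, d2)
  # transients (known from truth only via flags): no pre-determined individual
  # lacks detections, and truth records realized random effects
  expect_length(d1$truth$survival$omega_phi, nrow(d1$stations))
  expect_true(all(nchar(d1$captures$detections) == sc$n_years))
  expect_identical(sort(unique(d1$counts$station_id)),
                   sort(d1$stations$station_id))
})
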