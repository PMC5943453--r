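# Block-built samplers for the three observation models. Parameter names in
# the chains follow the link-scale notation: mu_phi, beta_phi[region],
# beta_phi_sex, beta_phi_hf, trend_phi[region], alpha_pi, ..., pr_intercept,
# rho_intercept, omega_*[station], sigma2_*; abundance uses
# alpha_lambda[region], beta_trend[region], beta_hf, beta_effort,
# omega_lam[station], eps[obs], sigma2_station, sigma2_noise; productivity
# uses alpha_p[region], trend_p[region], beta_p_hf, omega_p[station],
# sigma2_p.

PRIOR_COEF_SD <- sqrt(1000)  # normal(0, variance 10^3) on coefficients
PRIOR_IG_SHAPE <- 0.001      # inverse-gamma(0.001, 0.001) on variances
PRIOR_IG_RATE <- 0.001

.sex_numeric <- function(sex) {
  if (is.numeric(sex)) return(ifelse(sex %in% c(0, 1), sex, NA_real_))
  up <- toupper(as.character(sex))
  out <- rep(NA_real_, length(sex))
  out[up %in% c("F", "FEMALE", "0")] <- 0
  out[up %in% c("M", "MALE", "1")] <- 1
  out
}

.hf_z_all <- function(stations, config) {
  hfcol <- paste0("hf_", config$hf_scale)
  s <- stats::sd(stations[[hfcol]])
  if (!is.finite(s) || s == 0) {
    list(z = rep(0, nrow(stations)), mean = mean(stations[[hfcol]]), sd = NA,
         use = FALSE)
  } else {
    list(z = (stations[[hfcol]] - mean(stations[[hfcol]])) / s,
         mean = mean(stations[[hfcol]]), sd = s, use = TRUE)
  }
}

.ig_gibbs <- function(omega) {
  1 / rgamma(1, PRIOR_IG_SHAPE + length(omega) / 2,
             PRIOR_IG_RATE + sum(omega^2) / 2)
}

# ---- survival (transient CJS) ------------------------------------------

.survival_component <- function(captures, stations, config, first_year = NULL,
                                n_years = NULL) {
  sex <- .sex_numeric(captures$sex)
  if (anyNA(sex)) {
    message(sprintf("survival: excluding %d individual(s) of unknown sex",
                    sum(is.na(sex))))
    captures <- captures[!is.na(sex), , drop = FALSE]
    sex <- sex[!is.na(sex)]
  }
  keep <- filter_survival_stations(captures, config$min_marked_individuals)
  sel <- captures$station_id %in% keep
  captures <- captures[sel, , drop = FALSE]
  sex <- sex[sel]
  if (nrow(captures) == 0) .stopf("no survival data after filtering")
  hf <- .hf_z_all(stations, config)
  st <- stations[stations$station_id %in% keep, , drop = FALSE]
  hf_z <- hf$z[stations$station_id %in% keep]
  y <- detections_to_matrix(captures$detections)
  Tn <- ncol(y)
  if (!is.null(n_years) && n_years != Tn) {
    .stopf("detection strings span %d years but n_years = %d", Tn, n_years)
  }
  t_mid <- (Tn - 1) / 2
  fl <- t(apply(y, 1, .first_last))
  regions <- REGION_LEVELS[REGION_LEVELS %in% unique(st$region)]
  k_st <- match(st$region, regions)
  s_idx <- match(as.character(captures$station_id), st$station_id)
  K <- length(regions); S <- nrow(st)
  nm_reg <- function(base, r) sprintf("%s[%s]", base, r)
  fixed <- c("mu_phi",
             if (K > 1) nm_reg("beta_phi", regions[-1]),
             "beta_phi_sex",
             if (hf$use) "beta_phi_hf",
             nm_reg("trend_phi", regions),
             "alpha_pi",
             if (K > 1) nm_reg("beta_pi", regions[-1]),
             "beta_pi_sex",
             if (hf$use) "beta_pi_hf",
             "pr_intercept", "pr_sex", "rho_intercept", "rho_sex")
  omega_names <- lapply(c("omega_phi", "omega_pi", "omega_pr", "omega_rho"),
                        function(b) sprintf("%s[%s]", b, st$station_id))
  names(omega_names) <- c("phi", "pi", "pr", "rho")
  sig_names <- sprintf("sigma2_%s", names(omega_names))
  all_names <- c(fixed, unlist(omega_names), sig_names)
  ix <- function(nm) nm  # name-based: indices stay valid after components concatenate
  i <- list(mu = ix("mu_phi"),
            bphi_reg = if (K > 1) ix(nm_reg("beta_phi", regions[-1])) else integer(0),
            bphi_sex = ix("beta_phi_sex"),
            bphi_hf = if (hf$use) ix("beta_phi_hf") else NA_integer_,
            trend = ix(nm_reg("trend_phi", regions)),
            alpha_pi = ix("alpha_pi"),
            bpi_reg = if (K > 1) ix(nm_reg("beta_pi", regions[-1])) else integer(0),
            bpi_sex = ix("beta_pi_sex"),
            bpi_hf = if (hf$use) ix("beta_pi_hf") else NA_integer_,
            pr = ix(c("pr_intercept", "pr_sex")),
            rho = ix(c("rho_intercept", "rho_sex")),
            omega = lapply(omega_names, ix),
            sig = ix(sig_names),
            fixed = ix(fixed))
  tc <- (seq_len(Tn) - 1) - t_mid
  first <- as.integer(fl[, 1]); last <- as.integer(fl[, 2])
  pred <- as.integer(captures$predetermined)
  ll_by_station <- function(theta) {
    cjs_loglik_by_station(y, first, last, pred, sex,
                          as.integer(s_idx), as.integer(k_st), hf_z, tc,
                          theta[i$mu],
                          c(0, theta[i$bphi_reg]),
                          theta[i$bphi_sex],
                          if (hf$use) theta[i$bphi_hf] else 0,
                          theta[i$trend],
                          theta[i$alpha_pi],
                          c(0, theta[i$bpi_reg]),
                          theta[i$bpi_sex],
                          if (hf$use) theta[i$bpi_hf] else 0,
                          theta[i$pr[1]], theta[i$pr[2]],
                          theta[i$rho[1]], theta[i$rho[2]],
                          theta[i$omega$phi], theta[i$omega$pi],
                          theta[i$omega$pr], theta[i$omega$rho], S)
  }
  blocks <- list(
    block_rw(fixed, function(theta) {
      sum(ll_by_station(theta)) +
        sum(dnorm(theta[i$fixed], 0, PRIOR_COEF_SD, log = TRUE))
    }, scale = 0.2))
  for (f in names(omega_names)) {
    local({
      f_ <- f
      io <- i$omega[[f_]]
      is2 <- i$sig[match(f_, names(omega_names))]
      blocks[[length(blocks) + 1]] <<- block_rw_vec(
        omega_names[[f_]],
        function(theta) {
          ll_by_station(theta) +
            dnorm(theta[io], 0, sqrt(theta[is2]), log = TRUE)
        }, scale = 0.3)
      blocks[[length(blocks) + 1]] <<- block_gibbs(
        sig_names[match(f_, names(omega_names))],
        function(theta) .ig_gibbs(theta[io]))
    })
  }
  init <- function() {
    v <- stats::setNames(numeric(length(all_names)), all_names)
    v[i$fixed] <- rnorm(length(i$fixed))
    v[i$sig] <- 1
    v
  }
  list(names = all_names, blocks = blocks, init = init,
       meta = list(regions = regions, stations = st, hf_z = hf_z,
                   n_years = Tn, t_mid = t_mid, n_individuals = nrow(captures),
                   hf_scaling = hf[c("mean", "sd")]))
}

# ---- abundance (Poisson log-linear) ------------------------------------

.abundance_component <- function(counts, stations, config) {
  keep <- filter_abundance_stations(counts)
  counts <- counts[counts$station_id %in% keep, , drop = FALSE]
  if (nrow(counts) == 0) .stopf("no count data after filtering")
  hf <- .hf_z_all(stations, config)
  st <- stations[stations$station_id %in% keep, , drop = FALSE]
  hf_z <- hf$z[stations$station_id %in% keep]
  first_year <- min(counts$year)
  n_years <- max(counts$year) - first_year + 1
  t_mid <- (n_years - 1) / 2
  ef_mean <- mean(counts$effort); ef_sd <- stats::sd(counts$effort)
  if (!is.finite(ef_sd) || ef_sd == 0) .stopf("effort has zero variance")
  regions <- REGION_LEVELS[REGION_LEVELS %in% unique(st$region)]
  k_st <- match(st$region, regions)
  s_idx <- match(as.character(counts$station_id), st$station_id)
  K <- length(regions); S <- nrow(st); n <- nrow(counts)
  kk <- k_st[s_idx]
  t_c <- (counts$year - first_year) - t_mid
  ef_z <- (counts$effort - ef_mean) / ef_sd
  hfo <- hf_z[s_idx]
  C <- counts$adult_count
  nm_reg <- function(base, r) sprintf("%s[%s]", base, r)
  fixed <- c(nm_reg("alpha_lambda", regions), nm_reg("beta_trend", regions),
             if (hf$use) "beta_hf", "beta_effort")
  omega_nm <- sprintf("omega_lam[%s]", st$station_id)
  eps_nm <- sprintf("eps[%d]", seq_len(n))
  all_names <- c(fixed, omega_nm, eps_nm, "sigma2_station", "sigma2_noise")
  ix <- function(nm) nm  # name-based: indices stay valid after components concatenate
  i <- list(alpha = ix(nm_reg("alpha_lambda", regions)),
            trend = ix(nm_reg("beta_trend", regions)),
            hf = if (hf$use) ix("beta_hf") else NA_integer_,
            ef = ix("beta_effort"),
            omega = ix(omega_nm), eps = ix(eps_nm),
            s2_st = ix("sigma2_station"), s2_no = ix("sigma2_noise"),
            fixed = ix(fixed))
  obs_by_station <- split(seq_len(n), s_idx)
  stopifnot(length(obs_by_station) == S)
  ll_by_obs <- function(theta) {
    eta <- theta[i$alpha][kk] + theta[i$trend][kk] * t_c +
      (if (hf$use) theta[i$hf] else 0) * hfo + theta[i$ef] * ef_z +
      theta[i$omega][s_idx] + theta[i$eps]
    dpois(C, exp(.clamp(eta, 300)), log = TRUE)
  }
  blocks <- list(
    block_rw(fixed, function(theta) {
      sum(ll_by_obs(theta)) +
        sum(dnorm(theta[i$fixed], 0, PRIOR_COEF_SD, log = TRUE))
    }, scale = 0.1),
    block_rw_vec(omega_nm, function(theta) {
      ll <- ll_by_obs(theta)
      vapply(obs_by_station, function(jj) sum(ll[jj]), 0) +
        dnorm(theta[i$omega], 0, sqrt(theta[i$s2_st]), log = TRUE)
    }, scale = 0.2),
    block_rw_vec(eps_nm, function(theta) {
      ll_by_obs(theta) + dnorm(theta[i$eps], 0, sqrt(theta[i$s2_no]), log = TRUE)
    }, scale = 0.3),
    block_gibbs("sigma2_station", function(theta) .ig_gibbs(theta[i$omega])),
    block_gibbs("sigma2_noise", function(theta) .ig_gibbs(theta[i$eps])))
  init <- function() {
    v <- stats::setNames(numeric(length(all_names)), all_names)
    v[i$fixed] <- rnorm(length(i$fixed))
    v[i$alpha] <- log(pmax(mean(C), 0.5)) + rnorm(K, 0, 0.2)
    v[c(i$s2_st, i$s2_no)] <- 1
    v
  }
  list(names = all_names, blocks = blocks, init = init,
       meta = list(regions = regions, stations = st, hf_z = hf_z,
                   first_year = first_year, n_years = n_years, t_mid = t_mid,
                   effort_scaling = list(mean = ef_mean, sd = ef_sd),
                   hf_scaling = hf[c("mean", "sd")]))
}

# ---- productivity (binomial) -------------------------------------------

.productivity_component <- function(productivity, stations, config,
                                    first_year = NULL, n_years = NULL) {
  keep <- filter_productivity_stations(productivity)
  prod <- productivity[productivity$station_id %in% keep &
                         productivity$total >= 1, , drop = FALSE]
  if (nrow(prod) == 0) .stopf("no productivity data after filtering")
  hf <- .hf_z_all(stations, config)
  st <- stations[stations$station_id %in% keep, , drop = FALSE]
  hf_z <- hf$z[stations$station_id %in% keep]
  if (is.null(first_year)) first_year <- min(prod$year)
  if (is.null(n_years)) n_years <- max(prod$year) - first_year + 1
  t_mid <- (n_years - 1) / 2
  regions <- REGION_LEVELS[REGION_LEVELS %in% unique(st$region)]
  k_st <- match(st$region, regions)
  s_idx <- match(as.character(prod$station_id), st$station_id)
  K <- length(regions); S <- nrow(st); n <- nrow(prod)
  kk <- k_st[s_idx]
  t_c <- (prod$year - first_year) - t_mid
  hfo <- hf_z[s_idx]
  J <- prod$juveniles; N <- prod$total
  if (any(J > N)) .stopf("juveniles exceed total captures")
  nm_reg <- function(base, r) sprintf("%s[%s]", base, r)
  fixed <- c(nm_reg("alpha_p", regions), nm_reg("trend_p", regions),
             if (hf$use) "beta_p_hf")
  omega_nm <- sprintf("omega_p[%s]", st$station_id)
  all_names <- c(fixed, omega_nm, "sigma2_p")
  ix <- function(nm) nm  # name-based: indices stay valid after components concatenate
  i <- list(alpha = ix(nm_reg("alpha_p", regions)),
            trend = ix(nm_reg("trend_p", regions)),
            hf = if (hf$use) ix("beta_p_hf") else NA_integer_,
            omega = ix(omega_nm), s2 = ix("sigma2_p"), fixed = ix(fixed))
  obs_by_station <- split(seq_len(n), s_idx)
  ll_by_obs <- function(theta) {
    lp <- theta[i$alpha][kk] + theta[i$trend][kk] * t_c +
      (if (hf$use) theta[i$hf] else 0) * hfo + theta[i$omega][s_idx]
    dbinom(J, N, invlogit(.clamp(lp)), log = TRUE)
  }
  blocks <- list(
    block_rw(fixed, function(theta) {
      sum(ll_by_obs(theta)) +
        sum(dnorm(theta[i$fixed], 0, PRIOR_COEF_SD, log = TRUE))
    }, scale = 0.1),
    block_rw_vec(omega_nm, function(theta) {
      ll <- ll_by_obs(theta)
      vapply(obs_by_station, function(jj) sum(ll[jj]), 0) +
        dnorm(theta[i$omega], 0, sqrt(theta[i$s2]), log = TRUE)
    }, scale = 0.2),
    block_gibbs("sigma2_p", function(theta) .ig_gibbs(theta[i$omega])))
  init <- function() {
    v <- stats::setNames(numeric(length(all_names)), all_names)
    v[i$fixed] <- rnorm(length(i$fixed))
    v[i$s2] <- 1
    v
  }
  list(names = all_names, blocks = blocks, init = init,
       meta = list(regions = regions, stations = st, hf_z = hf_z,
                   first_year = first_year, n_years = n_years, t_mid = t_mid,
                   hf_scaling = hf[c("mean", "sd")]))
}

.assemble_fit <- function(components, mcmc) {
  all_names <- unlist(lapply(components, `[[`, "names"))
  if (anyDuplicated(all_names)) .stopf("duplicate parameter names across components")
  init <- function() {
    do.call(c, unname(lapply(components, function(cp) cp$init())))
  }
  blocks <- do.call(c, unname(lapply(components, `[[`, "blocks")))
  fit <- sample_posterior(mcmc_model(init, blocks), mcmc)
  attr(fit, "meta") <- lapply(components, `[[`, "meta")
  fit
}

#' Fit the demographic models
#'
#' `fit_survival()` fits the hierarchical transient-CJS model to capture
#' histories; `fit_abundance()` fits the Poisson log-linear count model;
#' `fit_joint()` fits both in a single sampler run so that the joint
#' posterior supports derived recruitment; `fit_productivity()` fits the
#' binomial juvenile-proportion model separately.
#'
#' Station filtering (at least one capture for abundance, no juvenile-only
#' stations for productivity, at least `min_marked_individuals` for
#' survival), footprint-scale selection and covariate standardization all
#' follow the supplied [analysis_config()]; footprint is z-scored across
#' the full supplied station table, effort across the analysed
#' station-years, and the year covariate is centered at the study midpoint.
#' Individuals of unknown sex are excluded from the survival component with
#' a message.
#'
#' @param counts count table (`station_id`, `year`, `adult_count`,
#'   `effort`).
#' @param captures capture-history table (`station_id`, `sex`,
#'   `detections`, `predetermined`).
#' @param productivity productivity table (`station_id`, `year`,
#'   `juveniles`, `total`).
#' @param stations station table (`station_id`, `region`, footprint
#'   columns).
#' @param config an [analysis_config()].
#' @param mcmc an [mcmc_config()].
#' @return a `posterior_chains` object carrying a `meta` attribute with the
#'   station tables, regions and scaling constants used.
#' @export
fit_joint <- function(counts, captures, stations, config = analysis_config(),
                      mcmc = mcmc_preset("reduced")) {
  .assemble_fit(list(abundance = .abundance_component(counts, stations, config),
                     survival = .survival_component(captures, stations, config)),
                mcmc)
}

#' @rdname fit_joint
#' @export
fit_abundance <- function(counts, stations, config = analysis_config(),
                          mcmc = mcmc_preset("reduced")) {
  .assemble_fit(list(abundance = .abundance_component(counts, stations, config)),
                mcmc)
}

#' @rdname fit_joint
#' @export
fit_survival <- function(captures, stations, config = analysis_config(),
                         mcmc = mcmc_preset("reduced")) {
  .assemble_fit(list(survival = .survival_component(captures, stations, config)),
                mcmc)
}

#' @rdname fit_joint
#' @export
fit_productivity <- function(productivity, stations, config = analysis_config(),
                             mcmc = mcmc_preset("reduced")) {
  .assemble_fit(list(productivity = .productivity_component(productivity,
                                                            stations, config)),
                mcmc)
}
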