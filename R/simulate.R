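#' Simulate a constant-effort banding network
#'
#' `simulate_stations()` lays out the network: station ids, regions with
#' consistent coordinates, human-footprint values for the two raster epochs
#' at both radii (clipped to the 0-50 index scale), a contiguous block of
#' active years per station, and per-year mist-netting effort. The per-epoch
#' 10 km values are generated correlated with the 1 km values, mirroring the
#' strong collinearity seen between the two radii in real networks.
#'
#' @param scenario a [simulation_scenario()].
#' @param seed integer seed; defaults to the scenario seed.
#' @return data.frame with one row per station (`station_id`, `region`,
#'   `longitude`, `latitude`, raw epoch footprints, assigned `hf_1km` /
#'   `hf_10km`, `active_years` list-column, `effort_by_year` list-column),
#'   with the calendar `years` attribute attached.
#' @export
simulate_stations <- function(scenario, seed = scenario$seed) {
  if (scenario$n_years < 2) .stopf("n_years must be >= 2")
  set.seed(seed)
  years <- scenario$first_year + seq_len(scenario$n_years) - 1L
  boxes <- list(west = c(-120, -103, 48, 58),
                central = c(-101.5, -90.5, 47.5, 52),
                east = c(-75, -62, 43, 46.9))
  rows <- list()
  for (k in seq_along(REGION_LEVELS)) {
    reg <- REGION_LEVELS[k]
    n <- scenario$n_stations[[reg]]
    if (n == 0) next
    b <- boxes[[reg]]
    hf93_1 <- pmin(pmax(rnorm(n, scenario$hf_mean[[reg]], scenario$hf_sd[[reg]]), 0), 50)
    hf09_1 <- pmin(pmax(hf93_1 + scenario$hf_change[[reg]] +
                          rnorm(n, 0, scenario$hf_sd[[reg]] / 4), 0), 50)
    hf93_10 <- pmin(pmax(0.8 * hf93_1 + 0.2 * scenario$hf_mean[[reg]] +
                           rnorm(n, 0, scenario$hf_sd[[reg]] / 2), 0), 50)
    hf09_10 <- pmin(pmax(hf93_10 + scenario$hf_change[[reg]] +
                           rnorm(n, 0, scenario$hf_sd[[reg]] / 4), 0), 50)
    if (scenario$mean_active_years >= scenario$n_years) {
      # stations operate throughout the study
      start <- rep(1L, n)
      dur <- rep(scenario$n_years, n)
    } else {
      start <- sample.int(max(scenario$n_years - 1L, 1L), n, replace = TRUE)
      dur <- 2L + rpois(n, max(scenario$mean_active_years - 2, 0))
    }
    rows[[reg]] <- data.frame(
      station_id = sprintf("%s%02d", toupper(substr(reg, 1, 1)), seq_len(n)),
      region = reg,
      longitude = runif(n, b[1], b[2]),
      latitude = runif(n, b[3], b[4]),
      hf_1993_1km = hf93_1, hf_2009_1km = hf09_1,
      hf_1993_10km = hf93_10, hf_2009_10km = hf09_10,
      start = start, dur = dur)
  }
  st <- do.call(rbind, rows)
  if (is.null(st)) .stopf("scenario has no stations")
  rownames(st) <- NULL
  st$active_years <- lapply(seq_len(nrow(st)), function(i) {
    years[seq(st$start[i], min(st$start[i] + st$dur[i] - 1L, scenario$n_years))]
  })
  st$start <- NULL
  st$dur <- NULL
  st$hf_1km <- vapply(seq_len(nrow(st)), function(i) {
    assign_footprint_value(st$active_years[[i]], st$hf_1993_1km[i],
                           st$hf_2009_1km[i], st$station_id[i])
  }, 0)
  st$hf_10km <- vapply(seq_len(nrow(st)), function(i) {
    assign_footprint_value(st$active_years[[i]], st$hf_1993_10km[i],
                           st$hf_2009_10km[i], st$station_id[i])
  }, 0)
  st$effort_by_year <- lapply(seq_len(nrow(st)), function(i) {
    ey <- rnorm(length(st$active_years[[i]]), scenario$effort_mean,
                scenario$effort_sd)
    stats::setNames(pmax(ey, 0.1 * scenario$effort_mean), st$active_years[[i]])
  })
  attr(st, "years") <- years
  st
}

# flat station-year table (station row index, calendar year, effort)
.station_years <- function(stations) {
  n <- vapply(stations$active_years, length, 0L)
  data.frame(s = rep(seq_len(nrow(stations)), n),
             station_id = rep(stations$station_id, n),
             year = unlist(stations$active_years),
             effort = unname(unlist(stations$effort_by_year)))
}

# standardized covariates for generation, matching standardize_covariates()
.generator_covariates <- function(stations, scenario, hf_scale = "1km") {
  sy <- .station_years(stations)
  sc <- .covariate_scaling(stations, sy$effort, scenario$first_year,
                           scenario$n_years)
  hfcol <- paste0("hf_", hf_scale)
  list(sy = sy, scaling = sc,
       hf_z = (stations[[hfcol]] - sc[[paste0(hfcol, "_mean")]]) /
         sc[[paste0(hfcol, "_sd")]],
       t_c = (sy$year - scenario$first_year) - sc$t_mid,
       effort_z = (sy$effort - sc$effort_mean) / sc$effort_sd,
       region = .region_index(stations$region))
}

#' Simulate adult counts, productivity and capture histories
#'
#' `simulate_counts()` draws, for every active station-year, an adult count
#' from a Poisson whose log mean is the abundance linear predictor (region
#' intercept + region trend + footprint + effort + station effect +
#' observation-level lognormal noise). Inactive station-years produce no
#' record. `simulate_productivity()` draws juvenile counts from a binomial
#' with the logit-linear productivity predictor, given total captures
#' (supplied, or drawn Poisson at the scenario rate).
#' `simulate_capture_histories()` draws newly banded adults per
#' station-year, assigns sex, residency (probability `pi`), a
#' pre-determination flag for residents only (probability `rho`), and then
#' annual survival (`phi`, with any regional trend) and recapture (`pr`)
#' for residents; transients are never seen after their first year.
#' Station random effects in the parameter objects that are `NULL` are
#' treated as exactly zero; [simulate_banding_data()] draws them.
#'
#' @param stations station table from [simulate_stations()].
#' @param params the matching parameter object ([abundance_params()],
#'   [productivity_params()] or [survival_params()]).
#' @param scenario the [simulation_scenario()] (study span and rates).
#' @param totals optional data.frame (`station_id`, `year`, `total`) of
#'   total captures for the productivity draw.
#' @param seed integer seed.
#' @return data.frames: counts (`station_id`, `year`, `adult_count`,
#'   `effort`), productivity (`station_id`, `year`, `juveniles`, `total`),
#'   capture histories (`individual_id`, `station_id`, `sex` 0 = female /
#'   1 = male, `first_year`, `detections` 0/1 string over the full study,
#'   `predetermined`).
#' @export
simulate_counts <- function(stations, params, scenario,
                            seed = scenario$seed) {
  stopifnot(inherits(params, "abundance_params"))
  set.seed(seed)
  cov <- .generator_covariates(stations, scenario)
  sy <- cov$sy
  k <- cov$region[sy$s]
  eta <- params$alpha_lambda[k] + params$beta_trend[k] * cov$t_c +
    params$beta_hf * cov$hf_z[sy$s] + params$beta_effort * cov$effort_z +
    .omega(params$omega_lambda, sy$s) +
    rnorm(nrow(sy), 0, params$sigma_noise)
  data.frame(station_id = sy$station_id, year = sy$year,
             adult_count = rpois(nrow(sy), exp(.clamp(eta))),
             effort = sy$effort)
}

#' @rdname simulate_counts
#' @export
simulate_productivity <- function(stations, params, scenario, totals = NULL,
                                  seed = scenario$seed) {
  stopifnot(inherits(params, "productivity_params"))
  set.seed(seed)
  cov <- .generator_covariates(stations, scenario)
  sy <- cov$sy
  if (is.null(totals)) {
    sy$total <- rpois(nrow(sy), scenario$captures_per_station_year)
  } else {
    m <- match(paste(sy$station_id, sy$year),
               paste(totals$station_id, totals$year))
    sy$total <- ifelse(is.na(m), 0L, totals$total[m])
  }
  if (any(sy$total < 0)) .stopf("total captures must be >= 0")
  k <- cov$region[sy$s]
  lp <- params$alpha_p[k] + params$beta_p_trend[k] * cov$t_c +
    params$beta_p_hf * cov$hf_z[sy$s] + .omega(params$omega_p, sy$s)
  sy$juveniles <- rbinom(nrow(sy), sy$total, invlogit(lp))
  keep <- if (is.null(totals)) sy$total > 0 else rep(TRUE, nrow(sy))
  out <- sy[keep, c("station_id", "year", "juveniles", "total")]
  rownames(out) <- NULL
  out
}

#' @rdname simulate_counts
#' @export
simulate_capture_histories <- function(stations, params, scenario,
                                       seed = scenario$seed) {
  stopifnot(inherits(params, "survival_params"))
  if (scenario$n_years < 2) .stopf("n_years must be >= 2")
  set.seed(seed)
  cov <- .generator_covariates(stations, scenario)
  sy <- cov$sy
  n_new <- rpois(nrow(sy), scenario$new_per_station_year)
  s <- rep(sy$s, n_new)
  entry <- rep(sy$year, n_new) - scenario$first_year + 1L  # occasion index
  n <- length(s)
  if (n == 0) {
    return(data.frame(individual_id = character(), station_id = character(),
                      sex = integer(), first_year = integer(),
                      detections = character(), predetermined = integer()))
  }
  Tn <- scenario$n_years
  k <- cov$region[s]
  sex <- rbinom(n, 1, scenario$sex_ratio)
  hf <- cov$hf_z[s]
  pi_i <- invlogit(params$alpha_pi + params$beta_pi_region[k] +
                     params$beta_pi_sex * sex + params$beta_pi_hf * hf +
                     .omega(params$omega_pi, s))
  pr_i <- invlogit(params$pr_intercept + params$pr_sex * sex +
                     .omega(params$omega_pr, s))
  rho_i <- invlogit(params$rho_intercept + params$rho_sex * sex +
                      .omega(params$omega_rho, s))
  resident <- rbinom(n, 1, pi_i) == 1
  predet <- integer(n)
  predet[resident] <- rbinom(sum(resident), 1, rho_i[resident])
  phi_base <- params$mu_phi + params$beta_phi_region[k] +
    params$beta_phi_sex * sex + params$beta_phi_hf * hf +
    .omega(params$omega_phi, s)
  t_mid <- cov$scaling$t_mid
  det <- matrix(0L, n, Tn)
  det[cbind(seq_len(n), entry)] <- 1L
  alive <- resident
  for (t in seq_len(Tn - 1)) {
    at_risk <- alive & entry <= t
    phi_t <- invlogit(phi_base + params$beta_phi_trend[k] * (t - 1 - t_mid))
    surv <- at_risk & (rbinom(n, 1, phi_t) == 1)
    alive[at_risk] <- surv[at_risk]
    redet <- surv & (rbinom(n, 1, pr_i) == 1)
    det[cbind(which(redet), rep(t + 1L, sum(redet)))] <- 1L
  }
  data.frame(individual_id = sprintf("ind%05d", seq_len(n)),
             station_id = stations$station_id[s],
             sex = sex,
             first_year = scenario$first_year + entry - 1L,
             detections = apply(det, 1, paste, collapse = ""),
             predetermined = predet)
}

#' Simulate a complete ground-truth-labelled banding dataset
#'
#' Runs the full generator: station layout, station random effects for all
#' four sub-models (drawn from their true SDs), adult counts, productivity
#' and capture histories — all from one seed, bit-reproducibly. The
#' returned `truth` element records every true parameter (including the
#' realized station effects), the covariate-scaling constants and the seed;
#' [write_banding_data()] serializes it as a JSON sidecar.
#'
#' @param scenario a [simulation_scenario()].
#' @return a `banding_data` list with elements `stations`, `counts`,
#'   `productivity`, `captures`, `truth`.
#' @export
simulate_banding_data <- function(scenario) {
  set.seed(scenario$seed)
  seeds <- sample.int(2^31 - 2, 5)
  stations <- simulate_stations(scenario, seed = seeds[1])
  S <- nrow(stations)
  set.seed(seeds[2])
  ab <- scenario$abundance
  if (is.null(ab$omega_lambda)) ab$omega_lambda <- rnorm(S, 0, ab$sigma_station)
  pd <- scenario$productivity
  if (is.null(pd$omega_p)) pd$omega_p <- rnorm(S, 0, pd$sigma_p)
  sv <- scenario$survival
  for (f in c("phi", "pi", "pr", "rho")) {
    of <- paste0("omega_", f)
    if (is.null(sv[[of]])) sv[[of]] <- rnorm(S, 0, sv[[paste0("sigma_", f)]])
  }
  counts <- simulate_counts(stations, ab, scenario, seed = seeds[3])
  productivity <- simulate_productivity(stations, pd, scenario, seed = seeds[4])
  captures <- simulate_capture_histories(stations, sv, scenario, seed = seeds[5])
  scaling <- .covariate_scaling(stations, counts$effort, scenario$first_year,
                                scenario$n_years)
  truth <- list(seed = scenario$seed,
                n_stations = as.list(scenario$n_stations),
                n_years = scenario$n_years,
                first_year = scenario$first_year,
                abundance = unclass(ab), productivity = unclass(pd),
                survival = unclass(sv), scaling = scaling)
  structure(list(stations = stations, counts = counts,
                 productivity = productivity, captures = captures,
                 truth = truth),
            class = "banding_data")
}
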