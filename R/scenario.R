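#' Simulation scenario for a constant-effort banding network
#'
#' Bundles everything the synthetic-data generator needs: network layout,
#' study length, entry rates, the true parameters of the abundance,
#' productivity and survival models, covariate distributions and the seed.
#' The defaults emulate the network the models were designed for: 59
#' stations split (23, 3, 33) across west/central/east regions, 24 annual
#' occasions, a few newly banded adults per station-year, footprint on the
#' 0-50 human-footprint index scale (higher and more variable in west/east
#' than central), and effort near 480 net-hours per station-year (6-9
#' operating days of a 6-h, ~10-net protocol).
#'
#' @param n_stations integer vector of stations per region, named or in
#'   `(west, central, east)` order; regions with 0 stations are absent.
#' @param n_years number of annual occasions (>= 2).
#' @param new_per_station_year Poisson rate of newly captured adults per
#'   station-year entering the mark-recapture data.
#' @param captures_per_station_year Poisson rate of total (adult + juvenile)
#'   captures per station-year for the productivity table.
#' @param abundance,productivity,survival true parameter sets; see
#'   [abundance_params()].
#' @param hf_mean,hf_sd per-region mean and SD of the 1993 human-footprint
#'   index at the 1 km scale (values clipped to `[0, 50]`).
#' @param hf_change per-region additive change 1993 -> 2009.
#' @param effort_mean,effort_sd net-hours per station-year (truncated > 0).
#' @param mean_active_years average number of active years per station;
#'   stations operate a contiguous block of at least 2 years. A value
#'   greater than or equal to `n_years` makes every station operate for the
#'   whole study.
#' @param sex_ratio probability a new individual is male.
#' @param first_year calendar year of occasion 1.
#' @param seed integer seed; fully determines every generated dataset.
#' @return a list with class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(n_stations = c(west = 23, central = 3, east = 33),
                                n_years = 24,
                                new_per_station_year = 2.5,
                                captures_per_station_year = 5,
                                abundance = abundance_params(),
                                productivity = productivity_params(),
                                survival = survival_params(),
                                hf_mean = c(west = 11, central = 3.3, east = 9.7),
                                hf_sd = c(west = 5, central = 1.5, east = 5),
                                hf_change = c(west = 3.7, central = 0.2, east = 0.4),
                                effort_mean = 480, effort_sd = 80,
                                mean_active_years = 8,
                                sex_ratio = 0.5,
                                first_year = 1993,
                                seed = 1L) {
  if (length(n_stations) != 3) .stopf("n_stations must give (west, central, east)")
  if (is.null(names(n_stations))) names(n_stations) <- REGION_LEVELS
  n_stations <- n_stations[REGION_LEVELS]
  if (any(n_stations < 0) || any(n_stations != round(n_stations))) {
    .stopf("n_stations must be non-negative integers")
  }
  if (!is.numeric(n_years) || n_years < 2) .stopf("n_years must be >= 2")
  stopifnot(new_per_station_year >= 0, captures_per_station_year >= 0,
            sex_ratio >= 0, sex_ratio <= 1, effort_mean > 0,
            mean_active_years >= 2)
  stopifnot(inherits(abundance, "abundance_params"),
            inherits(productivity, "productivity_params"),
            inherits(survival, "survival_params"))
  structure(list(n_stations = n_stations, n_years = as.integer(n_years),
                 new_per_station_year = new_per_station_year,
                 captures_per_station_year = captures_per_station_year,
                 abundance = abundance, productivity = productivity,
                 survival = survival,
                 hf_mean = hf_mean, hf_sd = hf_sd, hf_change = hf_change,
                 effort_mean = effort_mean, effort_sd = effort_sd,
                 mean_active_years = mean_active_years,
                 sex_ratio = sex_ratio,
                 first_year = as.integer(first_year),
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}
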