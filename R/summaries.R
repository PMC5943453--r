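#' Regional abundance index per posterior draw
#'
#' The region-level index of breeding density is the station sum of
#' expected adult counts at mean effort with the observation-level noise
#' set to zero:
#' `N[k, t] = sum_s exp(alpha_lambda[k] + beta_trend[k] t_c + beta_hf hf_z_s
#' + omega_s)` over the region's analysed stations. An intercept-only
#' variant (`per_station = TRUE`) returns the per-station average instead
#' of the sum.
#'
#' @param fit a fit containing the abundance component ([fit_joint()] or
#'   [fit_abundance()]).
#' @param region region label.
#' @param per_station average over stations instead of summing.
#' @return matrix of draws x years; column names are calendar years.
#' @export
regional_index <- function(fit, region, per_station = FALSE) {
  meta <- attr(fit, "meta")$abundance
  if (is.null(meta)) .stopf("fit has no abundance component")
  st <- meta$stations
  sel <- which(st$region == region)
  if (length(sel) == 0) .stopf("no analysed stations in region '%s'", region)
  draws <- pooled_draws(fit)
  alpha <- draws[, sprintf("alpha_lambda[%s]", region)]
  trend <- draws[, sprintf("beta_trend[%s]", region)]
  bhf <- if ("beta_hf" %in% colnames(draws)) draws[, "beta_hf"] else 0
  om <- draws[, sprintf("omega_lam[%s]", st$station_id[sel]), drop = FALSE]
  t_c <- (seq_len(meta$n_years) - 1) - meta$t_mid
  hf <- meta$hf_z[sel]
  Nkt <- matrix(0, nrow(draws), meta$n_years)
  for (j in seq_along(sel)) {
    Nkt <- Nkt + exp(outer(alpha + bhf * hf[j] + om[, j], rep(1, meta$n_years)) +
                       outer(trend, t_c))
  }
  if (per_station) Nkt <- Nkt / length(sel)
  colnames(Nkt) <- meta$first_year + seq_len(meta$n_years) - 1
  Nkt
}

#' Regional survival per posterior draw
#'
#' Apparent survival at mean covariates and zero station effect, averaged
#' with equal weight over the two sexes, for each survival interval
#' (year t to t + 1).
#'
#' @param fit a fit containing the survival component.
#' @param region region label.
#' @return matrix of draws x (T - 1) intervals.
#' @export
region_survival <- function(fit, region) {
  meta <- attr(fit, "meta")$survival
  if (is.null(meta)) .stopf("fit has no survival component")
  if (!region %in% meta$regions) .stopf("region '%s' not in survival fit", region)
  draws <- pooled_draws(fit)
  off_nm <- sprintf("beta_phi[%s]", region)
  off <- if (off_nm %in% colnames(draws)) draws[, off_nm] else 0
  trend <- draws[, sprintf("trend_phi[%s]", region)]
  base <- draws[, "mu_phi"] + off
  bsex <- draws[, "beta_phi_sex"]
  t_c <- (seq_len(meta$n_years - 1) - 1) - meta$t_mid
  phi <- matrix(0, nrow(draws), length(t_c))
  for (t in seq_along(t_c)) {
    phi[, t] <- (invlogit(base + trend * t_c[t]) +
                   invlogit(base + bsex + trend * t_c[t])) / 2
  }
  phi
}

#' Derived recruitment from the joint posterior
#'
#' Applies the identity `rec[k, t+1] = N[k, t+1] - N[k, t] * phi[k, t]`
#' draw by draw: new recruits are next year's regional index minus the
#' survivors of this year's. Values can be negative in draws where the
#' index falls faster than survival alone allows; they are retained in the
#' series (and excluded, with a count, from the log-linear trend fit).
#'
#' @param N draws x years matrix from [regional_index()].
#' @param phi draws x intervals matrix from [region_survival()] (at least
#'   `ncol(N) - 1` columns, same draw count).
#' @return object of class `"recruitment_series"` with elements `rec`
#'   (draws x (years - 1)), `N` and `phi`.
#' @export
recruitment_series <- function(N, phi) {
  Tn <- ncol(N)
  if (nrow(N) != nrow(phi)) .stopf("N and phi have different draw counts")
  if (ncol(phi) < Tn - 1) .stopf("phi needs at least ncol(N) - 1 columns")
  rec <- N[, 2:Tn, drop = FALSE] -
    N[, 1:(Tn - 1), drop = FALSE] * phi[, 1:(Tn - 1), drop = FALSE]
  colnames(rec) <- colnames(N)[-1]
  structure(list(rec = rec, N = N, phi = phi), class = "recruitment_series")
}

#' Per-draw log-linear recruitment trend
#'
#' For each posterior draw, the least-squares slope of `log(rec)` on year
#' over the years where recruitment is positive. Draws with fewer than
#' `min_positive` positive years are excluded and counted.
#'
#' @param series a [recruitment_series()].
#' @param min_positive minimum positive years per draw (default 3).
#' @return list with `slopes` (per retained draw), `n_excluded`, and
#'   `summary` (a [trend_summary()] row when enough draws remain).
#' @export
recruitment_trend <- function(series, min_positive = 3) {
  stopifnot(inherits(series, "recruitment_series"))
  rec <- series$rec
  if (ncol(rec) < min_positive) .stopf("need at least %d years", min_positive)
  yr <- seq_len(ncol(rec))
  slopes <- apply(rec, 1, function(r) {
    ok <- r > 0
    if (sum(ok) < min_positive) return(NA_real_)
    x <- yr[ok]; ylog <- log(r[ok])
    sum((x - mean(x)) * (ylog - mean(ylog))) / sum((x - mean(x))^2)
  })
  n_excluded <- sum(is.na(slopes))
  slopes <- slopes[!is.na(slopes)]
  if (length(slopes) == 0) .stopf("all draws excluded from recruitment trend")
  list(slopes = slopes, n_excluded = n_excluded,
       summary = if (length(slopes) >= 100)
         trend_summary(slopes, "recruitment") else NULL)
}

#' Percent-per-year conversion of a log-linear trend coefficient
#'
#' @param coefficient trend on the natural-log (or logit-linear) per-year
#'   scale.
#' @return `100 * (exp(coefficient) - 1)`.
#' @export
percent_per_year <- function(coefficient) 100 * (exp(coefficient) - 1)

#' Summarize a posterior trend coefficient
#'
#' @param draws posterior draws of the coefficient (per year).
#' @param parameter label.
#' @param mass HPD mass (default 0.90).
#' @return one-row data.frame: posterior mean, HPD bounds, percent per year
#'   (`100 (exp(mean) - 1)`), and the posterior mass below zero.
#' @export
trend_summary <- function(draws, parameter = "trend", mass = 0.90) {
  hpd <- hpd_interval(draws, mass)
  data.frame(parameter = parameter, mean = mean(draws),
             hpd_lower = hpd[1], hpd_upper = hpd[2],
             percent_per_year = percent_per_year(mean(draws)),
             prob_decline = prob_mass_below_zero(draws),
             row.names = NULL)
}

#' Assemble the reporting tables
#'
#' Builds, from whichever fitted components are supplied: (a) mean apparent
#' survival and residency by region and sex with 90% HPD intervals, (b) the
#' footprint covariate effects with the posterior mass below zero, and (c)
#' per-region trend summaries for density, productivity, survival and
#' derived recruitment (coefficient, percent per year, 90% HPD,
#' Pr(decline)). Missing components leave their sections `NULL` and are
#' listed in `$gaps`. The report is a pure function of the chains:
#' regenerating it from the same fits gives identical tables.
#'
#' @param joint fit from [fit_joint()] (or [fit_abundance()] /
#'   [fit_survival()] for partial reports).
#' @param productivity fit from [fit_productivity()], optional.
#' @param mass credible mass for intervals.
#' @return list of data.frames with class `"demography_report"`.
#' @export
make_report <- function(joint = NULL, productivity = NULL, mass = 0.90) {
  gaps <- character(0)
  surv_tab <- cov_tab <- trend_tab <- NULL
  meta <- if (!is.null(joint)) attr(joint, "meta") else NULL
  cov_rows <- list()
  trend_rows <- list()
  if (!is.null(meta$survival)) {
    draws <- pooled_draws(joint)
    rows <- list()
    for (reg in meta$survival$regions) {
      off_nm <- sprintf("beta_phi[%s]", reg)
      phi_off <- if (off_nm %in% colnames(draws)) draws[, off_nm] else 0
      pi_off_nm <- sprintf("beta_pi[%s]", reg)
      pi_off <- if (pi_off_nm %in% colnames(draws)) draws[, pi_off_nm] else 0
      for (sx in c(0, 1)) {
        phi <- invlogit(draws[, "mu_phi"] + phi_off + draws[, "beta_phi_sex"] * sx)
        pii <- invlogit(draws[, "alpha_pi"] + pi_off + draws[, "beta_pi_sex"] * sx)
        hp <- hpd_interval(phi, mass); hq <- hpd_interval(pii, mass)
        rows[[length(rows) + 1]] <- data.frame(
          region = reg, sex = c("female", "male")[sx + 1],
          phi_mean = mean(phi), phi_lower = hp[1], phi_upper = hp[2],
          pi_mean = mean(pii), pi_lower = hq[1], pi_upper = hq[2])
      }
    }
    surv_tab <- do.call(rbind, rows)
    for (nm in c("beta_phi_hf", "beta_pi_hf")) {
      if (nm %in% colnames(draws)) {
        cov_rows[[nm]] <- .effect_row(draws[, nm], nm, mass)
      }
    }
    for (reg in meta$survival$regions) {
      trend_rows[[paste0("survival.", reg)]] <-
        cbind(rate = "survival", region = reg,
              trend_summary(draws[, sprintf("trend_phi[%s]", reg)],
                            sprintf("trend_phi[%s]", reg), mass))
    }
  } else gaps <- c(gaps, "survival")
  if (!is.null(meta$abundance)) {
    draws <- pooled_draws(joint)
    if ("beta_hf" %in% colnames(draws)) {
      cov_rows[["beta_hf"]] <- .effect_row(draws[, "beta_hf"], "beta_hf", mass)
    }
    for (reg in meta$abundance$regions) {
      trend_rows[[paste0("density.", reg)]] <-
        cbind(rate = "density", region = reg,
              trend_summary(draws[, sprintf("beta_trend[%s]", reg)],
                            sprintf("beta_trend[%s]", reg), mass))
    }
  } else gaps <- c(gaps, "abundance")
  if (!is.null(meta$abundance) && !is.null(meta$survival)) {
    for (reg in intersect(meta$abundance$regions, meta$survival$regions)) {
      tr <- recruitment_trend(recruitment_series(regional_index(joint, reg),
                                                 region_survival(joint, reg)))
      if (!is.null(tr$summary)) {
        trend_rows[[paste0("recruitment.", reg)]] <-
          cbind(rate = "recruitment", region = reg, tr$summary)
      }
    }
  } else gaps <- c(gaps, "recruitment")
  if (!is.null(productivity)) {
    pmeta <- attr(productivity, "meta")$productivity
    draws <- pooled_draws(productivity)
    if ("beta_p_hf" %in% colnames(draws)) {
      cov_rows[["beta_p_hf"]] <- .effect_row(draws[, "beta_p_hf"], "beta_p_hf", mass)
    }
    for (reg in pmeta$regions) {
      trend_rows[[paste0("productivity.", reg)]] <-
        cbind(rate = "productivity", region = reg,
              trend_summary(draws[, sprintf("trend_p[%s]", reg)],
                            sprintf("trend_p[%s]", reg), mass))
    }
  } else gaps <- c(gaps, "productivity")
  if (length(cov_rows)) cov_tab <- do.call(rbind, c(cov_rows, make.row.names = FALSE))
  if (length(trend_rows)) trend_tab <- do.call(rbind, c(trend_rows, make.row.names = FALSE))
  if (length(gaps)) message("report gaps: ", paste(gaps, collapse = ", "))
  structure(list(survival_residency = surv_tab, covariate_effects = cov_tab,
                 trends = trend_tab, gaps = gaps),
            class = "demography_report")
}

.effect_row <- function(draws, name, mass) {
  hp <- hpd_interval(draws, mass)
  data.frame(effect = name, mean = mean(draws), hpd_lower = hp[1],
             hpd_upper = hp[2], prob_below_zero = prob_mass_below_zero(draws),
             row.names = NULL)
}

#' @export
print.demography_report <- function(x, ...) {
  for (nm in c("survival_residency", "covariate_effects", "trends")) {
    if (!is.null(x[[nm]])) {
      cat("==", nm, "==\n")
      print(x[[nm]], digits = 3)
      cat("\n")
    }
  }
  if (length(x$gaps)) cat("missing sections:", paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}

#' Plot per-region trend coefficients with credible intervals
#'
#' One panel per demographic rate, regions on the x axis, posterior mean
#' trend coefficient with its HPD interval. Requires ggplot2.
#'
#' @param report a [make_report()] result with a `trends` table.
#' @return a ggplot object.
#' @export
plot_trends <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    .stopf("plot_trends requires the ggplot2 package")
  }
  tr <- report$trends
  if (is.null(tr)) .stopf("report has no trends table")
  ggplot2::ggplot(tr, ggplot2::aes(x = region, y = mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = hpd_lower, ymax = hpd_upper)) +
    ggplot2::facet_wrap(~rate, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "trend coefficient (per year, link scale)")
}

#' Write report tables to CSV/JSON
#'
#' @param report a [make_report()] result.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("survival_residency", "covariate_effects", "trends")) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
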