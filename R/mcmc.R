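#' MCMC configuration
#'
#' Settings for the adaptive Metropolis-within-Gibbs sampler. The defaults
#' are the full inference protocol: two chains of 100,000 iterations, the
#' first 80,000 discarded as burn-in, thinned by 2 — 10,000 retained draws
#' per chain, 20,000 pooled. `mcmc_preset("reduced")` is the first-class
#' short protocol used in tests and examples (2 chains x 4,000 iterations,
#' 2,000 burn-in, no thinning).
#'
#' Priors follow the package convention throughout: normal(0, variance
#' 10^3) on every coefficient (SD about 31.6 on the link scale) and
#' inverse-gamma(0.001, 0.001) on every variance component.
#'
#' @param n_chains number of chains (>= 1; diagnostics need >= 2).
#' @param n_iterations iterations per chain.
#' @param burn_in iterations discarded (must be < `n_iterations`).
#' @param thin keep every `thin`-th post-burn-in draw (>= 1).
#' @param seed master seed; chain seeds derive from it deterministically.
#' @param target_accept proposal-scale adaptation target (~0.35).
#' @param adapt_window iterations per adaptation batch (burn-in only).
#' @return a list with class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_chains = 2, n_iterations = 100000, burn_in = 80000,
                        thin = 2, seed = 1, target_accept = 0.35,
                        adapt_window = 50) {
  if (burn_in >= n_iterations) .stopf("burn_in must be < n_iterations")
  if (thin < 1) .stopf("thin must be >= 1")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), target_accept = target_accept,
                 adapt_window = as.integer(adapt_window)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @param preset `"full"` (the default protocol) or `"reduced"`.
#' @param ... overrides passed to [mcmc_config()].
#' @export
mcmc_preset <- function(preset = c("full", "reduced"), ...) {
  preset <- match.arg(preset)
  if (preset == "full") mcmc_config(...)
  else mcmc_config(n_iterations = 4000, burn_in = 2000, thin = 1, ...)
}

#' Build a sampling model from update blocks
#'
#' A model is an initializer plus an ordered list of blocks. Three block
#' types are supported: `block_rw()` updates each of its parameters in turn
#' by adaptive random-walk Metropolis against a shared scalar log-posterior
#' (evaluations are cached within the block); `block_rw_vec()` proposes all
#' of its parameters at once and accepts elementwise against a vector of
#' per-component conditional log-posteriors, which is valid only when the
#' components are conditionally independent given the rest (station random
#' effects, observation-level noise); `block_gibbs()` draws directly from a
#' full conditional (conjugate variance updates).
#'
#' @param init function returning a named numeric vector of initial values
#'   (called once per chain, after the chain RNG is seeded).
#' @param blocks list of blocks.
#' @param pars character vector of parameter names the block updates.
#' @param logpost function(theta) -> scalar log-posterior (up to a
#'   constant) for `block_rw`.
#' @param logpost_vec function(theta) -> per-component conditional
#'   log-posteriors, aligned with `pars`, for `block_rw_vec`.
#' @param draw function(theta) -> named replacement values for
#'   `block_gibbs`.
#' @param scale initial random-walk proposal SD.
#' @return an object of class `"mcmc_model"`.
#' @export
mcmc_model <- function(init, blocks) {
  structure(list(init = init, blocks = blocks), class = "mcmc_model")
}

#' @rdname mcmc_model
#' @export
block_rw <- function(pars, logpost, scale = 0.5) {
  list(type = "rw", pars = pars, logpost = logpost, scale = scale)
}

#' @rdname mcmc_model
#' @export
block_rw_vec <- function(pars, logpost_vec, scale = 0.5) {
  list(type = "rw_vec", pars = pars, logpost_vec = logpost_vec, scale = scale)
}

#' @rdname mcmc_model
#' @export
block_gibbs <- function(pars, draw) {
  list(type = "gibbs", pars = pars, draw = draw)
}

.run_chain <- function(model, config, seed) {
  set.seed(seed)
  theta <- model$init()
  pnames <- names(theta)
  blocks <- model$blocks
  nb <- length(blocks)
  idx <- lapply(blocks, function(b) match(b$pars, pnames))
  for (j in seq_len(nb)) {
    if (anyNA(idx[[j]])) .stopf("block references unknown parameter(s)")
  }
  ls <- lapply(blocks, function(b) rep(log(b$scale %||% 0.5), length(b$pars)))
  acc <- lapply(blocks, function(b) numeric(length(b$pars)))
  n_batch <- 0L
  n_keep <- (config$n_iterations - config$burn_in) %/% config$thin
  draws <- matrix(NA_real_, n_keep, length(theta),
                  dimnames = list(NULL, pnames))
  kept <- 0L
  check_lp <- function(lp, theta) {
    if (is.nan(lp)) {
      .stopf("non-finite log-posterior during sampling at: %s",
             paste(sprintf("%s=%.3g", names(theta)[seq_len(min(8, length(theta)))],
                           theta[seq_len(min(8, length(theta)))]), collapse = ", "))
    }
    lp
  }
  for (iter in seq_len(config$n_iterations)) {
    for (j in seq_len(nb)) {
      b <- blocks[[j]]
      ix <- idx[[j]]
      if (b$type == "gibbs") {
        theta[ix] <- b$draw(theta)
      } else if (b$type == "rw") {
        cur <- check_lp(b$logpost(theta), theta)
        if (cur == -Inf) .stopf("log-posterior is -Inf at current state")
        for (m in seq_along(ix)) {
          old <- theta[ix[m]]
          theta[ix[m]] <- old + exp(ls[[j]][m]) * rnorm(1)
          lp <- check_lp(b$logpost(theta), theta)
          if (log(runif(1)) < lp - cur) {
            cur <- lp
            acc[[j]][m] <- acc[[j]][m] + 1
          } else {
            theta[ix[m]] <- old
          }
        }
      } else {  # rw_vec: conditionally independent components
        cur <- b$logpost_vec(theta)
        old <- theta[ix]
        theta[ix] <- old + exp(ls[[j]]) * rnorm(length(ix))
        prop <- b$logpost_vec(theta)
        if (any(is.nan(prop)) || any(is.nan(cur))) check_lp(NaN, theta)
        rej <- log(runif(length(ix))) >= prop - cur
        theta[ix[rej]] <- old[rej]
        acc[[j]] <- acc[[j]] + as.numeric(!rej)
      }
    }
    if (iter %% config$adapt_window == 0 && iter <= config$burn_in) {
      n_batch <- n_batch + 1L
      delta <- min(0.05, 1 / sqrt(n_batch))
      for (j in seq_len(nb)) {
        if (blocks[[j]]$type == "gibbs") next
        rate <- acc[[j]] / config$adapt_window
        ls[[j]] <- ls[[j]] + ifelse(rate > config$target_accept, delta, -delta)
        acc[[j]][] <- 0
      }
    }
    if (iter > config$burn_in &&
        (iter - config$burn_in) %% config$thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- theta
    }
  }
  draws[seq_len(kept), , drop = FALSE]
}

#' Draw from the posterior of a model
#'
#' Runs the configured number of chains of the adaptive
#' Metropolis-within-Gibbs sampler. Proposal scales adapt toward the target
#' acceptance rate during burn-in only, so the post-burn-in kernel is a
#' fixed Markov kernel. Identical seed and configuration give bit-identical
#' chains.
#'
#' @param model an [mcmc_model()].
#' @param config an [mcmc_config()].
#' @return an object of class `"posterior_chains"`: a list of per-chain
#'   draw matrices (retained iterations x parameters) plus the
#'   configuration.
#' @export
sample_posterior <- function(model, config = mcmc_config()) {
  stopifnot(inherits(model, "mcmc_model"))
  set.seed(config$seed)
  chain_seeds <- sample.int(2^31 - 2, config$n_chains)
  chains <- lapply(chain_seeds, function(s) .run_chain(model, config, s))
  structure(list(chains = chains, params = colnames(chains[[1]]),
                 config = config),
            class = "posterior_chains")
}

#' Pooled posterior draws
#'
#' @param x a `posterior_chains` object.
#' @param params optional subset of parameter names.
#' @return matrix of pooled draws (all chains stacked).
#' @export
pooled_draws <- function(x, params = NULL) {
  stopifnot(inherits(x, "posterior_chains"))
  out <- do.call(rbind, x$chains)
  if (!is.null(params)) out[, params, drop = FALSE] else out
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat(sprintf("posterior_chains: %d chains x %d retained draws, %d parameters\n",
              length(x$chains), nrow(x$chains[[1]]), length(x$params)))
  invisible(x)
}

#' @export
summary.posterior_chains <- function(object, mass = 0.90, ...) {
  pooled <- pooled_draws(object)
  hpd <- t(apply(pooled, 2, hpd_interval, mass = mass))
  data.frame(parameter = object$params,
             mean = colMeans(pooled),
             sd = apply(pooled, 2, stats::sd),
             hpd_lower = hpd[, 1], hpd_upper = hpd[, 2],
             rhat = vapply(object$params, function(p) rhat(object, p), 0),
             row.names = NULL)
}

#' Serialize posterior chains and diagnostics
#'
#' `write_chains()` writes one CSV per fitted model: `chain` and
#' `iteration` index columns followed by one column per parameter.
#' `read_chains()` restores a `posterior_chains` object (without the
#' sampler configuration). `diagnostics_report()` computes R-hat for every
#' parameter (plus retained draw counts) and optionally writes it as JSON.
#'
#' @param x a `posterior_chains` object.
#' @param file output path (CSV for chains, JSON for diagnostics).
#' @return `read_chains()` a `posterior_chains`; `diagnostics_report()` a
#'   list with `n_chains`, `retained_per_chain` and `rhat`.
#' @export
write_chains <- function(x, file) {
  stopifnot(inherits(x, "posterior_chains"))
  tabs <- lapply(seq_along(x$chains), function(j) {
    data.frame(chain = j, iteration = seq_len(nrow(x$chains[[j]])),
               x$chains[[j]], check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, tabs), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_chains
#' @export
read_chains <- function(file) {
  tab <- utils::read.csv(file, check.names = FALSE)
  chains <- lapply(split(tab, tab$chain), function(d) {
    as.matrix(d[order(d$iteration), setdiff(names(d), c("chain", "iteration")),
                drop = FALSE])
  })
  chains <- lapply(chains, function(m) { rownames(m) <- NULL; m })
  structure(list(chains = unname(chains), params = colnames(chains[[1]]),
                 config = NULL),
            class = "posterior_chains")
}

#' @rdname write_chains
#' @export
diagnostics_report <- function(x, file = NULL) {
  stopifnot(inherits(x, "posterior_chains"))
  rep <- list(n_chains = length(x$chains),
              retained_per_chain = nrow(x$chains[[1]]),
              rhat = as.list(stats::setNames(
                vapply(x$params, function(p) rhat(x, p), 0), x$params)))
  if (!is.null(file)) {
    jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA)
  }
  rep
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic split-free R-hat: with m chains of n draws, `W` the mean
#' within-chain variance and `B/n` the variance of the chain means, R-hat is
#' `sqrt((((n - 1) / n) W + B / n) / W)`. Identical chains (zero
#' between-chain variance) therefore return `sqrt((n - 1) / n)`, slightly
#' below 1.
#'
#' @param x a `posterior_chains` object (with `param` naming one
#'   parameter), a matrix with one column per chain, or a list of equal
#'   length numeric vectors.
#' @param param parameter name when `x` is a `posterior_chains`.
#' @return the R-hat value.
#' @export
rhat <- function(x, param = NULL) {
  if (inherits(x, "posterior_chains")) {
    if (is.null(param)) .stopf("give a parameter name")
    x <- vapply(x$chains, function(ch) ch[, param], numeric(nrow(x$chains[[1]])))
  } else if (is.list(x)) {
    if (length(unique(lengths(x))) != 1) .stopf("chains must have equal length")
    x <- do.call(cbind, x)
  }
  m <- ncol(x); n <- nrow(x)
  if (is.null(m) || m < 2) .stopf("R-hat needs at least 2 chains")
  if (n < 10) .stopf("R-hat needs at least 10 draws per chain")
  W <- mean(apply(x, 2, stats::var))
  B_over_n <- stats::var(colMeans(x))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Highest posterior density interval
#'
#' The narrowest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws.
#'
#' @param draws numeric vector (>= 100 draws).
#' @param mass interval mass in (0, 1], default 0.90.
#' @return numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.90) {
  if (length(draws) < 100) .stopf("hpd_interval needs at least 100 draws")
  if (mass <= 0 || mass > 1) .stopf("mass must be in (0, 1]")
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  width <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(width)
  c(x[i], x[i + m - 1])
}

#' Posterior mass below zero
#'
#' @param draws numeric vector (>= 1 draw).
#' @return fraction of draws strictly below 0.
#' @export
prob_mass_below_zero <- function(draws) {
  if (length(draws) < 1) .stopf("need at least 1 draw")
  mean(draws < 0)
}
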