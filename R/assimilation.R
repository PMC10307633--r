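# Per-profile Bayesian parameter estimation: two-phase adaptive Metropolis
# under uniform priors, with Gelman-Rubin convergence and Nash-Sutcliffe fit
# filtering, under the steady-state assumption.

#' Assimilation configuration
#'
#' Defaults are the scaled-down test profile (2,000 / 5,000 iterations); the
#' full protocol uses `n_test = 20000, n_formal = 50000`.
#'
#' @param n_test,n_formal iterations of the test and formal phases.
#' @param n_chains independent chains (3 in the full protocol).
#' @param burn_in fraction of the formal run discarded (0.5).
#' @param proposal_frac test-phase per-coordinate proposal sd as a fraction
#'   of the prior range.
#' @param adapt_every formal-phase covariance refresh interval (iterations).
#' @param epsilon diagonal jitter of the adapted proposal covariance.
#' @param sigma_model observation-error model: `"proportional"`
#'   (sd = sigma_c * obs), `"additive"` (sd = sigma_add) or `"lognormal"`
#'   (Gaussian in log space with sd sigma_c).
#' @param sigma_c proportional / log-space error coefficient.
#' @param sigma_add additive error sd (gC m^-3).
#' @param mic_max_frac maximum allowed profile-total MIC fraction of total
#'   mineral SOC (0.1: the 10 percent microbial-biomass constraint).
#' @param gr_threshold Gelman-Rubin convergence threshold (1.05).
#' @param e_threshold coefficient-of-efficiency fit threshold (0.0).
#' @param accept_lo,accept_hi target formal-run acceptance-ratio band.
#' @param retune retry the formal phase once with a rescaled proposal when
#'   the acceptance ratio leaves the band.
#' @return list of class `soilcue_assim_config`.
#' @export
assimilation_config <- function(n_test = 2000, n_formal = 5000, n_chains = 3,
                                burn_in = 0.5, proposal_frac = 0.05,
                                adapt_every = 100, epsilon = 1e-6,
                                sigma_model = c("proportional", "additive",
                                                "lognormal"),
                                sigma_c = 0.3, sigma_add = 500,
                                mic_max_frac = 0.1, gr_threshold = 1.05,
                                e_threshold = 0.0, accept_lo = 0.1,
                                accept_hi = 0.5, retune = TRUE) {
  stopifnot(n_test > 0, n_formal > 0, n_chains >= 1,
            burn_in >= 0, burn_in < 1)
  cfg <- list(n_test = n_test, n_formal = n_formal, n_chains = n_chains,
              burn_in = burn_in, proposal_frac = proposal_frac,
              adapt_every = adapt_every, epsilon = epsilon,
              sigma_model = match.arg(sigma_model), sigma_c = sigma_c,
              sigma_add = sigma_add, mic_max_frac = mic_max_frac,
              gr_threshold = gr_threshold, e_threshold = e_threshold,
              accept_lo = accept_lo, accept_hi = accept_hi, retune = retune)
  class(cfg) <- "soilcue_assim_config"
  cfg
}

#' Site context for assimilation
#'
#' @param grid layer grid.
#' @param forcings site forcings.
#' @param input_split litter input split.
#' @return list bundling the model context of one site.
#' @export
site_context <- function(grid, forcings,
                         input_split = c(ML = 0.45, CL = 0.35, LL = 0.20)) {
  list(grid = grid, forcings = forcings, input_split = input_split)
}

#' Log-likelihood of a profile under a parameter set
#'
#' Steady-state model density (mineral pools) at the observation depths
#' against observed layer stocks under independent Gaussian errors
#' (proportional sd by default).  Returns `-Inf` when the parameter set is
#' structurally invalid, the steady state infeasible, or the simulated
#' profile-total microbial biomass exceeds `mic_max_frac` (10 percent) of
#' total mineral SOC.
#'
#' @param profile profile with derived stocks.
#' @param params parameter vector.
#' @param context [site_context()].
#' @param config [assimilation_config()].
#' @return scalar log-likelihood (`-Inf` encodes infeasibility).
#' @export
profile_cost <- function(profile, params, context,
                         config = assimilation_config()) {
  if (length(validate_params(params, strict = FALSE))) return(-Inf)
  grid <- context$grid
  modifier <- environmental_modifier(context$forcings, params, grid)
  ss <- tryCatch(
    soil_steady_state(
      litter_steady_state(params, grid, modifier, context$forcings,
                          context$input_split),
      params, grid, modifier),
    error = function(e) NULL)
  if (is.null(ss) || !isTRUE(attr(ss, "feasible"))) return(-Inf)

  mineral_tot <- sum(ss[, MINERAL_POOLS] %*% rep(1, 4) * grid$thickness)
  mic_tot <- sum(ss[, "MIC"] * grid$thickness)
  if (mineral_tot <= 0 || mic_tot / mineral_tot > config$mic_max_frac) {
    return(-Inf)
  }

  obs <- profile$layers$stock_gC_m3
  if (is.null(obs)) stop("profile has no derived stocks: run derive_stocks()")
  mod <- model_equivalent_stock(ss, grid, profile)
  switch(config$sigma_model,
    proportional = {
      sd <- config$sigma_c * obs
      sum(stats::dnorm(obs, mod, sd, log = TRUE))
    },
    additive = sum(stats::dnorm(obs, mod, config$sigma_add, log = TRUE)),
    lognormal = {
      if (any(mod <= 0)) return(-Inf)
      sum(stats::dnorm(log(obs), log(mod), config$sigma_c, log = TRUE))
    })
}

# One Metropolis phase. start: free-parameter vector; propose(theta, i):
# returns candidate. Returns samples (n x d), log-posterior trace,
# acceptance ratio, and the accepted-state matrix.
run_chain_phase <- function(cost_fn, start, n_iter, propose, lower, upper,
                            adapt = NULL) {
  d <- length(start)
  samples <- matrix(NA_real_, n_iter, d)
  lp <- numeric(n_iter)
  theta <- start
  lp_cur <- cost_fn(theta)
  n_acc <- 0L
  acc_idx <- integer(0)
  for (i in seq_len(n_iter)) {
    if (!is.null(adapt)) adapt(i, samples, n_acc)
    cand <- propose(theta, i)
    if (all(cand >= lower & cand <= upper)) {
      lp_cand <- cost_fn(cand)
      if (is.finite(lp_cand) &&
          (lp_cand >= lp_cur || log(stats::runif(1)) < lp_cand - lp_cur)) {
        theta <- cand
        lp_cur <- lp_cand
        n_acc <- n_acc + 1L
        acc_idx <- c(acc_idx, i)
      }
    }
    samples[i, ] <- theta
    lp[i] <- lp_cur
  }
  list(samples = samples, log_posterior = lp,
       acceptance_ratio = n_acc / n_iter, accepted_index = acc_idx)
}

#' Two-phase adaptive Metropolis for one profile
#'
#' Test phase: per-coordinate Gaussian random-walk proposals with sd a fixed
#' fraction of each prior range, candidates outside the uniform prior
#' rejected.  Formal phase: multivariate Gaussian proposals started from the
#' test-phase acceptances, with covariance `2.38^2/d * Sigma + epsilon I`
#' continuously re-estimated from the accumulating formal samples every
#' `adapt_every` iterations.  The formal acceptance ratio is checked against
#' the `[accept_lo, accept_hi]` band post hoc; one retry with a rescaled
#' proposal is attempted when `config$retune` is set.
#'
#' @inheritParams profile_cost
#' @param priors prior table ([default_prior_spec()]).
#' @param seed integer seed (chain-specific).
#' @return list of class `soilcue_chain` with elements `test` and `formal`
#'   (each: `samples`, `log_posterior`, `acceptance_ratio`, `phase`,
#'   `seed`), plus `free_names`, `retuned`, `flags`.
#' @export
adaptive_metropolis <- function(profile, priors, context,
                                config = assimilation_config(), seed = 1) {
  set.seed(seed)
  free <- priors$free_flag
  d <- sum(free)
  if (d < 1) stop("no free parameters")
  lower <- priors$lower[free]
  upper <- priors$upper[free]
  rng <- upper - lower
  template <- stats::setNames(priors$value, priors$name)
  free_names <- priors$name[free]

  cost_fn <- function(theta) {
    v <- template
    v[free_names] <- theta
    p <- v
    class(p) <- "soilcue_params"
    profile_cost(profile, p, context, config)
  }

  # --- test phase: independent per-coordinate proposals
  sd_test <- config$proposal_frac * rng
  start <- (lower + upper) / 2
  if (!is.finite(cost_fn(start))) {
    # fall back to prior draws to find a feasible start
    for (try in 1:200) {
      cand <- stats::runif(d, lower, upper)
      if (is.finite(cost_fn(cand))) { start <- cand; break }
    }
  }
  test <- run_chain_phase(cost_fn, start, config$n_test,
                          function(theta, i) theta + stats::rnorm(d, 0, sd_test),
                          lower, upper)
  test$phase <- "test"
  test$seed <- seed

  # --- formal phase: adapted multivariate Gaussian proposals
  acc <- test$samples[test$accepted_index, , drop = FALSE]
  scale0 <- 2.38^2 / d
  base_cov <- if (nrow(acc) > 2 * d) stats::cov(acc) else diag(sd_test^2, d)
  formal_start <- if (nrow(acc)) acc[nrow(acc), ] else start

  run_formal <- function(scale_mult) {
    chol_prop <- NULL
    update_chol <- function(S) {
      S <- scale_mult * scale0 * S + diag(config$epsilon, d)
      chol_prop <<- tryCatch(chol(S), error = function(e) {
        chol(diag(diag(S) + config$epsilon, d))
      })
    }
    update_chol(base_cov)
    adapt <- function(i, samples, n_acc) {
      if (i > 2 * d && i %% config$adapt_every == 0) {
        update_chol(stats::cov(samples[seq_len(i - 1), , drop = FALSE]))
      }
    }
    run_chain_phase(cost_fn, formal_start, config$n_formal,
                    function(theta, i) {
                      theta + drop(stats::rnorm(d) %*% chol_prop)
                    },
                    lower, upper, adapt = adapt)
  }

  formal <- run_formal(1)
  retuned <- FALSE
  if (config$retune &&
      (formal$acceptance_ratio < config$accept_lo ||
       formal$acceptance_ratio > config$accept_hi)) {
    retuned <- TRUE
    mult <- if (formal$acceptance_ratio < config$accept_lo) 0.25 else 4
    formal <- run_formal(mult)
  }
  formal$phase <- "formal"
  formal$seed <- seed

  flags <- character()
  if (formal$acceptance_ratio == 0) flags <- c(flags, "zero_acceptance")
  out <- list(test = test, formal = formal, free_names = free_names,
              retuned = retuned, flags = flags)
  class(out) <- "soilcue_chain"
  out
}

#' Gelman-Rubin potential scale reduction
#'
#' Standard split-free PSRF over two or more chains of equal length:
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)` per parameter, with `W` the mean
#' within-chain variance and `B/n` the between-chain variance of means.
#'
#' @param chains list of numeric matrices (iterations x parameters).
#' @param burn_in_frac fraction of initial iterations discarded (0.5).
#' @return list with `per_parameter` (named vector) and `mean`.
#' @export
gelman_rubin <- function(chains, burn_in_frac = 0.5) {
  if (length(chains) < 2) stop("need at least 2 chains")
  n_iter <- unique(vapply(chains, nrow, 1L))
  if (length(n_iter) != 1) stop("chains must have equal length")
  keep <- seq.int(floor(burn_in_frac * n_iter) + 1, n_iter)
  post <- lapply(chains, function(ch) ch[keep, , drop = FALSE])
  n <- length(keep)
  means <- do.call(rbind, lapply(post, colMeans))
  vars <- do.call(rbind, lapply(post, function(ch) apply(ch, 2, stats::var)))
  W <- colMeans(vars)
  B_over_n <- apply(means, 2, stats::var)
  if (any(W == 0)) {
    rhat <- ifelse(W == 0 & B_over_n == 0, 1, Inf)
    rhat[W > 0] <- sqrt(((n - 1) / n * W[W > 0] + B_over_n[W > 0]) / W[W > 0])
  } else {
    rhat <- sqrt(((n - 1) / n * W + B_over_n) / W)
  }
  names(rhat) <- colnames(chains[[1]])
  list(per_parameter = rhat, mean = mean(rhat))
}

#' Assimilate one profile
#'
#' Runs `n_chains` independent two-phase chains, discards the burn-in half
#' of each formal run, and summarizes: posterior means (the point
#' estimates) and sds, per-parameter and mean Gelman-Rubin statistics, the
#' best-fit coefficient of efficiency at the posterior-mean parameters, and
#' the convergence / fit / constraint flags used for downstream filtering.
#'
#' @inheritParams adaptive_metropolis
#' @param seed base seed; chain `k` uses `seed + 1000 * k`.
#' @return list of class `soilcue_posterior`: `site_id`, `posterior_mean`,
#'   `posterior_sd`, `gelman_rubin`, `mean_gr`, `e_fit`, `acceptance_ratios`,
#'   `params` (full vector at posterior means), `flags` (list: converged,
#'   fit_ok, mic_ok), `chains` (formal sample matrices).
#' @export
assimilate_profile <- function(profile, priors, context,
                               config = assimilation_config(), seed = 1) {
  chains <- lapply(seq_len(config$n_chains), function(k) {
    adaptive_metropolis(profile, priors, context, config,
                        seed = seed + 1000L * k)
  })
  formal <- lapply(chains, function(ch) ch$formal$samples)
  n_iter <- nrow(formal[[1]])
  keep <- seq.int(floor(config$burn_in * n_iter) + 1, n_iter)
  pooled <- do.call(rbind, lapply(formal, function(s) s[keep, , drop = FALSE]))
  free_names <- chains[[1]]$free_names
  colnames(pooled) <- free_names

  post_mean <- colMeans(pooled)
  post_sd <- apply(pooled, 2, stats::sd)
  gr <- if (config$n_chains >= 2) {
    gelman_rubin(lapply(formal, function(s) {
      colnames(s) <- free_names
      s
    }), config$burn_in)
  } else {
    list(per_parameter = stats::setNames(rep(NA_real_, length(free_names)),
                                         free_names), mean = NA_real_)
  }

  params_hat <- stats::setNames(priors$value, priors$name)
  params_hat[free_names] <- post_mean
  params_hat <- microbial_params(values = params_hat)

  ss <- steady_state(params_hat, context$grid, context$forcings,
                     input_split = context$input_split)
  mic_ok <- FALSE
  e_fit <- NA_real_
  if (isTRUE(attr(ss, "feasible"))) {
    mineral_tot <- sum(ss[, MINERAL_POOLS] %*% rep(1, 4) *
                         context$grid$thickness)
    mic_ok <- sum(ss[, "MIC"] * context$grid$thickness) / mineral_tot <=
      config$mic_max_frac
    e_fit <- coefficient_of_efficiency(
      profile$layers$stock_gC_m3,
      model_equivalent_stock(ss, context$grid, profile))
  }

  out <- list(
    site_id = profile$site_id,
    posterior_mean = post_mean, posterior_sd = post_sd,
    gelman_rubin = gr$per_parameter, mean_gr = gr$mean,
    e_fit = e_fit,
    acceptance_ratios = vapply(chains, function(ch)
      ch$formal$acceptance_ratio, 1),
    params = params_hat,
    flags = list(converged = is.finite(gr$mean) && gr$mean <= config$gr_threshold,
                 fit_ok = is.finite(e_fit) && e_fit > config$e_threshold,
                 mic_ok = mic_ok),
    chains = formal
  )
  class(out) <- "soilcue_posterior"
  out
}

#' Posterior summary table
#'
#' @param summaries list of `soilcue_posterior` objects.
#' @param file CSV path.
#' @export
write_posterior_summaries <- function(summaries, file) {
  rows <- lapply(summaries, function(s) {
    data.frame(site_id = s$site_id,
               t(s$posterior_mean),
               mean_gr = s$mean_gr, e_fit = s$e_fit,
               converged = s$flags$converged, fit_ok = s$flags$fit_ok,
               mic_ok = s$flags$mic_ok, check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' @export
print.soilcue_posterior <- function(x, ...) {
  cat("<soilcue_posterior> site ", x$site_id,
      ": mean G-R ", round(x$mean_gr, 3),
      ", E ", round(x$e_fit, 3),
      ", converged ", x$flags$converged, "\n", sep = "")
  invisible(x)
}
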