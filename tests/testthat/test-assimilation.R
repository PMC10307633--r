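# assimilation: likelihood, adaptive Metropolis, Gelman-Rubin, recovery.

make_recovery_case <- function(seed) {
  priors <- recovery_priors()
  theta <- draw_recovery_truth(priors, seed = seed)
  recovery_profile(theta, priors, grid_clm(), seed = seed + 500)
}

test_that("profile cost: zero residual is maximal, sigma algebra, MIC cap", {
  g <- grid_clm()
  priors <- recovery_priors()
  p <- microbial_params(values = stats::setNames(priors$value, priors$name))
  case <- make_recovery_case(1)
  ctx <- site_context(g, case$forcings)
  cfg <- assimilation_config(sigma_c = 0.3)

  v <- stats::setNames(priors$value, priors$name)
  v[names(case$truth)] <- case$truth
  p_true <- microbial_params(values = v)
  ll_true <- profile_cost(case$profile, p_true, ctx, cfg)
  ll_off <- profile_cost(case$profile, p, ctx, cfg)
  expect_gte(ll_true, ll_off)

  # doubling sigma changes the log-likelihood by the predictable constant:
  # residuals are zero at truth, so only the normalization moves
  cfg2 <- assimilation_config(sigma_c = 0.6)
  n_obs <- nrow(case$profile$layers)
  expect_equal(profile_cost(case$profile, p_true, ctx, cfg2) - ll_true,
               -n_obs * log(2), tolerance = 1e-9)

  # invalid and infeasible parameter sets cost -Inf
  expect_identical(profile_cost(case$profile,
                                microbial_params(a_DOC_ML = 0.9), ctx, cfg),
                   -Inf)
  expect_identical(profile_cost(case$profile,
                                microbial_params(v_max_decom = 5, a_mSOC_LL = 0.3),
                                ctx, cfg), -Inf)

  # the 10 percent microbial-biomass constraint rejects high-MIC states
  cfg_tight <- assimilation_config(mic_max_frac = 1e-6)
  expect_identical(profile_cost(case$profile, p_true, ctx, cfg_tight), -Inf)
})

test_that("gelman_rubin: converged, disjoint and inflated chains", {
  set.seed(4)
  same <- lapply(1:3, function(i) matrix(rnorm(4000), ncol = 2))
  gr <- gelman_rubin(same, burn_in_frac = 0.5)
  expect_lt(abs(gr$mean - 1), 0.02)

  disjoint <- list(matrix(rnorm(1000, 0), ncol = 1),
                   matrix(rnorm(1000, 10), ncol = 1))
  expect_gt(gelman_rubin(disjoint, 0.5)$mean, 1.05)

  # inflating one chain's mean strictly increases R-hat
  shift <- seq(0, 2, by = 0.5)
  rh <- vapply(shift, function(s) {
    ch <- list(matrix(rnorm(1000, 0), ncol = 1),
               matrix(rnorm(1000, s), ncol = 1))
    gelman_rubin(ch, 0)$mean
  }, 1)
  expect_true(all(diff(rh) > 0))

  # burn-in discards exactly the first half
  ch <- lapply(1:2, function(i) matrix(c(rep(1e3, 500), rnorm(500)), ncol = 1))
  expect_lt(gelman_rubin(ch, 0.5)$mean, 1.1)
  expect_error(gelman_rubin(same[1]), "at least 2")
})

test_that("chains are bit-reproducible under identical seeds and respect bounds", {
  case <- make_recovery_case(2)
  priors <- recovery_priors()
  ctx <- site_context(grid_clm(), case$forcings)
  cfg <- assimilation_config(n_test = 300, n_formal = 600, sigma_c = 0.15)
  a <- adaptive_metropolis(case$profile, priors, ctx, cfg, seed = 77)
  b <- adaptive_metropolis(case$profile, priors, ctx, cfg, seed = 77)
  expect_identical(a$formal$samples, b$formal$samples)
  expect_identical(a$test$samples, b$test$samples)

  lo <- priors$lower[priors$free_flag]
  hi <- priors$upper[priors$free_flag]
  for (ph in list(a$test, a$formal)) {
    expect_true(all(sweep(ph$samples, 2, lo, `>=`)))
    expect_true(all(sweep(ph$samples, 2, hi, `<=`)))
    expect_gte(ph$acceptance_ratio, 0)
    expect_lte(ph$acceptance_ratio, 1)
  }

  # a nearly degenerate prior pins the chain
  pr2 <- recovery_priors()
  i <- match("eta_DOC", pr2$name)
  pr2$lower[i] <- 0.35; pr2$upper[i] <- 0.35 + 1e-9; pr2$value[i] <- 0.35
  free1 <- default_prior_spec(free = "eta_DOC")
  pr2$free_flag <- free1$free_flag
  d <- adaptive_metropolis(case$profile, pr2, ctx, cfg, seed = 5)
  expect_lt(diff(range(d$formal$samples)), 1e-8)
})

test_that("noiseless recovery: eta_DOC found, flags meaningful", {
  priors <- recovery_priors()
  cfg <- assimilation_config(n_test = 1500, n_formal = 3000, n_chains = 3,
                             sigma_c = 0.15)
  errs <- c()
  for (s in 1:3) {
    case <- make_recovery_case(10 + s)
    if (is.null(case)) next
    res <- assimilate_profile(case$profile, priors,
                              site_context(grid_clm(), case$forcings),
                              cfg, seed = 400 + s)
    errs <- c(errs, res$posterior_mean["eta_DOC"] - case$truth["eta_DOC"])
    expect_lte(res$mean_gr, 1.1)
    expect_true(res$flags$fit_ok)
    expect_gt(res$e_fit, 0.8)
    expect_true(res$flags$mic_ok)
  }
  expect_lt(mean(abs(errs)), 0.08)
})

test_that("credible-interval coverage under 10 percent observation noise", {
  priors <- recovery_priors()
  cfg <- assimilation_config(n_test = 1000, n_formal = 2500, n_chains = 1,
                             sigma_c = 0.1)
  covered <- total <- 0
  sdlog <- sqrt(log(1 + 0.1^2))
  for (s in 1:10) {
    case <- make_recovery_case(30 + s)
    if (is.null(case)) next
    set.seed(900 + s)
    noisy <- case$profile
    noisy$layers$stock_gC_m3 <- noisy$layers$stock_gC_m3 *
      rlnorm(nrow(noisy$layers), -sdlog^2 / 2, sdlog)
    res <- assimilate_profile(noisy, priors,
                              site_context(grid_clm(), case$forcings),
                              cfg, seed = 600 + s)
    ch <- res$chains[[1]]
    keep <- seq.int(nrow(ch) / 2 + 1, nrow(ch))
    j <- match("eta_DOC", names(res$posterior_mean))
    ci <- quantile(ch[keep, j], c(0.025, 0.975))
    total <- total + 1
    covered <- covered +
      (case$truth["eta_DOC"] >= ci[1] && case$truth["eta_DOC"] <= ci[2])
  }
  expect_gte(total, 8)
  expect_gte(covered / total, 0.7)
})
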