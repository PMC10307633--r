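# Steady states: closed forms, the ODE oracle, mass balance, uniqueness.

test_that("single-layer litter balance and zero-input limit", {
  g <- make_layer_grid(2, "uniform", max_depth = 0.4)
  p <- microbial_params(d_bio = 0)
  fc <- site_forcings(300, 12, 0.6, g)
  mo <- environmental_modifier(fc, p, g)
  lit <- litter_steady_state(p, g, mo, fc)
  # per-layer balance: x = input_flux / (k xi) for each litter pool
  alloc <- input_allocation_profile(p, g)
  for (pool in c("ML", "CL", "LL")) {
    split <- c(ML = 0.45, CL = 0.35, LL = 0.20)[[pool]]
    k <- p[[paste0("k_", pool)]]
    expect_equal(lit[, pool],
                 300 * split * alloc / g$thickness / (k * mo$xi_total),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # no input -> all litter pools zero
  fc0 <- site_forcings(0, 12, 0.6, g)
  expect_true(all(litter_steady_state(p, g, mo, fc0) == 0))
})

test_that("zero-input limit of the mineral closed forms", {
  g <- grid_uni()
  p <- microbial_params()
  fc0 <- site_forcings(0, 12, 0.6, g)
  mo <- environmental_modifier(fc0, p, g)
  ss <- soil_steady_state(litter_steady_state(p, g, mo, fc0), p, g, mo)
  expect_true(isTRUE(attr(ss, "feasible")))
  expect_true(all(ss[, c("DOC", "MIC", "ENZ", "mSOC")] == 0))
})

test_that("eta_DOC near 1 with full recycling diverges (biomass denominator)", {
  # with c = 1 (full recycling) the x_MIC denominator is (1 - eta) k xi
  p <- microbial_params(eta_DOC = 0.999, a_DOC_MIC = 0.55, a_ENZ_MIC = 0.05,
                        a_mSOC_MIC = 0.40, a_DOC_mSOC = 1)
  g <- grid_uni()
  fc <- site_forcings(500, 12, 0.6, g)
  mo <- environmental_modifier(fc, p, g)
  ss <- soil_steady_state(litter_steady_state(p, g, mo, fc), p, g, mo)
  # enormous biomass, and infeasible because uptake capacity cannot keep up
  expect_true(max(ss[, "MIC"]) > 1e5 || !isTRUE(attr(ss, "feasible")))
})

test_that("analytic steady state is an exact fixed point on the clm5 grid", {
  g <- grid_clm()
  fc <- forcings_temperate(g)
  for (p in draw_params(10, seed = 42)) {
    mo <- environmental_modifier(fc, p, g)
    ss <- steady_state(p, g, fc, mo)
    if (!isTRUE(attr(ss, "feasible"))) next
    r <- model_rhs(ss, p, g, mo, fc)
    expect_lt(max(abs(r)), 1e-8 * fc$npp)
    # respiration balances input exactly at steady state
    expect_equal(total_respiration(ss, p, g, mo), fc$npp,
                 tolerance = 1e-10)
  }
})

test_that("analytic and ODE-oracle steady states agree on a resolvable column", {
  g <- grid_uni()
  fc <- forcings_temperate(g)
  n_checked <- 0
  for (p in draw_params(12, seed = 7)) {
    mo <- environmental_modifier(fc, p, g)
    ss <- steady_state(p, g, fc, mo)
    if (!isTRUE(attr(ss, "feasible"))) next
    num <- integrate_to_steady_state(p, g, fc, mo)
    expect_true(isTRUE(attr(num, "converged")))
    expect_lt(max(abs(num - ss) / (abs(ss) + 1e-9 * max(ss))), 1e-3)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 5)
})

test_that("oracle: stationarity at the fixed point and uniqueness across starts", {
  g <- grid_uni()
  fc <- forcings_temperate(g)
  p <- microbial_params()
  mo <- environmental_modifier(fc, p, g)
  ss <- steady_state(p, g, fc, mo)

  # starting at the analytic state, the residual is already ~0
  num0 <- integrate_to_steady_state(p, g, fc, mo, x0 = ss)
  expect_lt(max(abs(num0 - ss) / (abs(ss) + 1e-9 * max(ss))), 1e-6)

  # two different positive starts converge to the same state
  a <- integrate_to_steady_state(p, g, fc, mo,
                                 x0 = matrix(0.1, 20, 8))
  b <- integrate_to_steady_state(p, g, fc, mo,
                                 x0 = matrix(50, 20, 8))
  expect_lt(max(abs(a - b) / (abs(a) + 1e-9 * max(a))), 1e-3)

  # mass balance of the rhs at arbitrary states: d(total C)/dt = I - resp
  set.seed(9)
  st <- pool_state(g, matrix(runif(160, 0, 100), 20, 8))
  r <- model_rhs(st, p, g, mo, fc)
  expect_equal(sum(r * g$thickness),
               fc$npp - total_respiration(st, p, g, mo), tolerance = 1e-8)

  expect_error(integrate_to_steady_state(p, g, fc, mo, t_max = -1), "t_max")
})

test_that("infeasible parameter sets are flagged, never clipped", {
  g <- grid_uni()
  fc <- forcings_temperate(g)
  # starve the enzymatic capacity
  p <- microbial_params(v_max_decom = 5, a_mSOC_LL = 0.3)
  ss <- steady_state(p, g, fc)
  expect_false(attr(ss, "feasible"))
  expect_match(attr(ss, "reason"), "decomposition capacity")
})
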