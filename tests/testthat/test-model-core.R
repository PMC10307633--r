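# model_core: grid, parameters, modifiers, operators, rates.

test_that("layer grids: uniform split, clm5 node law, degenerate input", {
  g2 <- make_layer_grid(2, "uniform", max_depth = 1)
  expect_equal(g2$thickness, c(0.5, 0.5))

  g <- make_layer_grid(20, "clm5")
  expect_true(all(diff(g$node_depth) > 0))
  expect_equal(g$node_depth[1], 0.025 * (exp(0.25) - 1), tolerance = 1e-12)
  expect_equal(g$node_depth[1], 0.007, tolerance = 0.01)
  expect_equal(diff(g$interface_depth), g$thickness)

  expect_error(make_layer_grid(1), "n_layers")
  expect_error(make_layer_grid(10, "nonsense"), "arg")
})

test_that("parameter invariants are enforced", {
  expect_silent(validate_params(microbial_params()))
  # donor outflow > 1
  expect_error(validate_params(microbial_params(a_DOC_ML = 0.8, a_MIC_ML = 0.5)),
               "outflow")
  expect_error(validate_params(microbial_params(eta_DOC = 1)), "eta_DOC")
  expect_error(validate_params(microbial_params(k_MIC = -1)))
  expect_error(microbial_params(not_a_param = 1), "unknown")
  # prior draws respect structure
  for (p in draw_params(25, seed = 5)) {
    expect_length(validate_params(p, strict = FALSE), 0)
  }
})

test_that("pathway CUEs follow the renormalized growth fractions", {
  p <- microbial_params(a_MIC_ML = 0.3, a_DOC_ML = 0.4)
  expect_equal(unname(pool_cue_values(p)["eta_ML"]), 0.5)
  p2 <- microbial_params(a_MIC_ML = 0.37, a_DOC_ML = 0)
  expect_equal(unname(pool_cue_values(p2)["eta_ML"]), 0.37)
  expect_equal(unname(pool_cue_values(p)["eta_DOC"]), p[["eta_DOC"]])
  expect_error(pool_cue_values(microbial_params(a_DOC_ML = 1, a_MIC_ML = 0)),
               "undefined")
})

test_that("environmental modifier shapes and reference points", {
  g <- grid_clm()
  p <- microbial_params()
  fc <- site_forcings(500, 25, 0.6, g)
  mo <- environmental_modifier(fc, p, g)
  expect_equal(mo$xi_t, rep(1, 20))                      # T = T_ref
  expect_equal(mo$xi_d, exp(-g$node_depth / p[["z_tau"]]))

  mo2 <- environmental_modifier(site_forcings(500, 15, 0.6, g),
                                microbial_params(q10 = 2), g)
  expect_equal(mo2$xi_t, rep(0.5, 20))                   # Q10 = 2, dT = -10

  # z_tau -> large removes depth attenuation
  mo3 <- environmental_modifier(fc, microbial_params(z_tau = 2), g)
  expect_true(all(mo3$xi_d >= exp(-g$node_depth / 2)))
  expect_equal(environmental_modifier(fc, microbial_params(z_tau = 1e12), g)$xi_d,
               rep(1, 20), tolerance = 1e-6)

  expect_error(site_forcings(500, NaN, 0.5, g), "non-finite")
})

test_that("operator assembly: A sparsity, B normalization, V conservation", {
  g <- grid_uni()
  p <- microbial_params()
  ops <- assemble_operators(p, g)

  # exact block sparsity pattern of the transfer matrix
  expected <- matrix(0, 8, 8, dimnames = list(soilcue:::POOLS, soilcue:::POOLS))
  diag(expected) <- -1
  expected["CL", "CWD"] <- p[["a_CL_CWD"]]; expected["LL", "CWD"] <- p[["a_LL_CWD"]]
  expected["DOC", "ML"] <- p[["a_DOC_ML"]]; expected["DOC", "CL"] <- p[["a_DOC_CL"]]
  expected["DOC", "MIC"] <- p[["a_DOC_MIC"]]; expected["DOC", "ENZ"] <- 1
  expected["DOC", "mSOC"] <- p[["a_DOC_mSOC"]]
  expected["MIC", "ML"] <- p[["a_MIC_ML"]]; expected["MIC", "CL"] <- p[["a_MIC_CL"]]
  expected["MIC", "LL"] <- p[["a_MIC_LL"]]; expected["MIC", "DOC"] <- p[["eta_DOC"]]
  expected["ENZ", "MIC"] <- p[["a_ENZ_MIC"]]
  expected["mSOC", "LL"] <- p[["a_mSOC_LL"]]; expected["mSOC", "MIC"] <- p[["a_mSOC_MIC"]]
  expect_equal(ops$A_block, expected)
  expect_equal(ops$A, kronecker(expected, diag(1, 20)), ignore_attr = TRUE)

  # B sums to one over all entries; no CWD input by default
  expect_equal(sum(ops$B), 1)
  expect_equal(sum(ops$B[1:20]), 0)

  # allocation law: fraction below 5 cm is beta^5
  p9 <- microbial_params(beta_root = 0.9)
  alloc <- input_allocation_profile(p9, make_layer_grid(20, "uniform", max_depth = 1))
  ifc <- make_layer_grid(20, "uniform", max_depth = 1)$interface_depth * 100
  below5 <- sum(alloc[ifc[-21] >= 5])
  expect_equal(below5, 0.9^5, tolerance = 1e-3)

  # D_bio = 0 gives a zero transport operator
  expect_true(all(assemble_operators(microbial_params(d_bio = 0), g)$V == 0))

  # V conserves depth-integrated mass exactly (zero decomposition)
  Vb <- soilcue:::transport_block(1e-3, g)
  x <- runif(20, 0, 10)
  expect_equal(sum((Vb %*% x) * g$thickness), 0, tolerance = 1e-12)

  expect_error(assemble_operators(microbial_params(a_DOC_ML = 0.9), g))
})

test_that("state-dependent rates follow the printed Michaelis-Menten forms", {
  g <- grid_uni()
  p <- microbial_params(v_max_assim = 10, K_m_assim = 50)
  mo <- environmental_modifier(site_forcings(500, 25, 1, g,
                                             xi_no = 1), microbial_params(psi_half = 1e-9), g)
  # xi == xi_d here; build a state with controlled entries in layer 1
  st <- pool_state(g)
  st[1, "MIC"] <- 1
  st[1, "DOC"] <- 50
  xi1 <- mo$xi_total[1]
  r <- state_dependent_rates(st, p, mo)
  expect_equal(r$k_DOC[1], 10 * 1 / (50 * xi1 + 50))
  # worked example at xi = 1 exactly
  mo1 <- mo; mo1$xi_total <- rep(1, 20)
  expect_equal(state_dependent_rates(st, p, mo1)$k_DOC[1], 0.1)
  # no microbes, no uptake; saturation sends the per-capita rate to zero
  expect_equal(state_dependent_rates(pool_state(g), p, mo1)$k_DOC, rep(0, 20))
  st2 <- st; st2[1, "DOC"] <- 1e12
  expect_lt(state_dependent_rates(st2, p, mo1)$k_DOC[1], 1e-10)
})
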