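# global_analysis: flattening, proportional response, climate regressions,
# permutation importance.

# small site set with matching contexts from the shared world
world_contexts <- function(w) {
  lapply(seq_len(w$n_sites), function(i) site_context(w$grid, w$forcings[[i]]))
}

test_that("flattening an already-constant field is a no-op", {
  w <- fixture("world_tiny", function() generate_world(12, seed = 8,
                                                       "cue-dominant"))
  idx <- which(w$truth$feasible)[1:10]
  pm <- w$params[idx, , drop = FALSE]
  ctx <- world_contexts(w)[idx]
  obs <- w$truth$soc_top1m[idx]
  # make the transport column constant: deviation must be exactly 0
  pm[, "d_bio"] <- 2e-5
  r <- flatten_component_experiment(pm, ctx, "transport", obs)
  expect_equal(r$total_abs_deviation, 0, tolerance = 1e-10)
  expect_equal(r$delta_e, 0, tolerance = 1e-8)
  expect_error(flatten_component_experiment(pm, ctx, "bogus", obs), "arg")
})

test_that("input perturbation uses seeded two-standard-deviation coin flips", {
  w <- fixture("world_tiny", function() generate_world(12, seed = 8,
                                                       "cue-dominant"))
  idx <- which(w$truth$feasible)[1:10]
  pm <- w$params[idx, , drop = FALSE]
  ctx <- world_contexts(w)[idx]
  obs <- w$truth$soc_top1m[idx]
  r1 <- flatten_component_experiment(pm, ctx, "input", obs, seed = 3)
  r2 <- flatten_component_experiment(pm, ctx, "input", obs, seed = 3)
  expect_identical(r1$total_abs_deviation, r2$total_abs_deviation)
  r3 <- flatten_component_experiment(pm, ctx, "input", obs, seed = 4)
  expect_false(identical(r1$total_abs_deviation, r3$total_abs_deviation))
  expect_gt(r1$total_abs_deviation, 0)
})

test_that("ranking fidelity: the scenario's dominant component ranks first", {
  # cue-dominant world
  w <- world_small()
  idx <- which(w$truth$feasible)[1:40]
  rk <- rank_components(w$params[idx, , drop = FALSE],
                        world_contexts(w)[idx], w$truth$soc_top1m[idx],
                        seed = 11)
  expect_equal(rk$component[1], "CUE")
  expect_true(rk$delta_e[rk$component == "CUE"] > 0)

  # decomposability-dominant world
  wd <- fixture("world_decomp", function()
    generate_world(40, seed = 202, "decomp-dominant"))
  idxd <- which(wd$truth$feasible)
  rkd <- rank_components(wd$params[idxd, , drop = FALSE],
                         world_contexts(wd)[idxd],
                         wd$truth$soc_top1m[idxd], seed = 11)
  expect_equal(rkd$component[1], "decomposability")
})

test_that("proportional response passes through the origin and reports elasticity", {
  w <- fixture("world_tiny", function() generate_world(12, seed = 8,
                                                       "cue-dominant"))
  idx <- which(w$truth$feasible)[1:8]
  pm <- w$params[idx, , drop = FALSE]
  ctx <- world_contexts(w)[idx]
  curve <- proportional_response(pm, ctx, "CUE",
                                 lambda_grid = c(0.9, 0.95, 1, 1.05, 1.1))
  at1 <- curve[curve$lambda == 1, ]
  expect_equal(at1$soc_change_pct, 0, tolerance = 1e-10)
  expect_equal(at1$metric_change_pct, 0, tolerance = 1e-10)
  # in this priming-flavoured world SOC falls monotonically as CUE scales up
  expect_true(all(diff(curve$soc_change_pct) < 0))
  lam <- lambda_for_soc_change(curve, 2)
  expect_true(is.finite(lam) && lam < 1)
  expect_error(proportional_response(pm, ctx, "CUE", c(1.1, 1.2)), "span")
})

test_that("xi-climate regressions recover exact and noisy generating laws", {
  set.seed(12)
  mat <- runif(500, -5, 25)
  map <- runif(500, 200, 2000)
  xi <- exp(0.05 * mat - 2)
  # noiseless generating law: lm warns about a perfect fit, by design
  r <- suppressWarnings(xi_climate_regression(xi, mat, map))
  expect_equal(unname(r$mat_fit["alpha"]), 0.05, tolerance = 1e-10)
  expect_equal(unname(r$mat_fit["beta"]), -2, tolerance = 1e-10)
  expect_equal(unname(r$mat_fit["r_squared"]), 1, tolerance = 1e-10)

  # noise lowers R^2 but leaves the slope unbiased in expectation
  alphas <- vapply(1:40, function(s) {
    set.seed(s)
    xin <- exp(0.05 * mat - 2 + rnorm(500, 0, 0.3))
    f <- xi_climate_regression(xin, mat, map)
    f$mat_fit[["alpha"]]
  }, 1)
  expect_lt(abs(mean(alphas) - 0.05), 0.003)
  set.seed(1)
  xin <- exp(0.05 * mat - 2 + rnorm(500, 0, 0.3))
  expect_lt(xi_climate_regression(xin, mat, map)$mat_fit[["r_squared"]], 1)

  expect_error(xi_climate_regression(xi, rep(1, 500), map), "variance")

  # linear MAP form
  xi2 <- 0.0002 * map + 0.1
  r2 <- suppressWarnings(xi_climate_regression(xi2, mat, map))
  expect_equal(unname(r2$map_fit["alpha"]), 0.0002, tolerance = 1e-10)
})

# small trained predictor on synthetic covariate structure for PI tests
pi_fixture <- function() fixture("pi_fixture", function() {
  set.seed(21)
  w <- generate_world(150, seed = 301, "cue-dominant")
  free <- c("eta_DOC", "k_ML", "K_m_assim", "beta_root")
  Y <- w$params[, free]
  cfg <- network_config(hidden = c(32, 32), max_epochs = 500, patience = 120)
  pred <- train_parameter_network(w$covariates, Y, cfg, seed = 22)
  list(world = w, predictor = pred, y = Y)
})

test_that("permutation importance: generating categories dominate", {
  fx <- pi_fixture()
  pi_mat <- permutation_importance(fx$predictor, fx$world$covariates, fx$y,
                                   n_perm = 60, seed = 5)
  # eta_DOC is generated from soil-structural (and climatic) covariates;
  # geographic ones enter the trained map only as copula-correlated proxies
  expect_gt(pi_mat["soil_structural", "cue"], 1.3)
  expect_gt(pi_mat["soil_structural", "cue"], pi_mat["geographic", "cue"])
  expect_true(all(is.finite(pi_mat)))
  expect_error(permutation_importance(fx$predictor, fx$world$covariates,
                                      fx$y,
                                      categories = data.frame(
                                        variable = "nope", category = "x"),
                                      n_perm = 2),
               "empty")
})

test_that("a category the map provably ignores has PI exactly 1", {
  # hand-built linear predictor using only x1; x2 forms its own category
  pred <- structure(list(
    best_guess = list(layers = list(list(W = matrix(c(0.9, 0), 2, 1),
                                         b = 0))),
    ensemble = NULL,
    norm_x = list(lo = c(x1 = 0, x2 = 0), rng = c(x1 = 1, x2 = 1),
                  constant = c(FALSE, FALSE)),
    norm_y = list(lo = c(eta_DOC = 0.2), rng = c(eta_DOC = 0.4)),
    x_names = c("x1", "x2"), y_names = "eta_DOC"),
    class = "soilcue_predictor")
  X <- data.frame(site_id = c("a", "b", "c"), x1 = c(0, 0.5, 1),
                  x2 = c(0.3, 0.9, 0.1))
  Y <- cbind(eta_DOC = c(0.2, 0.4, 0.6))
  cats <- data.frame(variable = c("x1", "x2"),
                     category = c("used", "ignored"))
  pi_mat <- permutation_importance(pred, X, Y, categories = cats,
                                   n_perm = 25, seed = 3)
  expect_equal(unname(pi_mat["ignored", "cue"]), 1, tolerance = 1e-12)
  expect_gt(pi_mat["used", "cue"], 1)
})

test_that("PI Monte-Carlo error of a null category shrinks like 1/sqrt(n_perm)", {
  fx <- pi_fixture()
  spread <- vapply(c(5, 45), function(np) {
    reps <- vapply(1:6, function(s)
      permutation_importance(fx$predictor, fx$world$covariates, fx$y,
                             n_perm = np, seed = 100 + s)["geographic", "cue"],
      1)
    sd(reps)
  }, 1)
  expect_lt(spread[2], spread[1])
})

test_that("hand-computed two-site, one-parameter PI ratio", {
  # a linear one-weight "network" built by hand so the Eq.-style ratio can
  # be verified in closed form against the implementation
  pred <- structure(list(
    best_guess = list(layers = list(list(W = matrix(0.9), b = 0))),
    ensemble = NULL,
    norm_x = list(lo = c(x1 = 0), rng = c(x1 = 1), constant = FALSE),
    norm_y = list(lo = c(eta_DOC = 0.2), rng = c(eta_DOC = 0.4)),
    x_names = "x1", y_names = "eta_DOC"), class = "soilcue_predictor")
  X <- data.frame(site_id = c("a", "b"), x1 = c(0, 1))
  Y <- cbind(eta_DOC = c(0.2, 0.6))
  cats <- data.frame(variable = "x1", category = "only")
  pi_mat <- permutation_importance(pred, X, Y, categories = cats,
                                   n_perm = 40, seed = 9)
  # same draws, direct formula: Yn = (0, 1); intact pred = (0, 0.9)
  mse0 <- mean(c(0, (0.9 - 1)^2))
  set.seed(9)
  acc <- 0
  for (r in 1:40) {
    u <- runif(2)
    acc <- acc + mean((0.9 * u - c(0, 1))^2) / mse0
  }
  expect_equal(unname(pi_mat["only", "cue"]), acc / 40, tolerance = 1e-12)
})
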