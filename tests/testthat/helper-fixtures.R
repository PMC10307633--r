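# Shared fixtures, built lazily and cached for the whole run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

grid_clm <- function() fixture("grid_clm", function() make_layer_grid(20, "clm5"))
grid_uni <- function() fixture("grid_uni", function()
  make_layer_grid(20, "uniform", max_depth = 2))

forcings_temperate <- function(grid = grid_clm()) {
  site_forcings(npp = 500, temperature = 12, water = 0.6, grid = grid,
                mat = 12, map = 800)
}

# small cue-dominant world + profiles, shared across tests
world_small <- function() fixture("world_small", function()
  generate_world(60, seed = 101, "cue-dominant"))

# free-parameter mask used for scaled-down (desk-scale) assimilation:
# eta_DOC is the single profile-magnitude lever; the others are shape or
# litter parameters that do not trade off with it (see methods vignette)
recovery_free <- c("eta_DOC", "k_ML", "K_m_assim", "beta_root")

recovery_priors <- function(free = recovery_free) {
  priors <- default_prior_spec(free = free)
  base <- soilcue:::world_base_params()
  priors$value[match(names(base), priors$name)] <- base
  priors
}

# a noiseless profile generated from known free-parameter values theta,
# with every non-free parameter equal to the prior table value (so the
# assimilation model matches the generator exactly)
recovery_profile <- function(theta, priors, grid, seed) {
  set.seed(seed)
  v <- stats::setNames(priors$value, priors$name)
  v[names(theta)] <- theta
  p <- microbial_params(values = v)
  mat <- runif(1, 6, 18)
  map <- runif(1, 700, 1300)
  fc <- site_forcings(300 + 400 * plogis((mat - 8) / 6) * map / (map + 900),
                      mat + 1.5 * exp(-grid$node_depth / 0.5),
                      map / (map + 900), grid, mat = mat, map = map)
  ss <- steady_state(p, grid, fc)
  if (!isTRUE(attr(ss, "feasible"))) return(NULL)
  nl <- sample(4:8, 1)
  bounds <- sort(c(0, runif(nl - 1, 5, 145), 150))
  mineral <- rowSums(ss[, c("DOC", "MIC", "ENZ", "mSOC")])
  mid <- (bounds[-length(bounds)] + bounds[-1]) / 2 / 100
  obs <- approx(grid$node_depth, mineral, xout = mid, rule = 2)$y
  pr <- soc_profile(paste0("recov_", seed), bounds[-length(bounds)],
                    bounds[-1], obs / 1000, bd_g_cm3 = 1)
  pr$layers$stock_gC_m3 <- obs
  list(profile = pr, forcings = fc, truth = theta, state = ss)
}

# draw free-parameter truths from the central part of the priors
draw_recovery_truth <- function(priors, free = recovery_free, seed) {
  set.seed(seed)
  lo <- stats::setNames(priors$lower, priors$name)[free]
  hi <- stats::setNames(priors$upper, priors$name)[free]
  lo + (0.15 + 0.7 * runif(length(free))) * (hi - lo)
}
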