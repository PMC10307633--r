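# Synthetic world with known truth: correlated environmental covariates,
# smooth parameter-covariate dependence, derived forcings, true steady
# states, noisy layered SOC profiles and a meta-analysis table - everything
# the pipeline needs, fully seeded, no external data.

COVAR_CATEGORIES <- c("soil_structural", "soil_chemical", "climatic",
                      "vegetation", "geographic")

# 12 covariates per category, names like soilstruct_03
covariate_names <- function() {
  pre <- c(soil_structural = "soilstruct", soil_chemical = "soilchem",
           climatic = "climate", vegetation = "veg", geographic = "geo")
  unlist(lapply(pre, function(p) sprintf("%s_%02d", p, 1:12)),
         use.names = FALSE)
}

#' Covariate category table
#'
#' @return data.frame mapping each of the 60 covariate names to one of the
#'   five categories (soil structural, soil chemical, climatic, vegetation,
#'   geographic).
#' @export
covariate_categories <- function() {
  data.frame(variable = covariate_names(),
             category = rep(COVAR_CATEGORIES, each = 12),
             stringsAsFactors = FALSE)
}

# Base ("true fixed") parameter values of the synthetic world.  Chosen so
# that the steady state is feasible and the microbial-biomass fraction stays
# below 10 percent across the whole climate envelope; see the methods
# vignette for the reasoning.
world_base_params <- function() {
  c(a_MIC_ML = 0.25, a_MIC_CL = 0.20, a_MIC_LL = 0.25,
    a_DOC_ML = 0.35, a_DOC_CL = 0.35, a_mSOC_LL = 0.28,
    a_DOC_MIC = 0.30, a_mSOC_MIC = 0.10, eta_DOC = 0.38,
    v_max_assim = 45, K_m_assim = 800,
    k_MIC = 18, v_max_decom = 60, K_m_decom = 18000,
    q10 = 1.8, z_tau = 1.0, beta_root = 0.88, d_bio = 2e-5)
}

clamp_to_priors <- function(values, margin = 0.02) {
  defs <- param_definitions()
  lo <- stats::setNames(defs$lower, defs$name)
  hi <- stats::setNames(defs$upper, defs$name)
  for (nm in names(values)) {
    w <- hi[nm] - lo[nm]
    values[nm] <- min(max(values[nm], lo[nm] + margin * w),
                      hi[nm] - margin * w)
  }
  values
}

#' Generate a synthetic world
#'
#' Draws `n_sites` sites: 60 environmental covariates from a correlated
#' Gaussian copula mapped to `[0, 1]` (within-category correlation 0.5,
#' across 0.15); MAT and MAP derived from the first climatic covariates;
#' site forcings (NPP increasing with MAT and MAP, soil temperature damped
#' with depth, moisture from MAP); true parameters as bounded logistic
#' functions of designated covariates plus small noise; and the true steady
#' state per site.
#'
#' Scenarios shape which component varies across space:
#' * `"cue-dominant"`: the DOC-pathway CUE `eta_DOC` spans ~0.10-0.66,
#'   decreasing with MAT (cold sites more efficient) and increasing with
#'   the first soil-structural covariate; all other parameters carry only
#'   small noise.
#' * `"decomp-dominant"`: `K_m_decom` and `k_MIC` vary strongly with soil
#'   chemistry; CUE nearly uniform.
#' * `"neutral"`: all parameter fields carry only small noise.
#'
#' @param n_sites number of sites (>= 10).
#' @param seed integer seed; the world is bit-for-bit reproducible.
#' @param scenario one of `"cue-dominant"`, `"decomp-dominant"`, `"neutral"`.
#' @param grid layer grid shared by all sites.
#' @return object of class `soilcue_world`: list with `n_sites`,
#'   `covariates` (data.frame `site_id` + 60 columns), `categories`,
#'   `params` (n_sites x n_params matrix of true values), `forcings`
#'   (list), `truth` (list: `states`, `soc_top1m`, `feasible`), `grid`,
#'   `scenario`, `seed`.
#' @export
generate_world <- function(n_sites, seed, scenario = c("cue-dominant",
                                                       "decomp-dominant",
                                                       "neutral"),
                           grid = make_layer_grid(20, "clm5")) {
  scenario <- match.arg(scenario)
  if (n_sites < 10) stop("'n_sites' must be >= 10")
  set.seed(seed)

  # --- covariates: Gaussian copula, block correlation
  nv <- 60
  R <- matrix(0.15, nv, nv)
  for (b in 0:4) R[b * 12 + 1:12, b * 12 + 1:12] <- 0.5
  diag(R) <- 1
  L <- chol(R)
  U <- stats::pnorm(matrix(stats::rnorm(n_sites * nv), n_sites) %*% L)
  colnames(U) <- covariate_names()

  mat <- 5 + 14 * U[, "climate_01"]
  map <- 600 + 800 * U[, "climate_02"]

  # --- true parameter fields
  defs <- param_definitions()
  base <- world_base_params()
  pmat <- matrix(rep(microbial_params(values = base), n_sites),
                 n_sites, nrow(defs), byrow = TRUE,
                 dimnames = list(NULL, defs$name))
  # small field noise on the assimilated subset (0.5 percent of prior
  # range; d_bio gets 5 percent relative noise instead - absolute noise on
  # its wide prior range would swamp its small base value)
  free <- setdiff(defs$name[defs$free], "d_bio")
  wjit <- stats::setNames(defs$upper - defs$lower, defs$name)
  pmat[, free] <- pmat[, free] +
    matrix(stats::rnorm(n_sites * length(free)), n_sites) %*%
    diag(0.005 * wjit[free], length(free))
  pmat[, "d_bio"] <- pmat[, "d_bio"] * exp(stats::rnorm(n_sites, 0, 0.05))

  if (scenario == "cue-dominant") {
    lin <- -0.15 * (mat - 12) + 4.0 * (U[, "soilstruct_01"] - 0.5) +
      stats::rnorm(n_sites, 0, 0.25)
    pmat[, "eta_DOC"] <- 0.10 + 0.58 * stats::plogis(lin)
    # the litter-pathway growth fractions co-vary with the DOC-pathway CUE:
    # they belong to the same (cue) component field
    s_cue <- pmat[, "eta_DOC"] - 0.38
    pmat[, "a_MIC_ML"] <- 0.25 + 0.50 * s_cue
    pmat[, "a_MIC_CL"] <- 0.20 + 0.40 * s_cue
    pmat[, "a_MIC_LL"] <- 0.25 + 0.20 * s_cue
  } else if (scenario == "decomp-dominant") {
    pmat[, "K_m_decom"] <- 15000 *
      exp(0.50 * (U[, "soilchem_01"] - 0.5) +
            stats::rnorm(n_sites, 0, 0.03))
    pmat[, "k_MIC"] <- 18 * exp(0.10 * (U[, "soilchem_02"] - 0.5))
    pmat[, "eta_DOC"] <- 0.38 + 0.05 * (U[, "soilstruct_01"] - 0.5)
  } else {
    pmat[, "eta_DOC"] <- 0.38 + 0.05 * (U[, "soilstruct_01"] - 0.5)
  }
  for (i in seq_len(n_sites)) {
    pmat[i, ] <- clamp_to_priors(pmat[i, ])
  }

  # --- forcings
  npp <- 300 + 400 * stats::plogis((mat - 8) / 6) * map / (map + 900)
  forcings <- vector("list", n_sites)
  truth_states <- vector("list", n_sites)
  soc1 <- rep(NA_real_, n_sites)
  feas <- logical(n_sites)
  for (i in seq_len(n_sites)) {
    tz <- mat[i] + 1.5 * exp(-grid$node_depth / 0.5)
    wz <- rep(map[i] / (map[i] + 900), grid$n_layers)
    forcings[[i]] <- site_forcings(npp[i], tz, wz, grid,
                                   mat = mat[i], map = map[i])
    p <- microbial_params(values = pmat[i, ])
    ss <- steady_state(p, grid, forcings[[i]])
    feas[i] <- isTRUE(attr(ss, "feasible"))
    truth_states[[i]] <- ss
    if (feas[i]) soc1[i] <- soc_stock(ss, grid)
  }

  out <- list(
    n_sites = n_sites,
    covariates = data.frame(site_id = sprintf("site_%04d", seq_len(n_sites)),
                            U, stringsAsFactors = FALSE),
    categories = covariate_categories(),
    params = pmat,
    forcings = forcings,
    mat = mat, map = map, npp = npp,
    truth = list(states = truth_states, soc_top1m = soc1, feasible = feas),
    grid = grid, scenario = scenario, seed = seed
  )
  class(out) <- "soilcue_world"
  out
}

#' @export
print.soilcue_world <- function(x, ...) {
  cat("<soilcue_world> ", x$n_sites, " sites, scenario '", x$scenario,
      "', seed ", x$seed, ", ", sum(x$truth$feasible),
      " feasible\n", sep = "")
  invisible(x)
}

#' Generate noisy layered SOC profiles from a world
#'
#' Observation layers are randomized per site (`n_obs_layers` in 3-8, max
#' depth 1-2 m) and the observed layer stock is the true mineral-pool
#' density at the layer midpoint times lognormal multiplicative noise with
#' coefficient of variation `noise_cv` (mean-one correction applied, so
#' replicate means converge to truth).  A configurable fraction of sites
#' violates the QC rules (too few layers or too shallow) so the filter is
#' exercised.
#'
#' @param world a [generate_world()] world.
#' @param noise_cv observation noise CV (0 = exact).
#' @param seed integer seed.
#' @param qc_violation_rate fraction of sites generated in violation of the
#'   structural QC rules.
#' @return list of `soilcue_profile` with derived stocks (`stock_gC_m3` set
#'   directly from the noisy observations; `soc_gC_kg` back-filled with a
#'   unit bulk density so the schema stays complete).
#' @export
generate_profiles <- function(world, noise_cv = 0.1, seed = 1,
                              qc_violation_rate = 0) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  out <- vector("list", world$n_sites)
  for (i in seq_len(world$n_sites)) {
    violate <- stats::runif(1) < qc_violation_rate
    if (violate && stats::runif(1) < 0.5) {
      n_lay <- 2L
      max_d <- stats::runif(1, 100, 200)
    } else if (violate) {
      n_lay <- sample(3:8, 1)
      max_d <- stats::runif(1, 20, 50)
    } else {
      n_lay <- sample(3:8, 1)
      max_d <- stats::runif(1, 100, 200)
    }
    bounds <- sort(c(0, stats::runif(n_lay - 1, 5, max_d - 5), max_d))
    upper <- bounds[-length(bounds)]
    lower <- bounds[-1]
    state <- world$truth$states[[i]]
    mineral <- rowSums(state[, MINERAL_POOLS])
    mid_m <- (upper + lower) / 2 / 100
    truth <- stats::approx(world$grid$node_depth, mineral, xout = mid_m,
                           rule = 2)$y
    noise <- if (noise_cv > 0) {
      stats::rlnorm(n_lay, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, n_lay)
    obs <- truth * noise
    pr <- soc_profile(world$covariates$site_id[i], upper, lower,
                      soc_gC_kg = obs / 1000, bd_g_cm3 = 1)
    pr$layers$bd_used_g_cm3 <- 1
    pr$layers$stock_gC_m3 <- obs
    out[[i]] <- pr
  }
  names(out) <- world$covariates$site_id
  out
}

#' Generate a synthetic CUE-SOC meta-analysis table
#'
#' Emulates the statistical structure of a multi-study incubation
#' compilation: `SOC = b0 + b_cue CUE + b_mat MAT + b_depth depth + u_study
#' + eps`, with study random intercepts `u ~ N(0, tau^2)`, residual
#' `eps ~ N(0, sigma^2)`, CUE ~ U(0.1, 0.6) negatively correlated with MAT
#' through a Gaussian copula (target Pearson r about -0.24), depth sampled
#' from typical sampling depths and isotope method assigned per study.
#'
#' @param n_records number of CUE-SOC pairs (default 132).
#' @param n_studies number of source studies (default 16).
#' @param effects named list overriding `b0, b_cue, b_mat, b_depth, tau,
#'   sigma, r_cue_mat`.
#' @param seed integer seed.
#' @return data.frame of class `soilcue_meta` with columns `source_study,
#'   lon, lat, isotope_method, depth_cm, mat_C, cue, soc_gC_kg,
#'   mbc_gC_kg, non_mbc_gC_kg`.
#' @export
generate_meta_table <- function(n_records = 132, n_studies = 16,
                                effects = list(), seed = 1) {
  if (n_studies < 2) stop("'n_studies' must be >= 2")
  ef <- utils::modifyList(
    list(b0 = 18, b_cue = 40, b_mat = -0.3, b_depth = -0.15,
         tau = 10, sigma = 5, r_cue_mat = -0.24),
    effects)
  set.seed(seed)
  study <- sort(sample(seq_len(n_studies), n_records, replace = TRUE))
  # every study appears at least once
  study[seq_len(n_studies)] <- seq_len(n_studies)
  z <- matrix(stats::rnorm(2 * n_records), n_records)
  z2 <- ef$r_cue_mat * z[, 1] + sqrt(1 - ef$r_cue_mat^2) * z[, 2]
  cue <- 0.1 + 0.5 * stats::pnorm(z[, 1])
  mat <- -5 + 30 * stats::pnorm(z2)
  depth <- sample(c(5, 10, 15, 20, 30), n_records, replace = TRUE)
  u <- stats::rnorm(n_studies, 0, ef$tau)
  soc <- ef$b0 + ef$b_cue * cue + ef$b_mat * mat + ef$b_depth * depth +
    u[study] + stats::rnorm(n_records, 0, ef$sigma)
  soc <- pmax(soc, 0.5)
  iso <- ifelse(seq_len(n_studies) %% 3 == 0, "18O", "13C/14C")[study]
  mbc <- pmax(0.015 * soc * (0.5 + cue) +
                stats::rnorm(n_records, 0, 0.05), 0.01)
  out <- data.frame(
    source_study = sprintf("study_%02d", study),
    lon = stats::runif(n_records, -180, 180),
    lat = stats::runif(n_records, -55, 70),
    isotope_method = iso, depth_cm = depth, mat_C = mat, cue = cue,
    soc_gC_kg = soc, mbc_gC_kg = mbc, non_mbc_gC_kg = pmax(soc - mbc, 0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("soilcue_meta", "data.frame")
  attr(out, "effects") <- ef
  out
}

#' Write the synthetic world's delimited-text files
#'
#' Emits the profile CSV, covariate CSV (+ category sidecar), forcing CSV
#' and meta CSV in the package's standard schemas.
#'
#' @param world a world; profiles and meta table generated with the given
#'   seeds.
#' @param dir output directory (created if needed).
#' @param noise_cv observation noise for the profile file.
#' @param seed seed for profiles and the meta table.
#' @return invisibly, the vector of files written.
#' @export
write_world <- function(world, dir, noise_cv = 0.1, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- character()
  profiles <- generate_profiles(world, noise_cv = noise_cv, seed = seed)
  f[1] <- file.path(dir, "profiles.csv")
  write_profiles(profiles, f[1])
  f[2] <- file.path(dir, "covariates.csv")
  utils::write.csv(world$covariates, f[2], row.names = FALSE)
  f[3] <- file.path(dir, "covariate_categories.csv")
  utils::write.csv(world$categories, f[3], row.names = FALSE)
  fr <- data.frame(site_id = world$covariates$site_id,
                   npp_gC_m2_yr = world$npp, mat_C = world$mat,
                   map_mm_yr = world$map)
  f[4] <- file.path(dir, "forcings.csv")
  utils::write.csv(fr, f[4], row.names = FALSE)
  f[5] <- file.path(dir, "meta_table.csv")
  utils::write.csv(generate_meta_table(seed = seed), f[5], row.names = FALSE)
  f[6] <- file.path(dir, "true_parameters.csv")
  utils::write.csv(cbind(site_id = world$covariates$site_id,
                         as.data.frame(world$params)), f[6],
                   row.names = FALSE)
  invisible(f)
}
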