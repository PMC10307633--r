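# System-level component summaries: the layered model state collapsed into
# seven scalars (CUE_system, T_system, K_system, V_system, xi_system,
# B_system, input I) used for maps, rankings and sensitivity analyses.

# Per-layer litter uptake fluxes entering microbial metabolism and the DOC
# assimilation flux (gC m^-3 yr^-1); shared by cue_system and profile cost.
uptake_fluxes <- function(state, params, modifier) {
  p <- params
  xi <- modifier$xi_total
  litter <- cbind(
    ML = p[["k_ML"]] * state[, "ML"] * (1 - p[["a_DOC_ML"]]) * xi,
    CL = p[["k_CL"]] * state[, "CL"] * (1 - p[["a_DOC_CL"]]) * xi,
    LL = p[["k_LL"]] * state[, "LL"] * (1 - p[["a_mSOC_LL"]]) * xi
  )
  doc <- p[["v_max_assim"]] * xi * state[, "MIC"] * state[, "DOC"] /
    (p[["K_m_assim"]] * xi + state[, "DOC"])
  list(litter = litter, doc = doc)
}

#' System-level carbon use efficiency
#'
#' Flux-weighted CUE over the three litter assimilation pathways and the DOC
#' assimilation pathway: microbial biomass production divided by total
#' substrate uptake, each layer-integrated with the layer thickness.
#'
#' @param state_ss steady-state pool state.
#' @param params parameter vector.
#' @param modifier environmental modifier profile.
#' @param grid layer grid.
#' @return scalar in `[min(eta), max(eta)]` of the four pathway CUEs.
#' @export
cue_system <- function(state_ss, params, modifier, grid) {
  eta <- pool_cue_values(params)
  up <- uptake_fluxes(state_ss, params, modifier)
  dz <- grid$thickness
  uptake_lit <- colSums(up$litter * dz)
  uptake_doc <- sum(up$doc * dz)
  denom <- sum(uptake_lit) + uptake_doc
  if (denom <= 0) stop("cue_system undefined: zero total microbial uptake")
  num <- sum(uptake_lit * eta[c("eta_ML", "eta_CL", "eta_LL")]) +
    uptake_doc * eta[["eta_DOC"]]
  unname(num / denom)
}

#' Top-of-column SOC stock
#'
#' Depth-integrated mineral-soil carbon (DOC + MIC + ENZ + mSOC) down to
#' `depth` (default 1 m), in kgC m^-2; partial overlap with the boundary
#' layer is weighted by the overlapping thickness.
#'
#' @param state pool state (gC m^-3).
#' @param grid layer grid.
#' @param depth integration depth, m.
#' @param pools columns to integrate; defaults to the four mineral pools.
#' @return scalar, kgC m^-2.
#' @export
soc_stock <- function(state, grid, depth = 1, pools = MINERAL_POOLS) {
  upper <- grid$interface_depth[-(grid$n_layers + 1)]
  w <- pmin(pmax(depth - upper, 0), grid$thickness)
  sum(state[, pools, drop = FALSE] * w) / 1000
}

#' All seven system-level component metrics
#'
#' * `cue_system`: see [cue_system()].
#' * `t_system`: sum of the non-microbial (non-CUE) transfer fractions of
#'   the A matrix, each weighted by its donor's share of the total
#'   decomposition flux.
#' * `k_system`: pool-size-weighted mean baseline decomposition rate of the
#'   litter pools plus that of the mineral pools (MIC, ENZ, mSOC), the two
#'   groups normalized separately as printed; `variant = "single"` gives the
#'   single-normalization alternative over all seven pools.
#' * `v_system`: per-layer vertical transport rate (diagonal outflow rate of
#'   the transport operator, yr^-1) weighted by the litter carbon it moves.
#' * `xi_system`: `xi_T xi_W xi_D` (nutrient term excluded) weighted by
#'   layer carbon.
#' * `b_system`: `[sum_z exp(ln(1 - Y_z) / D_z) / n]^5` with `Y_z` the
#'   cumulative input-allocation fraction above node depth `D_z` in cm - the
#'   fraction of plant input allocated below 5 cm, equal to `beta_root^5`
#'   under the asymptotic root law.
#' * `input_I`: the plant carbon input (gC m^-2 yr^-1).
#'
#' @inheritParams cue_system
#' @param forcings site forcings.
#' @param variant `"two-term"` (printed form, default) or `"single"` for
#'   `k_system` normalization.
#' @return object of class `soilcue_metrics`: named list of the seven
#'   scalars.
#' @export
component_system_metrics <- function(state_ss, params, modifier, grid,
                                     forcings,
                                     variant = c("two-term", "single")) {
  variant <- match.arg(variant)
  p <- params
  dz <- grid$thickness
  xi <- modifier$xi_total
  k <- all_rates(state_ss, params, modifier)
  if (all(state_ss <= 0)) stop("system metrics undefined: empty pool state")

  # T_system: flux-weighted non-CUE transfer
  t_out <- c(CWD = p[["a_CL_CWD"]] + p[["a_LL_CWD"]],
             ML = p[["a_DOC_ML"]], CL = p[["a_DOC_CL"]], LL = p[["a_mSOC_LL"]],
             DOC = 0,
             MIC = p[["a_DOC_MIC"]] + p[["a_ENZ_MIC"]] + p[["a_mSOC_MIC"]],
             ENZ = 1, mSOC = p[["a_DOC_mSOC"]])
  flux_j <- colSums(state_ss * k * xi * dz)        # per donor pool
  t_system <- sum(t_out[POOLS] * flux_j) / sum(flux_j)

  # K_system: pool-weighted baseline rates
  pool_mass <- colSums(state_ss * dz)
  kbar <- colSums(k * state_ss * dz) / ifelse(pool_mass > 0, pool_mass, 1)
  lit <- LITTER_POOLS
  soil <- c("MIC", "ENZ", "mSOC")
  if (variant == "two-term") {
    k_system <- sum(kbar[lit] * pool_mass[lit]) / sum(pool_mass[lit]) +
      sum(kbar[soil] * pool_mass[soil]) / sum(pool_mass[soil])
  } else {
    grp <- c(lit, soil)
    k_system <- sum(kbar[grp] * pool_mass[grp]) / sum(pool_mass[grp])
  }

  # V_system: the transport operator moves litter pools only, so the
  # vertical movement rate is weighted by the carbon it acts on (litter);
  # xi_system is weighted by total layer carbon
  layer_mass <- rowSums(state_ss) * dz
  litter_mass <- rowSums(state_ss[, LITTER_POOLS, drop = FALSE]) * dz
  v_z <- -diag(transport_block(p[["d_bio"]], grid))
  v_system <- sum(v_z * litter_mass) / sum(litter_mass)
  xi_swd <- modifier$xi_t * modifier$xi_w * modifier$xi_d
  xi_system <- sum(xi_swd * layer_mass) / sum(layer_mass)

  # B_system from the cumulative allocation fractions at node depths (cm);
  # log(1 - Y_z) is evaluated in log space (beta^d underflows at the deep
  # nodes of the exponential grid)
  d_cm <- grid$node_depth * 100
  log1m_y <- d_cm * log(p[["beta_root"]])
  b_system <- (mean(exp(log1m_y / d_cm)))^5

  out <- list(cue_system = cue_system(state_ss, params, modifier, grid),
              t_system = unname(t_system), k_system = unname(k_system),
              v_system = unname(v_system), xi_system = unname(xi_system),
              b_system = unname(b_system), input_I = forcings$npp)
  class(out) <- c("soilcue_metrics", "list")
  out
}

#' @export
print.soilcue_metrics <- function(x, ...) {
  cat("<soilcue_metrics>\n")
  print(round(unlist(x), 4))
  invisible(x)
}

#' Documented parameter regions for the three CUE-SOC regimes
#'
#' Named list of parameter overrides under which a CUE sweep produces a
#' positive, null or negative steady-state CUE-SOC relationship:
#' * `"positive"`: no direct litter-to-mSOC bypass and slow microbial
#'   turnover, so mineral SOC forms from necromass whose flux grows with
#'   CUE (entombing-dominated).
#' * `"negative"`: strong lignin-to-mSOC bypass with fast microbial and
#'   enzyme turnover and little necromass stabilization, so a higher CUE
#'   mainly builds enzymes that decompose the bypass-derived mSOC
#'   (priming-dominated).
#' * `"null"`: a weak lignin bypass balancing necromass gain against
#'   enzymatic (priming) loss, so the steady-state stock is nearly
#'   CUE-invariant over the sweep.
#'
#' @return named list of override vectors for [microbial_params()].
#' @export
regime_presets <- function() {
  list(
    positive = c(a_mSOC_LL = 0, a_MIC_LL = 0.4, k_MIC = 3,
                 a_mSOC_MIC = 0.42, v_max_decom = 30),
    negative = c(v_max_assim = 45, a_mSOC_MIC = 0.1, a_mSOC_LL = 0.2,
                 v_max_decom = 60, k_MIC = 14, k_ENZ = 4),
    null = c(a_mSOC_LL = 0.065, a_MIC_LL = 0.4, k_MIC = 14,
             v_max_assim = 45, a_mSOC_MIC = 0.42)
  )
}

#' Classify the CUE-SOC relationship of a parameter regime
#'
#' Sweeps the DOC-pathway CUE (`eta_DOC`) over `cue_grid` holding all other
#' parameters fixed, computes the steady-state top-1 m SOC stock at each
#' value, and classifies the relationship by the sign of the Spearman rank
#' correlation with a dead band: `|rho| < dead_band` is `"null"`.
#' Infeasible steady states along the sweep are excluded and reported.
#'
#' @param param_base base parameter vector.
#' @param cue_grid CUE values in (0, 1).
#' @param grid layer grid.
#' @param forcings site forcings.
#' @param dead_band Spearman dead band for the null class (default 0.2).
#' @return list with `relationship` (`"negative" | "null" | "positive"`),
#'   `rho`, `curve` (data.frame cue, soc_top1m_kgC_m2, feasible) and
#'   `n_excluded`.
#' @export
classify_cue_soc_regime <- function(param_base, cue_grid, grid, forcings,
                                    dead_band = 0.2) {
  if (any(cue_grid <= 0 | cue_grid >= 1)) stop("'cue_grid' must lie in (0, 1)")
  soc <- rep(NA_real_, length(cue_grid))
  feas <- logical(length(cue_grid))
  for (i in seq_along(cue_grid)) {
    pp <- param_base
    pp[["eta_DOC"]] <- cue_grid[i]
    ss <- steady_state(pp, grid, forcings)
    feas[i] <- isTRUE(attr(ss, "feasible"))
    if (feas[i]) soc[i] <- soc_stock(ss, grid)
  }
  if (sum(feas) < 3) {
    stop("CUE-SOC regime undefined: fewer than 3 feasible sweep points")
  }
  rho <- stats::cor(cue_grid[feas], soc[feas], method = "spearman")
  relationship <- if (abs(rho) < dead_band) "null" else {
    if (rho > 0) "positive" else "negative"
  }
  list(relationship = relationship, rho = unname(rho),
       curve = data.frame(cue = cue_grid, soc_top1m_kgC_m2 = soc,
                          feasible = feas),
       n_excluded = sum(!feas))
}

#' Write a site metrics table
#'
#' Long-format delimited text: one row per site with the seven system
#' metrics and the top-1 m SOC stock.
#'
#' @param metrics_list named list (by site id) of `soilcue_metrics`.
#' @param soc_top1m numeric vector of top-1 m stocks (kgC m^-2), same order.
#' @param file output CSV path.
#' @export
write_metrics_table <- function(metrics_list, soc_top1m, file) {
  df <- do.call(rbind, lapply(metrics_list, function(m) as.data.frame(m)))
  df <- cbind(site = names(metrics_list), df,
              soc_top1m_kgC_m2 = soc_top1m)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
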