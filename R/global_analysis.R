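# Component sensitivity analyses and the grouped permutation-importance
# analysis: which of the seven model components controls SOC storage and
# its spatial variation, and which covariate categories inform which
# components.

# user-facing component names -> parameter-table component labels
COMPONENTS <- c(CUE = "cue", transfer = "transfer",
                decomposability = "decomposability",
                environment = "environment", allocation = "allocation",
                transport = "transport", input = "input")

component_param_names <- function(component) {
  defs <- param_definitions()
  lab <- COMPONENTS[[component]]
  defs$name[defs$component == lab]
}

# steady-state top-1 m SOC for a matrix of per-site parameters
soc_field <- function(param_matrix, contexts, base_params = microbial_params()) {
  n <- nrow(param_matrix)
  soc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- base_params
    p[colnames(param_matrix)] <- param_matrix[i, ]
    ss <- steady_state(p, contexts[[i]]$grid, contexts[[i]]$forcings,
                       input_split = contexts[[i]]$input_split)
    if (isTRUE(attr(ss, "feasible"))) {
      soc[i] <- soc_stock(ss, contexts[[i]]$grid)
    }
  }
  soc
}

#' Spatial-flattening sensitivity experiment for one component
#'
#' Replaces the per-site parameters of one component with their across-site
#' means (spatially invariant counterpart) while all other parameters keep
#' their site-specific values, recomputes steady-state SOC, and reports the
#' total absolute deviation from the best (unflattened) field together with
#' the drop in explained variation.  The plant carbon input is a forcing,
#' not a parameter: for `component = "input"` each site's input is
#' perturbed by plus or minus two across-site standard deviations (seeded
#' coin flip per site, floored at 5 percent of the original input).
#'
#' @param param_matrix per-site optimized parameters (sites x named
#'   columns), e.g. assimilation posterior means or network predictions.
#' @param contexts list of [site_context()] per site.
#' @param component one of `"CUE", "transfer", "decomposability",
#'   "environment", "allocation", "transport", "input"`.
#' @param observed observed (or synthetic-truth) top-1 m stocks for the
#'   explained-variation score.
#' @param base_params template for parameters not in `param_matrix`.
#' @param seed seed for the input coin flips.
#' @return list of class `soilcue_flatten`: `component`,
#'   `total_abs_deviation` (kgC m^-2 summed over sites), `e_before`,
#'   `e_after`, `delta_e`, `per_site` (data.frame), `n_infeasible`.
#' @export
flatten_component_experiment <- function(param_matrix, contexts, component,
                                         observed,
                                         base_params = microbial_params(),
                                         seed = 1) {
  component <- match.arg(component, names(COMPONENTS))
  soc_best <- soc_field(param_matrix, contexts, base_params)

  flat <- param_matrix
  contexts_flat <- contexts
  if (component == "input") {
    npp <- vapply(contexts, function(ct) ct$forcings$npp, 1)
    set.seed(seed)
    sgn <- sample(c(-1, 1), length(contexts), replace = TRUE)
    npp_pert <- pmax(npp + sgn * 2 * stats::sd(npp), 0.05 * npp)
    for (i in seq_along(contexts_flat)) {
      contexts_flat[[i]]$forcings$npp <- npp_pert[i]
    }
  } else {
    cols <- intersect(component_param_names(component), colnames(flat))
    # a component with no columns in the matrix is already spatially
    # constant (e.g. under a reduced assimilation mask): deviation is 0 by
    # construction
    if (length(cols)) {
      flat[, cols] <- matrix(colMeans(flat[, cols, drop = FALSE]),
                             nrow(flat), length(cols), byrow = TRUE)
    }
  }
  soc_flat <- soc_field(flat, contexts_flat, base_params)

  ok <- is.finite(soc_best) & is.finite(soc_flat) & is.finite(observed)
  e_before <- coefficient_of_efficiency(observed[ok], soc_best[ok])
  e_after <- coefficient_of_efficiency(observed[ok], soc_flat[ok])
  out <- list(component = component,
              total_abs_deviation = sum(abs(soc_flat[ok] - soc_best[ok])),
              e_before = e_before, e_after = e_after,
              delta_e = e_before - e_after,
              per_site = data.frame(soc_best = soc_best, soc_flat = soc_flat),
              n_infeasible = sum(!ok))
  class(out) <- "soilcue_flatten"
  out
}

#' Flatten all seven components and rank them
#'
#' @inheritParams flatten_component_experiment
#' @return data.frame (one row per component, sorted by decreasing total
#'   absolute deviation) with `component`, `total_abs_deviation`,
#'   `e_before`, `e_after`, `delta_e`, `n_infeasible`.
#' @export
rank_components <- function(param_matrix, contexts, observed,
                            base_params = microbial_params(), seed = 1) {
  rows <- lapply(names(COMPONENTS), function(cp) {
    r <- flatten_component_experiment(param_matrix, contexts, cp, observed,
                                      base_params, seed)
    data.frame(component = cp, total_abs_deviation = r$total_abs_deviation,
               e_before = r$e_before, e_after = r$e_after,
               delta_e = r$delta_e, n_infeasible = r$n_infeasible)
  })
  out <- do.call(rbind, rows)
  out[order(-out$total_abs_deviation), ]
}

#' Proportional-response curve of one component
#'
#' Scales all parameters of a component by each factor in `lambda_grid`
#' (clipping to prior bounds, flagged), recomputes the steady state at
#' every site, and reports the relative change of total SOC and of the
#' component's system-level metric against the unscaled (`lambda = 1`)
#' reference.
#'
#' @inheritParams flatten_component_experiment
#' @param lambda_grid scale factors; must include values spanning 1.
#' @return data.frame of class `soilcue_response`: `lambda`,
#'   `soc_change_pct`, `metric_change_pct`, `n_feasible`, `clipped`.
#' @export
proportional_response <- function(param_matrix, contexts, component,
                                  lambda_grid = seq(0.9, 1.1, by = 0.025),
                                  base_params = microbial_params()) {
  component <- match.arg(component, setdiff(names(COMPONENTS), "input"))
  if (min(lambda_grid) > 1 || max(lambda_grid) < 1) {
    stop("'lambda_grid' must span 1")
  }
  cols <- intersect(component_param_names(component), colnames(param_matrix))
  defs <- param_definitions()
  lo <- stats::setNames(defs$lower, defs$name)[cols]
  hi <- stats::setNames(defs$upper, defs$name)[cols]
  metric_name <- c(CUE = "cue_system", transfer = "t_system",
                   decomposability = "k_system", environment = "xi_system",
                   allocation = "b_system", transport = "v_system")[[component]]

  eval_at <- function(lam) {
    pm <- param_matrix
    scaled <- sweep(pm[, cols, drop = FALSE], 2, lam, `*`)
    clip <- sweep(scaled, 2, lo, `<`) | sweep(scaled, 2, hi, `>`)
    scaled <- sweep(sweep(scaled, 2, lo, pmax), 2, hi, pmin)
    pm[, cols] <- scaled
    soc <- met <- rep(NA_real_, nrow(pm))
    for (i in seq_len(nrow(pm))) {
      p <- base_params
      p[colnames(pm)] <- pm[i, ]
      ct <- contexts[[i]]
      ss <- steady_state(p, ct$grid, ct$forcings,
                         input_split = ct$input_split)
      if (isTRUE(attr(ss, "feasible"))) {
        soc[i] <- soc_stock(ss, ct$grid)
        mo <- environmental_modifier(ct$forcings, p, ct$grid)
        met[i] <- unlist(component_system_metrics(ss, p, mo, ct$grid,
                                                  ct$forcings))[metric_name]
      }
    }
    list(soc = soc, met = met, clipped = any(clip))
  }

  ref <- eval_at(1)
  ok0 <- is.finite(ref$soc)
  if (!any(ok0)) stop("all sites infeasible at lambda = 1")
  rows <- lapply(lambda_grid, function(lam) {
    r <- eval_at(lam)
    ok <- ok0 & is.finite(r$soc)
    data.frame(
      lambda = lam,
      soc_change_pct = 100 * (sum(r$soc[ok]) / sum(ref$soc[ok]) - 1),
      metric_change_pct = 100 * (mean(r$met[ok]) / mean(ref$met[ok]) - 1),
      n_feasible = sum(ok), clipped = r$clipped)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("soilcue_response", "data.frame")
  out
}

#' Interpolate the scale factor achieving a target SOC change
#'
#' Inverse linear interpolation on a [proportional_response()] curve, e.g.
#' the lambda at which total SOC rises by 10 percent.
#'
#' @param curve response curve.
#' @param target_pct target SOC change in percent.
#' @return interpolated lambda (NA when outside the curve's range).
#' @export
lambda_for_soc_change <- function(curve, target_pct = 10) {
  o <- order(curve$soc_change_pct)
  stats::approx(curve$soc_change_pct[o], curve$lambda[o],
                xout = target_pct, ties = "ordered")$y
}

#' Climate regressions of the system-level environmental modifier
#'
#' Ordinary least squares on the two stated forms:
#' `log(xi_system) = alpha * MAT + beta` and `xi_system = alpha * MAP +
#' beta`.
#'
#' @param xi_system per-site system-level modifier (> 0 for the log form).
#' @param mat,map per-site mean annual temperature (degC) and
#'   precipitation (mm yr^-1).
#' @return list with `mat_fit` and `map_fit`, each `c(alpha, beta,
#'   r_squared)`.
#' @export
xi_climate_regression <- function(xi_system, mat, map) {
  ok <- is.finite(xi_system) & xi_system > 0
  if (sum(ok) < 3) stop("need at least 3 finite sites")
  if (stats::var(mat[ok]) == 0 || stats::var(map[ok]) == 0) {
    stop("zero predictor variance")
  }
  f1 <- stats::lm(log(xi_system[ok]) ~ mat[ok])
  f2 <- stats::lm(xi_system[ok] ~ map[ok])
  pack <- function(f) c(alpha = unname(stats::coef(f)[2]),
                        beta = unname(stats::coef(f)[1]),
                        r_squared = summary(f)$r.squared)
  list(mat_fit = pack(f1), map_fit = pack(f2))
}

#' Grouped permutation importance of covariate categories
#'
#' For each covariate category, its (normalized) columns are replaced by
#' uniform random values on `[0, 1]` (`mode = "uniform"`, as stated; a
#' column-shuffle mode is available for comparison) and the best-guess
#' network re-predicts all sites.  The component-grouped mean squared error
#' against the data-assimilation parameter values, on the normalized scale,
#' is compared with the intact prediction:
#' `PI = MSE_permuted / MSE_intact`, averaged over `n_perm` repetitions.
#'
#' @param predictor trained [train_parameter_network()] best-guess model.
#' @param covariates covariate table used for prediction.
#' @param y_da matrix of site parameter values from data assimilation
#'   (columns matching the predictor's targets).
#' @param categories data.frame `variable, category`
#'   (default [covariate_categories()]).
#' @param n_perm permutation repetitions (1000 in the full protocol).
#' @param seed integer seed.
#' @param mode `"uniform"` or `"shuffle"`.
#' @return matrix of PI values, categories x model components.
#' @export
permutation_importance <- function(predictor, covariates, y_da,
                                   categories = covariate_categories(),
                                   n_perm = 1000, seed = 1,
                                   mode = c("uniform", "shuffle")) {
  mode <- match.arg(mode)
  set.seed(seed)
  X <- as.matrix(covariates[, predictor$x_names, drop = FALSE])
  Xn <- sweep(sweep(X, 2, predictor$norm_x$lo), 2, predictor$norm_x$rng, `/`)
  Y <- as.matrix(y_da)[, predictor$y_names, drop = FALSE]
  Yn <- sweep(sweep(Y, 2, predictor$norm_y$lo), 2, predictor$norm_y$rng, `/`)

  defs <- param_definitions()
  comp_of <- stats::setNames(defs$component, defs$name)[predictor$y_names]
  comps <- unique(comp_of)

  fwd <- function(Xn_) {
    fw <- mlp_forward(predictor$best_guess$layers, Xn_)
    fw$acts[[length(fw$acts)]]
  }
  grouped_mse <- function(pred) {
    vapply(comps, function(cp) {
      j <- which(comp_of == cp)
      mean((pred[, j, drop = FALSE] - Yn[, j, drop = FALSE])^2)
    }, 1)
  }
  mse0 <- grouped_mse(fwd(Xn))
  if (any(mse0 == 0)) stop("intact MSE is zero: PI undefined")

  cats <- unique(categories$category)
  pi_mat <- matrix(NA_real_, length(cats), length(comps),
                   dimnames = list(cats, comps))
  for (ct in cats) {
    cols <- which(predictor$x_names %in%
                    categories$variable[categories$category == ct])
    if (!length(cols)) stop("empty covariate category: ", ct)
    acc <- 0
    for (r in seq_len(n_perm)) {
      Xp <- Xn
      if (mode == "uniform") {
        Xp[, cols] <- stats::runif(nrow(Xn) * length(cols))
      } else {
        for (j in cols) Xp[, j] <- Xp[sample(nrow(Xn)), j]
      }
      acc <- acc + grouped_mse(fwd(Xp)) / mse0
    }
    pi_mat[ct, ] <- acc / n_perm
  }
  pi_mat
}
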