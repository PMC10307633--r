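# Neural-network generalization of site-level posterior-mean parameters
# over environmental covariate space: a fully connected multilayer
# perceptron with ReLU activations, dropout, Adadelta optimization and the
# composite L1 x L2 (ratio loss x mean squared error) objective, trained on
# min-max normalized inputs and targets.  Implemented directly on BLAS
# matrix operations; no external deep-learning dependency.

#' Network configuration
#'
#' @param hidden hidden layer sizes (default the full 256, 512, 512, 256
#'   architecture; tests use smaller settings).
#' @param dropout dropout fraction per hidden layer (0.2).
#' @param batch_size minibatch size (32).
#' @param max_epochs training epoch cap (6000 in the full protocol).
#' @param val_frac validation fraction of each training run (0.1).
#' @param bootstrap_reps bootstrap ensemble size for uncertainty (200 in the
#'   full protocol; scale down for tests).
#' @param rho,eps_adadelta Adadelta decay and stabilizer.
#' @param patience epochs without validation improvement before stopping.
#' @param denom_floor ratio-loss denominator floor on the normalized scale.
#' @return list of class `soilcue_net_config`.
#' @export
network_config <- function(hidden = c(256, 512, 512, 256), dropout = 0.2,
                           batch_size = 32, max_epochs = 6000,
                           val_frac = 0.1, bootstrap_reps = 200,
                           rho = 0.95, eps_adadelta = 1e-6,
                           patience = 200, denom_floor = 1e-3) {
  stopifnot(all(hidden > 0), dropout >= 0, dropout < 1)
  cfg <- list(hidden = hidden, dropout = dropout, batch_size = batch_size,
              max_epochs = max_epochs, val_frac = val_frac,
              bootstrap_reps = bootstrap_reps, rho = rho,
              eps_adadelta = eps_adadelta, patience = patience,
              denom_floor = denom_floor)
  class(cfg) <- "soilcue_net_config"
  cfg
}

#' Composite L1 x L2 training loss
#'
#' `loss = RL * MSE` with the ratio loss `RL = mean |(true - pred) / true|`
#' (denominator floored at `denom_floor` in absolute value: targets are
#' min-max normalized, so values near zero occur) and
#' `MSE = mean (true - pred)^2`, both means over all `N = rows x params`
#' entries.
#'
#' @param pred,true numeric matrices of equal shape (normalized scale).
#' @param denom_floor ratio-loss denominator floor.
#' @return scalar loss.
#' @export
composite_loss <- function(pred, true, denom_floor = 1e-3) {
  if (!all(dim(pred) == dim(true))) stop("'pred' and 'true' shapes differ")
  den <- pmax(abs(true), denom_floor)
  rl <- mean(abs((true - pred) / den))
  mse <- mean((true - pred)^2)
  rl * mse
}

# --- minimal MLP machinery ------------------------------------------------

mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  lapply(seq_len(length(sizes) - 1), function(l) {
    # He initialization for the ReLU layers
    sd <- sqrt(2 / sizes[l])
    list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sd),
                    sizes[l], sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  })
}

mlp_forward <- function(layers, X, dropout = 0, train = FALSE) {
  L <- length(layers)
  acts <- vector("list", L + 1)
  masks <- vector("list", L)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(acts[[l]]), length(layers[[l]]$b),
             byrow = TRUE)
    if (l < L) {
      Z <- pmax(Z, 0)
      if (train && dropout > 0) {
        m <- matrix(stats::rbinom(length(Z), 1, 1 - dropout) / (1 - dropout),
                    nrow(Z), ncol(Z))
        Z <- Z * m
        masks[[l]] <- m
      }
    }
    acts[[l + 1]] <- Z
  }
  list(acts = acts, masks = masks)
}

# gradient of composite loss wrt predictions
composite_loss_grad <- function(pred, true, denom_floor) {
  den <- pmax(abs(true), denom_floor)
  n <- length(true)
  rl <- mean(abs((true - pred) / den))
  mse <- mean((true - pred)^2)
  d_rl <- sign(pred - true) / den / n
  d_mse <- 2 * (pred - true) / n
  rl * d_mse + mse * d_rl
}

mlp_backward <- function(layers, fw, grad_out, dropout) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- grad_out
  for (l in rev(seq_len(L))) {
    A <- fw$acts[[l]]
    grads[[l]] <- list(W = crossprod(A, delta), b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(layers[[l]]$W)
      act <- fw$acts[[l]]
      delta <- delta * (act > 0)
      if (dropout > 0 && !is.null(fw$masks[[l - 1]])) {
        delta <- delta * fw$masks[[l - 1]]
      }
    }
  }
  grads
}

# Adadelta state update (in place on the state list)
adadelta_step <- function(layers, grads, state, rho, eps) {
  for (l in seq_along(layers)) {
    for (nm in c("W", "b")) {
      g <- grads[[l]][[nm]]
      state[[l]][[nm]]$Eg <- rho * state[[l]][[nm]]$Eg + (1 - rho) * g^2
      dx <- -sqrt(state[[l]][[nm]]$Edx + eps) /
        sqrt(state[[l]][[nm]]$Eg + eps) * g
      state[[l]][[nm]]$Edx <- rho * state[[l]][[nm]]$Edx + (1 - rho) * dx^2
      layers[[l]][[nm]] <- layers[[l]][[nm]] + dx
    }
  }
  list(layers = layers, state = state)
}

mlp_train_once <- function(X, Y, cfg, seed, val_idx = NULL) {
  set.seed(seed)
  n <- nrow(X)
  if (is.null(val_idx)) {
    val_idx <- sample(n, max(1, round(cfg$val_frac * n)))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  layers <- mlp_init(ncol(X), cfg$hidden, ncol(Y))
  state <- lapply(layers, function(l) list(
    W = list(Eg = l$W * 0, Edx = l$W * 0),
    b = list(Eg = l$b * 0, Edx = l$b * 0)))
  best <- list(loss = Inf, layers = layers, epoch = 0)
  no_improve <- 0
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(tr_idx)
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      fw <- mlp_forward(layers, X[idx, , drop = FALSE], cfg$dropout,
                        train = TRUE)
      g_out <- composite_loss_grad(fw$acts[[length(fw$acts)]],
                                   Y[idx, , drop = FALSE], cfg$denom_floor)
      grads <- mlp_backward(layers, fw, g_out, cfg$dropout)
      upd <- adadelta_step(layers, grads, state, cfg$rho, cfg$eps_adadelta)
      layers <- upd$layers
      state <- upd$state
    }
    pred_val <- mlp_forward(layers, X[val_idx, , drop = FALSE])$acts
    vloss <- composite_loss(pred_val[[length(pred_val)]],
                            Y[val_idx, , drop = FALSE], cfg$denom_floor)
    if (is.finite(vloss) && vloss < best$loss) {
      best <- list(loss = vloss, layers = layers, epoch = epoch)
      no_improve <- 0
    } else {
      no_improve <- no_improve + 1
      if (no_improve >= cfg$patience) break
    }
  }
  if (!is.finite(best$loss)) stop("non-finite validation loss")
  best
}

# --- public training / prediction interface -------------------------------

normalize_minmax <- function(M) {
  lo <- apply(M, 2, min)
  hi <- apply(M, 2, max)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1
  list(X = sweep(sweep(M, 2, lo), 2, rng, `/`), lo = lo, rng = rng,
       constant = const)
}

#' Train the parameter-upscaling network
#'
#' Min-max normalizes covariates and targets to `[0, 1]` (statistics stored
#' for inversion), trains the MLP with the composite loss and selects the
#' epoch with the lowest validation loss.  With `bootstrap_reps > 0` an
#' ensemble is trained on with-replacement resamples (each with its own
#' 90/10 split) for 2-sigma uncertainty; the "best-guess" member is always
#' trained on the full data.
#'
#' @param covariates data.frame with `site_id` and the covariate columns.
#' @param params_table matrix/data.frame of per-site target parameters
#'   (posterior means), rows aligned with `covariates`.
#' @param cfg [network_config()].
#' @param seed integer seed; training is seed-deterministic.
#' @param bootstrap number of bootstrap members (default
#'   `cfg$bootstrap_reps`; 0 disables the ensemble).
#' @return object of class `soilcue_predictor` with the best-guess network,
#'   optional ensemble, normalization statistics and a training report.
#' @export
train_parameter_network <- function(covariates, params_table, cfg = network_config(),
                                    seed = 1, bootstrap = 0) {
  Xraw <- as.matrix(covariates[, setdiff(names(covariates), "site_id"),
                               drop = FALSE])
  Yraw <- as.matrix(params_table)
  if (nrow(Xraw) != nrow(Yraw)) stop("covariate and parameter rows differ")
  if (nrow(Xraw) < 50) stop("need at least 50 training rows")
  nx <- normalize_minmax(Xraw)
  ny <- normalize_minmax(Yraw)
  if (any(nx$constant)) {
    warning("constant covariate column(s): ",
            paste(colnames(Xraw)[nx$constant], collapse = ", "))
  }

  best_guess <- mlp_train_once(nx$X, ny$X, cfg, seed)
  ensemble <- NULL
  if (bootstrap > 0) {
    ensemble <- lapply(seq_len(bootstrap), function(b) {
      set.seed(seed + 7919L * b)
      rows <- sample(nrow(nx$X), replace = TRUE)
      mlp_train_once(nx$X[rows, , drop = FALSE], ny$X[rows, , drop = FALSE],
                     cfg, seed + 7919L * b)
    })
  }
  out <- list(best_guess = best_guess, ensemble = ensemble,
              norm_x = nx[c("lo", "rng", "constant")],
              norm_y = ny[c("lo", "rng")],
              x_names = colnames(Xraw), y_names = colnames(Yraw),
              cfg = cfg, seed = seed,
              report = list(architecture = cfg$hidden,
                            dropout = cfg$dropout,
                            val_loss = best_guess$loss,
                            best_epoch = best_guess$epoch,
                            n_train = nrow(Xraw)))
  class(out) <- "soilcue_predictor"
  out
}

#' @export
print.soilcue_predictor <- function(x, ...) {
  cat("<soilcue_predictor> hidden (",
      paste(x$report$architecture, collapse = ", "),
      "), dropout ", x$report$dropout,
      ", best epoch ", x$report$best_epoch,
      ", val loss ", signif(x$report$val_loss, 4), "\n", sep = "")
  invisible(x)
}

# normalized-scale prediction matrix for a covariate table
predictor_forward <- function(predictor, covariates, member = NULL) {
  X <- as.matrix(covariates[, predictor$x_names, drop = FALSE])
  Xn <- sweep(sweep(X, 2, predictor$norm_x$lo), 2, predictor$norm_x$rng, `/`)
  layers <- if (is.null(member)) {
    predictor$best_guess$layers
  } else {
    predictor$ensemble[[member]]$layers
  }
  fw <- mlp_forward(layers, Xn)
  fw$acts[[length(fw$acts)]]
}

#' Predict parameters (de-normalized, clipped to prior bounds)
#'
#' @param predictor trained [train_parameter_network()] object.
#' @param covariates covariate table (`site_id` + named columns).
#' @param priors prior table used for clipping (defaults to package priors).
#' @return list with `params` (matrix, de-normalized), `clipped` (logical
#'   matrix) and, when an ensemble exists, `sd2` (2-sigma per entry).
#' @export
predict_parameters <- function(predictor, covariates,
                               priors = default_prior_spec()) {
  denorm <- function(Yn) {
    sweep(sweep(Yn, 2, predictor$norm_y$rng, `*`), 2, predictor$norm_y$lo,
          `+`)
  }
  Y <- denorm(predictor_forward(predictor, covariates))
  colnames(Y) <- predictor$y_names
  lo <- stats::setNames(priors$lower, priors$name)[colnames(Y)]
  hi <- stats::setNames(priors$upper, priors$name)[colnames(Y)]
  clipped <- sweep(Y, 2, lo, `<`) | sweep(Y, 2, hi, `>`)
  Y <- sweep(Y, 2, lo, pmax)
  Y <- sweep(Y, 2, hi, pmin)
  sd2 <- NULL
  if (!is.null(predictor$ensemble)) {
    preds <- lapply(seq_along(predictor$ensemble), function(b)
      denorm(predictor_forward(predictor, covariates, member = b)))
    arr <- simplify2array(preds)
    sd2 <- 2 * apply(arr, c(1, 2), stats::sd)
    colnames(sd2) <- predictor$y_names
  }
  list(params = Y, clipped = clipped, sd2 = sd2)
}

#' Predict parameters and simulate SOC everywhere
#'
#' Applies the trained network to new covariates, de-normalizes and clips
#' the parameters to their prior bounds, runs the steady-state model per
#' site, and reports top-1 m SOC stocks plus the coefficient of efficiency
#' against any provided observations.
#'
#' @param predictor trained predictor.
#' @param covariates covariate table for the target sites.
#' @param contexts list of [site_context()] per site (same order).
#' @param base_params full parameter template supplying the non-predicted
#'   entries (defaults to package defaults).
#' @param observed optional vector of observed top-1 m stocks (kgC m^-2)
#'   for the skill score.
#' @param priors prior table for clipping.
#' @return list: `parameters` (data.frame site_id + predicted params),
#'   `soc_top1m` (kgC m^-2), `feasible`, `E` (or NA), `sd2`, `flagged`
#'   (sites with clipped or infeasible predictions).
#' @export
predict_parameters_and_soc <- function(predictor, covariates, contexts,
                                       base_params = microbial_params(),
                                       observed = NULL,
                                       priors = default_prior_spec()) {
  pred <- predict_parameters(predictor, covariates, priors)
  n <- nrow(pred$params)
  if (length(contexts) != n) stop("one context per covariate row required")
  soc <- rep(NA_real_, n)
  feas <- logical(n)
  for (i in seq_len(n)) {
    p <- base_params
    p[colnames(pred$params)] <- pred$params[i, ]
    ss <- steady_state(p, contexts[[i]]$grid, contexts[[i]]$forcings,
                       input_split = contexts[[i]]$input_split)
    feas[i] <- isTRUE(attr(ss, "feasible"))
    if (feas[i]) soc[i] <- soc_stock(ss, contexts[[i]]$grid)
  }
  E <- NA_real_
  if (!is.null(observed)) {
    ok <- feas & is.finite(observed)
    E <- coefficient_of_efficiency(observed[ok], soc[ok])
  }
  list(parameters = data.frame(site_id = covariates$site_id, pred$params,
                               stringsAsFactors = FALSE),
       soc_top1m = soc, feasible = feas, E = E, sd2 = pred$sd2,
       flagged = which(!feas | rowSums(pred$clipped) > 0))
}
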