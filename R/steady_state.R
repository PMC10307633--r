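# Steady states of dX/dt = B I + A xi K X + V X.
#
# The litter subsystem (CWD, ML, CL, LL) is linear in X and block
# lower-triangular (CWD feeds CL and LL, nothing feeds back), so its steady
# state is four tridiagonal n x n solves.  The mineral subsystem (DOC, MIC,
# ENZ, mSOC) is layer-local (no transport) and admits an exact closed form
# derived from the four pool balances; see soil_steady_state().

#' Right-hand side of the model ODE
#'
#' @param state pool state (gC m^-3).
#' @param params parameter vector.
#' @param grid layer grid.
#' @param modifier environmental modifier profile.
#' @param forcings site forcings (plant input `I`).
#' @param input_split litter input split (see [assemble_operators()]).
#' @return `n_layers x 8` matrix of time derivatives (gC m^-3 yr^-1).
#' @export
model_rhs <- function(state, params, grid, modifier, forcings,
                      input_split = c(ML = 0.45, CL = 0.35, LL = 0.20)) {
  p <- params
  n <- grid$n_layers
  xi <- modifier$xi_total
  k <- all_rates(state, params, modifier)
  f <- xi * k * state          # outgoing flux per pool/layer, gC m^-3 yr^-1

  dx <- -f
  dx[, "CL"] <- dx[, "CL"] + p[["a_CL_CWD"]] * f[, "CWD"]
  dx[, "LL"] <- dx[, "LL"] + p[["a_LL_CWD"]] * f[, "CWD"]
  dx[, "DOC"] <- dx[, "DOC"] + p[["a_DOC_ML"]] * f[, "ML"] +
    p[["a_DOC_CL"]] * f[, "CL"] + p[["a_DOC_MIC"]] * f[, "MIC"] +
    f[, "ENZ"] + p[["a_DOC_mSOC"]] * f[, "mSOC"]
  dx[, "MIC"] <- dx[, "MIC"] + p[["a_MIC_ML"]] * f[, "ML"] +
    p[["a_MIC_CL"]] * f[, "CL"] + p[["a_MIC_LL"]] * f[, "LL"] +
    p[["eta_DOC"]] * f[, "DOC"]
  dx[, "ENZ"] <- dx[, "ENZ"] + p[["a_ENZ_MIC"]] * f[, "MIC"]
  dx[, "mSOC"] <- dx[, "mSOC"] + p[["a_mSOC_LL"]] * f[, "LL"] +
    p[["a_mSOC_MIC"]] * f[, "MIC"]

  alloc <- input_allocation_profile(p, grid)
  for (pool in names(input_split)) {
    dx[, pool] <- dx[, pool] +
      forcings$npp * input_split[[pool]] * alloc / grid$thickness
  }
  if (p[["d_bio"]] > 0) {
    Vb <- transport_block(p[["d_bio"]], grid)
    for (pool in LITTER_POOLS) dx[, pool] <- dx[, pool] + Vb %*% state[, pool]
  }
  dx
}

#' Total respiration flux of a state
#'
#' Area-based CO2 efflux (gC m^-2 yr^-1): for each donor pool the respired
#' residual `1 - sum(outgoing fractions)` times its decomposition flux,
#' integrated over depth.  At steady state this equals the plant input `I`.
#'
#' @inheritParams model_rhs
#' @return scalar, gC m^-2 yr^-1.
#' @export
total_respiration <- function(state, params, grid, modifier) {
  resp_frac <- 1 - donor_outflow_sums(params)
  f <- modifier$xi_total * all_rates(state, params, modifier) * state
  sum((f %*% resp_frac[POOLS]) * grid$thickness)
}

#' Analytic steady state of the litter subsystem
#'
#' Solves `[A_litter xi K_litter + V_litter] X = -B_litter I` pool by pool
#' (CWD first, then ML, CL, LL which receive CWD transfer), each a
#' tridiagonal `n x n` linear system `(diag(k xi) - V) x = source`.
#'
#' @inheritParams model_rhs
#' @return pool state with the four litter columns filled.
#' @export
litter_steady_state <- function(params, grid, modifier, forcings,
                                input_split = c(ML = 0.45, CL = 0.35, LL = 0.20)) {
  p <- params
  n <- grid$n_layers
  xi <- modifier$xi_total
  alloc <- input_allocation_profile(p, grid)
  Vb <- transport_block(p[["d_bio"]], grid)
  src_input <- function(pool) {
    s <- if (pool %in% names(input_split)) input_split[[pool]] else 0
    forcings$npp * s * alloc / grid$thickness
  }
  solve_pool <- function(k, src) {
    M <- diag(k * xi, n) - Vb
    out <- tryCatch(solve(M, src), error = function(e) NULL)
    if (is.null(out)) {
      stop("degenerate litter subsystem: singular operator (zero ",
           "decomposition and transport?)")
    }
    out
  }
  x <- pool_state(grid)
  x[, "CWD"] <- solve_pool(p[["k_CWD"]], src_input("CWD"))
  f_cwd <- p[["k_CWD"]] * xi * x[, "CWD"]
  x[, "ML"] <- solve_pool(p[["k_ML"]], src_input("ML"))
  x[, "CL"] <- solve_pool(p[["k_CL"]], src_input("CL") + p[["a_CL_CWD"]] * f_cwd)
  x[, "LL"] <- solve_pool(p[["k_LL"]], src_input("LL") + p[["a_LL_CWD"]] * f_cwd)
  x
}

#' Analytic steady state of the mineral-soil subsystem
#'
#' Layer-local closed form of the DOC / MIC / ENZ / mSOC balances given the
#' litter steady state.  With `u_S = sum_L a_S,L k_L xi x_L` the litter
#' carbon inputs to pool S, `eta = eta_DOC` and the microbial recycling sum
#' `c = a_DOC,MIC + a_ENZ,MIC + a_DOC,mSOC a_mSOC,MIC`:
#'
#' * `x_MIC = (u_MIC + eta (u_DOC + a_DOC,mSOC u_mSOC)) / ((1 - eta c) k_MIC xi)`
#' * `x_ENZ = a_ENZ,MIC k_MIC x_MIC / k_ENZ`
#' * `x_DOC = F_D K_m_assim xi / (v_max_assim xi x_MIC - F_D)` with the DOC
#'   uptake flux `F_D = (k_MIC xi x_MIC - u_MIC) / eta`
#' * `x_mSOC = F_S K_m_decom xi / (v_max_decom xi x_ENZ - F_S)` with the
#'   mSOC decomposition flux `F_S = u_mSOC + a_mSOC,MIC k_MIC xi x_MIC`.
#'
#' Under full recycling (`c = 1`, `a_DOC,mSOC = 1`) this reduces to the
#' familiar `x_MIC = (u_MIC + eta (u_mSOC + u_DOC)) / ((1 - eta) k_MIC xi)`.
#' A negative or non-finite result (e.g. `v_max_decom xi x_ENZ <= F_S`, no
#' enzymatic capacity to balance the mSOC input) signals an infeasible
#' parameter set: the state is returned with `attr(, "feasible") = FALSE`
#' and a reason, never silently clipped.
#'
#' @param litter_ss litter steady state from [litter_steady_state()].
#' @inheritParams model_rhs
#' @return full pool state (litter columns copied through) with attributes
#'   `feasible` (logical) and `reason` (character, when infeasible).
#' @export
soil_steady_state <- function(litter_ss, params, grid, modifier) {
  p <- params
  xi <- modifier$xi_total
  eta <- p[["eta_DOC"]]
  u_MIC <- xi * (p[["a_MIC_ML"]] * p[["k_ML"]] * litter_ss[, "ML"] +
                 p[["a_MIC_CL"]] * p[["k_CL"]] * litter_ss[, "CL"] +
                 p[["a_MIC_LL"]] * p[["k_LL"]] * litter_ss[, "LL"])
  u_DOC <- xi * (p[["a_DOC_ML"]] * p[["k_ML"]] * litter_ss[, "ML"] +
                 p[["a_DOC_CL"]] * p[["k_CL"]] * litter_ss[, "CL"])
  u_mSOC <- xi * (p[["a_mSOC_LL"]] * p[["k_LL"]] * litter_ss[, "LL"])

  c_rec <- p[["a_DOC_MIC"]] + p[["a_ENZ_MIC"]] +
    p[["a_DOC_mSOC"]] * p[["a_mSOC_MIC"]]
  x <- litter_ss
  feasible <- TRUE
  reason <- character()
  if (eta * c_rec >= 1) {
    feasible <- FALSE
    reason <- "eta_DOC times microbial recycling sum >= 1 (divergent biomass)"
  } else {
    M <- (u_MIC + eta * (u_DOC + p[["a_DOC_mSOC"]] * u_mSOC)) /
      ((1 - eta * c_rec) * p[["k_MIC"]] * xi)
    E <- p[["a_ENZ_MIC"]] * p[["k_MIC"]] * M / p[["k_ENZ"]]
    f_M <- p[["k_MIC"]] * xi * M
    F_D <- (f_M - u_MIC) / eta
    F_S <- u_mSOC + p[["a_mSOC_MIC"]] * f_M

    den_D <- p[["v_max_assim"]] * xi * M - F_D
    den_S <- p[["v_max_decom"]] * xi * E - F_S
    D <- ifelse(F_D <= 0, 0, F_D * p[["K_m_assim"]] * xi / den_D)
    S <- ifelse(F_S <= 0, 0, F_S * p[["K_m_decom"]] * xi / den_S)

    if (any(F_D > 0 & den_D <= 0)) {
      feasible <- FALSE
      reason <- "DOC uptake capacity below required flux (v_max_assim too small)"
    }
    if (any(F_S > 0 & den_S <= 0)) {
      feasible <- FALSE
      reason <- c(reason,
                  "mSOC decomposition capacity below input flux (v_max_decom too small)")
    }
    x[, "DOC"] <- D
    x[, "MIC"] <- M
    x[, "ENZ"] <- E
    x[, "mSOC"] <- S
    if (any(!is.finite(x)) || any(x < 0)) {
      feasible <- FALSE
      reason <- c(reason, "non-finite or negative closed-form state")
    }
  }
  attr(x, "feasible") <- feasible
  attr(x, "reason") <- paste(reason, collapse = "; ")
  x
}

#' Combined analytic steady state
#'
#' @inheritParams model_rhs
#' @param modifier optional; computed from `forcings` and `params` when NULL.
#' @return full pool state with feasibility attributes (see
#'   [soil_steady_state()]).
#' @export
steady_state <- function(params, grid, forcings, modifier = NULL,
                         input_split = c(ML = 0.45, CL = 0.35, LL = 0.20)) {
  if (is.null(modifier)) modifier <- environmental_modifier(forcings, params, grid)
  lit <- litter_steady_state(params, grid, modifier, forcings, input_split)
  soil_steady_state(lit, params, grid, modifier)
}

# Analytic Jacobian of the stacked rhs (8n x 8n).
model_jacobian <- function(xvec, params, grid, modifier, ops) {
  p <- params
  n <- grid$n_layers
  xi <- rep(modifier$xi_total, 8)
  J <- sweep(ops$A, 2, xi * ops$K0, `*`) + ops$V

  st <- matrix(xvec, n, 8, dimnames = list(NULL, POOLS))
  xil <- modifier$xi_total
  idx <- function(pool) (match(pool, POOLS) - 1L) * n + seq_len(n)
  iD <- idx("DOC"); iM <- idx("MIC"); iE <- idx("ENZ"); iS <- idx("mSOC")

  # DOC uptake flux F_D = xi v_a MIC DOC / (K_a xi + DOC)
  denD <- p[["K_m_assim"]] * xil + st[, "DOC"]
  dFD_dD <- xil * p[["v_max_assim"]] * st[, "MIC"] * p[["K_m_assim"]] * xil / denD^2
  dFD_dM <- xil * p[["v_max_assim"]] * st[, "DOC"] / denD
  # mSOC decomposition flux F_S = xi v_d ENZ mSOC / (K_d xi + mSOC)
  denS <- p[["K_m_decom"]] * xil + st[, "mSOC"]
  dFS_dS <- xil * p[["v_max_decom"]] * st[, "ENZ"] * p[["K_m_decom"]] * xil / denS^2
  dFS_dE <- xil * p[["v_max_decom"]] * st[, "mSOC"] / denS

  add <- function(rows, cols, val) {
    ij <- cbind(rows, cols)
    J[ij] <<- J[ij] + val
  }
  add(iD, iD, -dFD_dD); add(iD, iM, -dFD_dM)
  add(iM, iD, p[["eta_DOC"]] * dFD_dD); add(iM, iM, p[["eta_DOC"]] * dFD_dM)
  add(iS, iS, -dFS_dS); add(iS, iE, -dFS_dE)
  add(iD, iS, p[["a_DOC_mSOC"]] * dFS_dS)
  add(iD, iE, p[["a_DOC_mSOC"]] * dFS_dE)
  J
}

#' Integrate the full nonlinear system to steady state
#'
#' Numerical oracle for the analytic solutions: pseudo-transient continuation
#' with a linearised implicit-Euler (Rosenbrock-Euler) step and the analytic
#' Jacobian of the `8 x n_layers` system, growing the step adaptively.  As
#' the step grows the iteration becomes a damped Newton solve of
#' `dX/dt = 0`, so the final state satisfies the stationarity condition far
#' more tightly than any forward path would.  Stiff-capable by construction.
#'
#' @inheritParams model_rhs
#' @param modifier optional; computed from `forcings` when NULL.
#' @param x0 initial state (matrix or `pool_state`); defaults to 1 gC m^-3
#'   everywhere.
#' @param t_max maximum pseudo-time (yr); generous by default - the
#'   pseudo-time is a continuation device, not physical spin-up time, and
#'   slow DOC modes at strong depth attenuation need ~1e7 yr before the
#'   Newton phase can engage.
#' @param tol convergence threshold on `max |dX/dt|` (gC m^-3 yr^-1);
#'   default `1e-9 * max(1, I)`.
#' @param max_steps iteration cap.
#' @return pool state with attributes `converged` (logical), `t` (pseudo-time
#'   reached), `residual` (final `max |dX/dt|`).
#' @export
integrate_to_steady_state <- function(params, grid, forcings, modifier = NULL,
                                      x0 = NULL, t_max = 1e12, tol = NULL,
                                      max_steps = 400,
                                      input_split = c(ML = 0.45, CL = 0.35, LL = 0.20)) {
  if (t_max <= 0) stop("'t_max' must be > 0")
  if (is.null(modifier)) modifier <- environmental_modifier(forcings, params, grid)
  if (is.null(tol)) tol <- 1e-9 * max(1, forcings$npp)
  n <- grid$n_layers
  N <- 8L * n
  ops <- assemble_operators(params, grid, input_split)
  x <- if (is.null(x0)) rep(1, N) else state_to_vec(pool_state(grid, x0))

  h <- 1e-2
  t <- 0
  converged <- FALSE
  res <- Inf
  newton_switch <- 1e-4 * max(1, forcings$npp)
  damp_until <- 0L
  for (step in seq_len(max_steps)) {
    f <- state_to_vec(model_rhs(vec_to_state(x, grid), params, grid, modifier,
                                forcings, input_split))
    res <- max(abs(f))
    if (converged) break
    if (t >= t_max && res >= newton_switch) break
    J <- model_jacobian(x, params, grid, modifier, ops)
    # once close, switch to Newton steps (h = Inf) to polish the fixed
    # point: near-inert deep layers equilibrate in pseudo-time only as
    # t ~ 1/(k xi), which Newton sidesteps entirely
    newton <- res < newton_switch && step >= damp_until
    repeat {
      Msys <- -J
      if (!newton) diag(Msys) <- diag(Msys) + 1 / h
      # full equilibration: near-inert layers scale rows by ~xi (down to
      # 1e-10) and saturated DOC columns by the vanishing Michaelis
      # sensitivity, either of which wrecks the raw condition number
      rs <- pmax(apply(abs(Msys), 1, max), 1e-300)
      Ms <- Msys / rs
      cs <- pmax(apply(abs(Ms), 2, max), 1e-300)
      Ms <- sweep(Ms, 2, cs, `/`)
      fs <- f / rs
      delta <- tryCatch(solve(Ms, fs) / cs, error = function(e) NULL)
      if (is.null(delta)) {
        # transiently singular Jacobian (e.g. an enzyme pool near zero wipes
        # out its layer's mSOC row): regularise with a small ridge
        for (lam in 10^c(-12, -9, -6)) {
          Mr <- Ms
          diag(Mr) <- diag(Mr) + lam
          delta <- tryCatch(solve(Mr, fs) / cs, error = function(e) NULL)
          if (!is.null(delta)) break
        }
      }
      if (!is.null(delta) && all(is.finite(delta))) break
      if (newton) { newton <- FALSE; next }
      h <- h / 4
      if (h < 1e-12) stop("pseudo-transient integration failed: step underflow")
    }
    # fraction-to-the-boundary damping keeps all pools strictly positive
    # (the Michaelis-Menten terms are hyperbolic and a full step overshoots)
    # projected step: any component that a full step would drive negative is
    # pulled to a fixed fraction of its current value instead (the
    # Michaelis-Menten terms are hyperbolic and full steps overshoot);
    # unconstrained components keep the full (quadratic) Newton update
    xn <- x + delta
    hit <- xn < 0
    xn[hit] <- 0.005 * x[hit]
    # reject exploding steps (a bad Newton direction far from the basin):
    # keep the previous state, shrink the pseudo-step, damp for a while
    if (!all(is.finite(xn)) || max(xn) > 1e200) {
      h <- max(h / 16, 1e-8)
      damp_until <- step + 20L
      next
    }
    scale_x <- max(xn, 1)
    active <- xn > 1e-12 * scale_x
    moved <- if (any(active)) {
      max(abs(xn[active] - x[active]) / (abs(xn[active]) + 1e-12 * scale_x))
    } else 0
    x <- xn
    if (!newton) {
      t <- t + h
      h <- min(h * 2, 1e10)
    }
    # converged when the residual is small AND a Newton step no longer moves
    # the state: the residual alone is blind to slow pools whose tiny rates
    # map large state errors to tiny time derivatives.  Boundary hits on
    # negligible components (shrunk to ~0 by repeated projection) do not
    # block convergence.
    blocking_hit <- any(hit & xn > 1e-12 * scale_x)
    if (newton && !blocking_hit && res < tol * 1e3 && moved < 1e-9) {
      converged <- TRUE   # loop once more to refresh the reported residual
    }
  }
  out <- vec_to_state(x, grid)
  attr(out, "converged") <- converged
  attr(out, "t") <- t
  attr(out, "residual") <- res
  if (!converged) {
    warning("integrate_to_steady_state: not converged (residual ",
            signif(res, 3), " after t = ", signif(t, 3), " yr)")
  }
  out
}
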