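# Matrix operators of the 8-pool layered model,
#   dX/dt = B I + A xi K X + V X,
# with X stacked pool-major: [CWD; ML; CL; LL; DOC; MIC; ENZ; mSOC], each
# block holding n_layers carbon densities (gC m^-3).

#' Pool state container
#'
#' @param grid layer grid.
#' @param values optional `n_layers x 8` matrix (gC m^-3).
#' @return `n_layers x 8` matrix of class `soilcue_state` with pool columns
#'   `CWD, ML, CL, LL, DOC, MIC, ENZ, mSOC`.
#' @export
pool_state <- function(grid, values = NULL) {
  x <- matrix(0, grid$n_layers, 8, dimnames = list(NULL, POOLS))
  if (!is.null(values)) {
    stopifnot(nrow(values) == grid$n_layers, ncol(values) == 8)
    x[] <- as.matrix(values)
  }
  class(x) <- c("soilcue_state", "matrix", "array")
  x
}

# stacked vector <-> state matrix
state_to_vec <- function(state) as.vector(state[, POOLS])
vec_to_state <- function(x, grid) {
  pool_state(grid, matrix(x, grid$n_layers, 8))
}

#' Depth allocation of plant carbon input
#'
#' Per-layer allocation fractions following the asymptotic root distribution
#' `Y(d) = 1 - beta_root^d` (cumulative fraction above depth `d` in cm):
#' layer `i` spanning `[u_i, l_i]` receives `beta^ (100 u_i) - beta^(100 l_i)`,
#' then the column is renormalized to sum to 1.
#'
#' @param params parameter vector (uses `beta_root`).
#' @param grid layer grid.
#' @return numeric vector of length `n_layers` summing to 1.
#' @export
input_allocation_profile <- function(params, grid) {
  beta <- params[["beta_root"]]
  d_cm <- grid$interface_depth * 100
  frac <- beta^d_cm[-length(d_cm)] - beta^d_cm[-1]
  frac / sum(frac)
}

#' Assemble the model operators
#'
#' Builds the full stacked operators of the matrix model: the input
#' allocation vector `B` (fractions of `I` per pool and layer, summing to 1),
#' the transfer matrix `A` (block structure with -1 diagonal blocks, the
#' DOC <- ENZ block equal to the identity, and diagonal transfer-fraction
#' blocks elsewhere), the constant baseline-rate vector `K0` (zero in the
#' DOC and mSOC positions, whose rates are state dependent), and the
#' vertical-transport matrix `V` (tridiagonal diffusion within each litter
#' pool, conserving depth-integrated mass with zero-flux boundaries).
#'
#' @param params parameter vector (validated).
#' @param grid layer grid.
#' @param input_split fractions of plant input routed to the ML, CL, LL
#'   (and optionally CWD) litter pools; must sum to 1.
#' @return list with elements `B` (length `8 n`), `A` (`8n x 8n`),
#'   `K0` (length `8 n`), `V` (`8n x 8n`) and `input_split`.
#' @export
assemble_operators <- function(params, grid,
                               input_split = c(ML = 0.45, CL = 0.35, LL = 0.20)) {
  validate_params(params)
  if (is.null(names(input_split)) ||
      !all(names(input_split) %in% c("CWD", "ML", "CL", "LL"))) {
    stop("'input_split' must be named with litter pools")
  }
  if (abs(sum(input_split) - 1) > 1e-8) stop("'input_split' must sum to 1")
  p <- params
  n <- grid$n_layers
  alloc <- input_allocation_profile(p, grid)

  B <- numeric(8 * n)
  for (pool in names(input_split)) {
    idx <- (match(pool, POOLS) - 1) * n + seq_len(n)
    B[idx] <- input_split[[pool]] * alloc
  }

  # A: 8x8 block pattern of scalar transfer fractions
  ablk <- diag(-1, 8)
  dimnames(ablk) <- list(POOLS, POOLS)
  ablk["CL", "CWD"] <- p[["a_CL_CWD"]]
  ablk["LL", "CWD"] <- p[["a_LL_CWD"]]
  ablk["DOC", "ML"] <- p[["a_DOC_ML"]]
  ablk["DOC", "CL"] <- p[["a_DOC_CL"]]
  ablk["DOC", "MIC"] <- p[["a_DOC_MIC"]]
  ablk["DOC", "ENZ"] <- 1
  ablk["DOC", "mSOC"] <- p[["a_DOC_mSOC"]]
  ablk["MIC", "ML"] <- p[["a_MIC_ML"]]
  ablk["MIC", "CL"] <- p[["a_MIC_CL"]]
  ablk["MIC", "LL"] <- p[["a_MIC_LL"]]
  ablk["MIC", "DOC"] <- p[["eta_DOC"]]
  ablk["ENZ", "MIC"] <- p[["a_ENZ_MIC"]]
  ablk["mSOC", "LL"] <- p[["a_mSOC_LL"]]
  ablk["mSOC", "MIC"] <- p[["a_mSOC_MIC"]]
  A <- kronecker(ablk, diag(1, n))

  k0 <- c(CWD = p[["k_CWD"]], ML = p[["k_ML"]], CL = p[["k_CL"]],
          LL = p[["k_LL"]], DOC = 0, MIC = p[["k_MIC"]],
          ENZ = p[["k_ENZ"]], mSOC = 0)
  K0 <- rep(k0, each = n)

  Vb <- transport_block(p[["d_bio"]], grid)
  V <- matrix(0, 8 * n, 8 * n)
  for (pool in LITTER_POOLS) {
    idx <- (match(pool, POOLS) - 1) * n + seq_len(n)
    V[idx, idx] <- Vb
  }
  list(B = B, A = A, K0 = K0, V = V, A_block = ablk, input_split = input_split)
}

# n x n tridiagonal diffusion operator on the node grid; conserves
# sum(x * thickness) exactly (zero-flux boundaries).
transport_block <- function(d_bio, grid) {
  n <- grid$n_layers
  Vb <- matrix(0, n, n)
  if (d_bio <= 0 || n < 2) return(Vb)
  dz_node <- diff(grid$node_depth)
  for (i in seq_len(n - 1)) {
    g <- d_bio / dz_node[i]
    Vb[i, i] <- Vb[i, i] - g / grid$thickness[i]
    Vb[i, i + 1] <- Vb[i, i + 1] + g / grid$thickness[i]
    Vb[i + 1, i + 1] <- Vb[i + 1, i + 1] - g / grid$thickness[i + 1]
    Vb[i + 1, i] <- Vb[i + 1, i] + g / grid$thickness[i + 1]
  }
  Vb
}

#' State-dependent baseline rates of DOC and mSOC
#'
#' Michaelis-Menten forms with the environmental modifier scaling the
#' Michaelis constant inside the denominator:
#' `k_DOC = v_max_assim * x_MIC / (K_m_assim * xi + x_DOC)` and
#' `k_mSOC = v_max_decom * x_ENZ / (K_m_decom * xi + x_mSOC)`.
#'
#' @param state pool state (gC m^-3).
#' @param params parameter vector.
#' @param modifier [environmental_modifier()] profile.
#' @return list of per-layer vectors `k_DOC`, `k_mSOC` (yr^-1).
#' @export
state_dependent_rates <- function(state, params, modifier) {
  p <- params
  xi <- modifier$xi_total
  list(
    k_DOC = p[["v_max_assim"]] * state[, "MIC"] /
      (p[["K_m_assim"]] * xi + state[, "DOC"]),
    k_mSOC = p[["v_max_decom"]] * state[, "ENZ"] /
      (p[["K_m_decom"]] * xi + state[, "mSOC"])
  )
}

# Full per-layer rate vector k(X) for all 8 pools (n x 8 matrix).
all_rates <- function(state, params, modifier) {
  p <- params
  sd <- state_dependent_rates(state, params, modifier)
  cbind(CWD = rep(p[["k_CWD"]], nrow(state)), ML = p[["k_ML"]],
        CL = p[["k_CL"]], LL = p[["k_LL"]], DOC = sd$k_DOC,
        MIC = p[["k_MIC"]], ENZ = p[["k_ENZ"]], mSOC = sd$k_mSOC)
}
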