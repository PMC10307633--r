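# Parameter vector for the 8-pool microbial model, grouped into the seven
# model components (cue, transfer, decomposability, environment, allocation,
# transport; plant input is a forcing, not a parameter).

POOLS <- c("CWD", "ML", "CL", "LL", "DOC", "MIC", "ENZ", "mSOC")
LITTER_POOLS <- c("CWD", "ML", "CL", "LL")
MINERAL_POOLS <- c("DOC", "MIC", "ENZ", "mSOC")

#' Parameter definition table
#'
#' One row per model parameter: name, component membership, default value and
#' uniform prior bounds, and whether the parameter is in the default
#' assimilated (free) subset.  The default free mask selects 23 parameters
#' spanning all components; `a_DOC_mSOC`, `a_ENZ_MIC`, `k_CWD`, `k_ENZ` and
#' `psi_half` are held fixed.
#'
#' @return a data.frame with columns `name`, `component`, `default`,
#'   `lower`, `upper`, `free`.
#' @export
param_definitions <- function() {
  def <- rbind(
    # component cue: microbial assimilation / growth partitioning
    c("a_MIC_ML",    "cue",             0.45, 0.10, 0.60, 1),
    c("a_MIC_CL",    "cue",             0.40, 0.10, 0.60, 1),
    c("a_MIC_LL",    "cue",             0.30, 0.05, 0.50, 1),
    c("eta_DOC",     "cue",             0.30, 0.05, 0.70, 1),
    c("v_max_assim", "cue",            15.00, 2.00, 50.0, 1),
    c("K_m_assim",   "cue",           250.00, 10.0, 1000, 1),
    # component transfer: non-microbial carbon transfer fractions
    c("a_CL_CWD",    "transfer",        0.45, 0.20, 0.50, 1),
    c("a_LL_CWD",    "transfer",        0.40, 0.20, 0.50, 1),
    c("a_DOC_ML",    "transfer",        0.25, 0.05, 0.40, 1),
    c("a_DOC_CL",    "transfer",        0.25, 0.05, 0.40, 1),
    c("a_mSOC_LL",   "transfer",        0.10, 0.02, 0.30, 1),
    c("a_DOC_MIC",   "transfer",        0.30, 0.05, 0.45, 1),
    c("a_ENZ_MIC",   "transfer",        0.05, 0.01, 0.10, 0),
    c("a_mSOC_MIC",  "transfer",        0.40, 0.10, 0.45, 1),
    c("a_DOC_mSOC",  "transfer",        0.80, 0.20, 1.00, 0),
    # component decomposability: baseline rates and Michaelis constants
    c("k_CWD",       "decomposability", 0.10, 0.01, 1.00, 0),
    c("k_ML",        "decomposability", 8.00, 1.00, 20.0, 1),
    c("k_CL",        "decomposability", 2.00, 0.20, 5.00, 1),
    c("k_LL",        "decomposability", 0.40, 0.05, 2.00, 1),
    c("k_MIC",       "decomposability", 10.0, 2.00, 20.0, 1),
    c("k_ENZ",       "decomposability", 2.00, 0.50, 10.0, 0),
    c("v_max_decom", "decomposability", 30.0, 5.00, 100., 1),
    c("K_m_decom",   "decomposability", 8000, 1000, 20000, 1),
    # component environment: modifier shapes
    c("q10",         "environment",     2.00, 1.20, 3.50, 1),
    c("psi_half",    "environment",     0.30, 0.05, 1.00, 0),
    c("z_tau",       "environment",     0.50, 0.10, 2.00, 1),
    # component allocation: rooting-depth allocation
    c("beta_root",   "allocation",      0.92, 0.70, 0.99, 1),
    # component transport: bioturbation diffusivity
    c("d_bio",       "transport",      1e-04, 0.00, 1e-3, 1)
  )
  out <- data.frame(
    name = def[, 1], component = def[, 2],
    default = as.numeric(def[, 3]),
    lower = as.numeric(def[, 4]), upper = as.numeric(def[, 5]),
    free = as.logical(as.numeric(def[, 6])),
    stringsAsFactors = FALSE
  )
  out
}

#' Construct a model parameter vector
#'
#' Returns the default parameter vector, optionally overriding named entries.
#' Fractions `a_recipient_donor` are carbon transfer fractions out of the
#' donor pool; rates `k_*`, `v_max_*` are yr^-1; `K_m_*` are gC m^-3;
#' `z_tau` is m; `beta_root` is the per-cm root allocation base;
#' `d_bio` is m^2 yr^-1.
#'
#' @param ... named scalar overrides, e.g. `eta_DOC = 0.4`.
#' @param values optional named numeric vector of overrides (same effect).
#' @return named numeric vector of class `soilcue_params`.
#' @export
microbial_params <- function(..., values = NULL) {
  defs <- param_definitions()
  p <- stats::setNames(defs$default, defs$name)
  ov <- c(list(...), as.list(values))
  if (length(ov)) {
    ov <- unlist(ov)
    bad <- setdiff(names(ov), defs$name)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  class(p) <- "soilcue_params"
  p
}

#' Validate a parameter vector
#'
#' Checks the structural invariants: every transfer fraction in `[0, 1]`,
#' the sum of outgoing fractions of each donor pool at most 1 (the residual
#' is respired CO2), all rates and Michaelis constants positive, and
#' `eta_DOC` strictly inside (0, 1).
#'
#' @param params parameter vector from [microbial_params()].
#' @param strict if `TRUE` (default) violations raise an error; otherwise a
#'   character vector of violation messages is returned (empty when valid).
#' @return `invisible(TRUE)` or the violations.
#' @export
validate_params <- function(params, strict = TRUE) {
  p <- params
  msg <- character()
  fr <- grep("^a_", names(p), value = TRUE)
  if (any(p[fr] < 0 | p[fr] > 1)) {
    msg <- c(msg, "transfer fractions must lie in [0, 1]")
  }
  out_sums <- donor_outflow_sums(p)
  if (any(out_sums > 1 + 1e-12)) {
    msg <- c(msg, paste0("donor outflow fractions exceed 1 for: ",
                         paste(names(out_sums)[out_sums > 1 + 1e-12],
                               collapse = ", ")))
  }
  pos <- c("k_CWD", "k_ML", "k_CL", "k_LL", "k_MIC", "k_ENZ",
           "v_max_assim", "K_m_assim", "v_max_decom", "K_m_decom",
           "q10", "psi_half", "z_tau")
  if (any(p[pos] <= 0)) msg <- c(msg, "rates and Michaelis constants must be > 0")
  if (p["eta_DOC"] <= 0 || p["eta_DOC"] >= 1) {
    msg <- c(msg, "eta_DOC must lie strictly inside (0, 1)")
  }
  if (p["d_bio"] < 0) msg <- c(msg, "d_bio must be >= 0")
  if (p["beta_root"] <= 0 || p["beta_root"] >= 1) {
    msg <- c(msg, "beta_root must lie strictly inside (0, 1)")
  }
  if (strict && length(msg)) stop(paste(msg, collapse = "; "))
  if (strict) invisible(TRUE) else msg
}

# Sum of outgoing transfer fractions per donor pool (ENZ always 1: all enzyme
# carbon returns to DOC).
donor_outflow_sums <- function(p) {
  c(CWD = unname(p["a_CL_CWD"] + p["a_LL_CWD"]),
    ML  = unname(p["a_DOC_ML"] + p["a_MIC_ML"]),
    CL  = unname(p["a_DOC_CL"] + p["a_MIC_CL"]),
    LL  = unname(p["a_mSOC_LL"] + p["a_MIC_LL"]),
    DOC = unname(p["eta_DOC"]),
    MIC = unname(p["a_DOC_MIC"] + p["a_ENZ_MIC"] + p["a_mSOC_MIC"]),
    ENZ = 1,
    mSOC = unname(p["a_DOC_mSOC"]))
}

#' Pathway carbon use efficiencies
#'
#' The microbial CUE of each assimilation pathway.  For the three litter
#' pathways, `eta = a_MIC / (1 - a_nonMIC)` where `a_nonMIC` is the
#' non-microbial bypass fraction of that litter pool (`a_DOC_ML`, `a_DOC_CL`,
#' `a_mSOC_LL` respectively); the DOC pathway CUE is `a_MIC_DOC = eta_DOC`
#' itself.
#'
#' @param params parameter vector.
#' @return named numeric vector `c(eta_ML, eta_CL, eta_LL, eta_DOC)`.
#' @export
pool_cue_values <- function(params) {
  p <- params
  den <- c(1 - p[["a_DOC_ML"]], 1 - p[["a_DOC_CL"]], 1 - p[["a_mSOC_LL"]])
  if (any(den <= 0)) {
    stop("pathway CUE undefined: non-microbial bypass fraction equals 1")
  }
  out <- c(eta_ML = p[["a_MIC_ML"]] / den[1],
           eta_CL = p[["a_MIC_CL"]] / den[2],
           eta_LL = p[["a_MIC_LL"]] / den[3],
           eta_DOC = p[["eta_DOC"]])
  out
}

#' Default uniform prior specification
#'
#' @param free optional character vector naming the free (assimilated)
#'   parameters; defaults to the 23-parameter mask in [param_definitions()].
#' @return data.frame of class `soilcue_priors` with columns `name`,
#'   `lower`, `upper`, `component`, `free_flag`.
#' @export
default_prior_spec <- function(free = NULL) {
  defs <- param_definitions()
  if (!is.null(free)) {
    bad <- setdiff(free, defs$name)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    defs$free <- defs$name %in% free
  }
  pr <- data.frame(name = defs$name, value = defs$default,
                   lower = defs$lower, upper = defs$upper,
                   component = defs$component, free_flag = defs$free,
                   stringsAsFactors = FALSE)
  class(pr) <- c("soilcue_priors", "data.frame")
  pr
}

#' Read / write a parameter-prior table
#'
#' Delimited-text interface: columns `name, value, lower, upper, component,
#' free_flag`.
#'
#' @param file path to a CSV file.
#' @param priors a prior table as returned by [default_prior_spec()].
#' @return `read_prior_spec` returns a `soilcue_priors` data.frame.
#' @export
read_prior_spec <- function(file) {
  pr <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("name", "value", "lower", "upper", "component", "free_flag")
  if (!all(need %in% names(pr))) {
    stop("prior table must have columns: ", paste(need, collapse = ", "))
  }
  pr$free_flag <- as.logical(pr$free_flag)
  if (any(pr$lower >= pr$upper)) stop("prior bounds must satisfy lower < upper")
  class(pr) <- c("soilcue_priors", "data.frame")
  pr
}

#' @rdname read_prior_spec
#' @export
write_prior_spec <- function(priors, file) {
  utils::write.csv(as.data.frame(priors), file, row.names = FALSE)
  invisible(file)
}

# Params vector from a prior table's `value` column.
params_from_priors <- function(priors) {
  microbial_params(values = stats::setNames(priors$value, priors$name))
}

#' Draw random parameter vectors from uniform priors
#'
#' @param n number of draws.
#' @param priors prior table.
#' @param seed optional integer seed.
#' @param require_valid drop draws violating structural invariants
#'   (donor outflow sums etc.) and redraw until `n` valid sets are found.
#' @return list of `soilcue_params` vectors.
#' @export
draw_params <- function(n, priors = default_prior_spec(), seed = NULL,
                        require_valid = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  free <- priors$free_flag
  out <- vector("list", n)
  i <- 0L
  guard <- 0L
  while (i < n) {
    guard <- guard + 1L
    if (guard > 200L * n) stop("too many invalid prior draws")
    v <- priors$value
    v[free] <- stats::runif(sum(free), priors$lower[free], priors$upper[free])
    p <- microbial_params(values = stats::setNames(v, priors$name))
    if (!require_valid || length(validate_params(p, strict = FALSE)) == 0) {
      i <- i + 1L
      out[[i]] <- p
    }
  }
  out
}

#' @export
print.soilcue_params <- function(x, ...) {
  cat("<soilcue_params> ", length(x), " parameters\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}
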