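#' Site forcings
#'
#' Bundle of the external drivers of the soil column: net primary
#' productivity (the plant carbon input `I`, gC m^-2 yr^-1), per-layer
#' annual-mean soil temperature (degC), per-layer relative water availability
#' (unitless, 0 = dry, 1 = saturated), a nitrogen-oxygen limitation scalar
#' per layer (defaults to 1) and site climate (mean annual temperature MAT,
#' mean annual precipitation MAP) used by the climate regressions.
#'
#' Scalars for `temperature`, `water` and `xi_no` are recycled across layers.
#'
#' @param npp plant carbon input, gC m^-2 yr^-1.
#' @param temperature soil temperature per layer (degC), scalar recycled.
#' @param water relative water availability per layer in `[0, 1]`.
#' @param grid a [make_layer_grid()] grid.
#' @param xi_no nitrogen-oxygen modifier per layer in `(0, 1]`.
#' @param mat,map site mean annual temperature (degC) and precipitation
#'   (mm yr^-1); default MAT to the surface-layer temperature.
#' @return object of class `soilcue_forcings`.
#' @export
site_forcings <- function(npp, temperature, water, grid, xi_no = 1,
                          mat = NULL, map = NA_real_) {
  n <- grid$n_layers
  expand <- function(x, what) {
    if (length(x) == 1) x <- rep(x, n)
    if (length(x) != n) stop("'", what, "' must have length 1 or n_layers")
    if (any(!is.finite(x))) stop("non-finite '", what, "'")
    x
  }
  temperature <- expand(temperature, "temperature")
  water <- expand(water, "water")
  xi_no <- expand(xi_no, "xi_no")
  if (any(water < 0 | water > 1)) stop("'water' must lie in [0, 1]")
  if (any(xi_no <= 0 | xi_no > 1)) stop("'xi_no' must lie in (0, 1]")
  if (!is.finite(npp) || npp < 0) stop("'npp' must be finite and >= 0")
  if (is.null(mat)) mat <- temperature[1]
  out <- list(npp = npp, temperature = temperature, water = water,
              xi_no = xi_no, mat = mat, map = map, n_layers = n)
  class(out) <- "soilcue_forcings"
  out
}

#' Environmental rate modifier profile
#'
#' Multiplicative modifiers of the baseline decomposition rates per layer:
#' temperature `xi_T = Q10^((T - 25) / 10)` (reference 25 degC), moisture
#' `xi_W = w / (w + psi_half)` (saturating in relative water availability
#' `w`, half-saturation `psi_half`, clamped to `[0, 1]`), depth
#' `xi_D = exp(-z / z_tau)`, and the supplied nitrogen-oxygen scalar
#' `xi_NO`.  The total modifier is their product, floored at `1e-10` so the
#' steady-state operators stay non-singular in very deep, effectively inert
#' layers.
#'
#' @param forcings a [site_forcings()] object on the same grid.
#' @param params parameter vector (uses `q10`, `psi_half`, `z_tau`).
#' @param grid layer grid.
#' @return object of class `soilcue_modifier`: list of per-layer vectors
#'   `xi_t`, `xi_w`, `xi_d`, `xi_no`, `xi_total`.
#' @export
environmental_modifier <- function(forcings, params, grid) {
  if (forcings$n_layers != grid$n_layers) {
    stop("forcings and grid disagree on the number of layers")
  }
  p <- params
  xi_t <- p[["q10"]]^((forcings$temperature - 25) / 10)
  xi_w <- pmin(pmax(forcings$water / (forcings$water + p[["psi_half"]]), 0), 1)
  xi_d <- exp(-grid$node_depth / p[["z_tau"]])
  xi_total <- pmax(xi_t * xi_w * xi_d * forcings$xi_no, 1e-10)
  out <- list(xi_t = xi_t, xi_w = xi_w, xi_d = xi_d, xi_no = forcings$xi_no,
              xi_total = xi_total)
  class(out) <- "soilcue_modifier"
  out
}
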