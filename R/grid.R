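#' Vertical soil layer grid
#'
#' Build the vertical discretization shared by all model operators.  The
#' default `"clm5"` scheme uses the exponentially thickening node spacing of
#' the Community Land Model, `z_i = f_s (exp(0.5 (i - 0.5)) - 1)` with
#' `f_s = 0.025` m, so the first node sits at about 0.007 m.  The
#' `"uniform"` scheme splits `max_depth` into equal layers.
#'
#' Layer interfaces are placed midway between adjacent nodes, with the soil
#' surface at 0; thicknesses are interface differences.
#'
#' @param n_layers number of layers (>= 2); the model default is 20.
#' @param scheme `"clm5"` or `"uniform"`.
#' @param max_depth column depth in m, used by the uniform scheme only.
#' @return an object of class `soilcue_grid`: a list with `n_layers`,
#'   `node_depth` (m), `thickness` (m) and `interface_depth`
#'   (length `n_layers + 1`, starting at 0).
#' @examples
#' g <- make_layer_grid(20, "clm5")
#' head(g$node_depth)
#' @export
make_layer_grid <- function(n_layers = 20, scheme = c("clm5", "uniform"),
                            max_depth = 1) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n_layers) || length(n_layers) != 1 || n_layers < 2 ||
      n_layers != round(n_layers)) {
    stop("'n_layers' must be a single integer >= 2")
  }
  n <- as.integer(n_layers)
  if (scheme == "clm5") {
    fs <- 0.025
    z <- fs * (exp(0.5 * (seq_len(n) - 0.5)) - 1)
  } else {
    if (max_depth <= 0) stop("'max_depth' must be > 0")
    dz <- max_depth / n
    z <- (seq_len(n) - 0.5) * dz
  }
  iface <- c(0, (z[-n] + z[-1]) / 2, 2 * z[n] - (z[n - 1] + z[n]) / 2)
  grid <- list(
    n_layers = n,
    node_depth = z,
    thickness = diff(iface),
    interface_depth = iface
  )
  class(grid) <- "soilcue_grid"
  stopifnot(all(diff(grid$node_depth) > 0), all(grid$thickness > 0))
  grid
}

#' @export
print.soilcue_grid <- function(x, ...) {
  cat("<soilcue_grid> ", x$n_layers, " layers, column depth ",
      signif(x$interface_depth[x$n_layers + 1], 4), " m\n", sep = "")
  invisible(x)
}
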