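# Layered SOC profile records (WoSIS-style): reading, derived stocks,
# quality control and the model-fit skill score.

#' Pedo-transfer bulk density
#'
#' Estimates bulk density from SOC content where no measured value exists:
#' `BD = alpha + beta * exp(-gamma * OM)` with `OM = 1.724 * SOC%` (organic
#' matter by the van Bemmelen factor) and fitted constants `alpha = 0.32`,
#' `beta = 1.30`, `gamma = 0.0089`.
#'
#' @param soc_content_pct SOC content in percent (gC per 100 g soil).
#' @return bulk density, g cm^-3; 1.62 at zero SOC, approaching 0.32 as
#'   organic matter grows.
#' @export
pedotransfer_bulk_density <- function(soc_content_pct) {
  if (any(soc_content_pct < 0, na.rm = TRUE)) {
    stop("SOC content must be >= 0")
  }
  om <- 1.724 * soc_content_pct
  0.32 + 1.30 * exp(-0.0089 * om)
}

#' Construct a layered SOC profile
#'
#' @param site_id identifier.
#' @param upper_cm,lower_cm layer bounds, cm, `upper < lower`, interval
#'   convention `[upper, lower)`.
#' @param soc_gC_kg SOC content, gC per kg soil.
#' @param bd_g_cm3 measured bulk density, g cm^-3; `NA` where absent.
#' @param coarse_frag_pct volumetric coarse-fragment percentage (optional).
#' @param lon,lat coordinates in degrees (optional).
#' @return object of class `soilcue_profile`.
#' @export
soc_profile <- function(site_id, upper_cm, lower_cm, soc_gC_kg,
                        bd_g_cm3 = NA_real_, coarse_frag_pct = NA_real_,
                        lon = NA_real_, lat = NA_real_) {
  n <- length(upper_cm)
  stopifnot(length(lower_cm) == n, length(soc_gC_kg) == n)
  if (any(upper_cm < 0) || any(upper_cm >= lower_cm)) {
    stop("layers must satisfy 0 <= upper_cm < lower_cm")
  }
  if (any(soc_gC_kg < 0, na.rm = TRUE)) stop("SOC content must be >= 0")
  layers <- data.frame(
    upper_cm = upper_cm, lower_cm = lower_cm, soc_gC_kg = soc_gC_kg,
    bd_g_cm3 = rep_len(bd_g_cm3, n),
    coarse_frag_pct = rep_len(coarse_frag_pct, n)
  )
  layers <- layers[order(layers$upper_cm), ]
  out <- list(site_id = site_id, lon = lon, lat = lat, layers = layers,
              qc_flags = character())
  class(out) <- "soilcue_profile"
  out
}

#' Derive layer stocks (gC m^-3)
#'
#' `stock = content (gC kg^-1) x BD (g cm^-3) x 1000 (kg m^-3 per g cm^-3)`.
#' Where measured bulk density is missing the pedo-transfer estimate is used
#' and the profile is flagged (`"bd_pedotransfer"`).  The coarse-fragment
#' multiplier `(1 - G/100)` is *not* applied to the per-layer density: it
#' belongs to areal aggregation (see [areal_stock()]).
#'
#' @param profile a [soc_profile()].
#' @return the profile with a `stock_gC_m3` column and updated `qc_flags`.
#' @export
derive_stocks <- function(profile) {
  ly <- profile$layers
  if (any(is.na(ly$soc_gC_kg))) stop("missing SOC content")
  bd <- ly$bd_g_cm3
  miss <- is.na(bd)
  if (any(miss)) {
    # content gC/kg -> percent
    bd[miss] <- pedotransfer_bulk_density(ly$soc_gC_kg[miss] / 10)
    profile$qc_flags <- union(profile$qc_flags, "bd_pedotransfer")
  }
  profile$layers$bd_used_g_cm3 <- bd
  profile$layers$stock_gC_m3 <- ly$soc_gC_kg * bd * 1000
  profile
}

#' Areal SOC stock of a profile with coarse-fragment correction
#'
#' Depth-integrated stock (kgC m^-2) over the observed layers, applying the
#' `(1 - G/100)` coarse-fragment multiplier per layer (0 where G = 100).
#'
#' @param profile profile with derived stocks.
#' @return scalar kgC m^-2.
#' @export
areal_stock <- function(profile) {
  ly <- profile$layers
  if (is.null(ly$stock_gC_m3)) stop("run derive_stocks() first")
  gmult <- 1 - ifelse(is.na(ly$coarse_frag_pct), 0, ly$coarse_frag_pct) / 100
  sum(ly$stock_gC_m3 * gmult * (ly$lower_cm - ly$upper_cm) / 100) / 1000
}

#' Quality-filter a set of profiles
#'
#' Keeps profiles with at least three observation layers *and* a maximum
#' observation depth strictly deeper than 50 cm (profiles reaching exactly
#' 50 cm are excluded).  Exclusion reasons are recorded per profile.
#'
#' @param profiles list of profiles (stocks need not be derived).
#' @return list with `kept` and `excluded` (each a list of profiles;
#'   excluded ones carry an `exclude_reason` element).
#' @export
qc_filter_profiles <- function(profiles) {
  kept <- list()
  excluded <- list()
  for (pr in profiles) {
    reasons <- character()
    if (nrow(pr$layers) < 3) reasons <- c(reasons, "too_few_layers")
    if (max(pr$layers$lower_cm) <= 50) reasons <- c(reasons, "too_shallow")
    if (length(reasons)) {
      pr$exclude_reason <- paste(reasons, collapse = ";")
      excluded[[length(excluded) + 1]] <- pr
    } else {
      kept[[length(kept) + 1]] <- pr
    }
  }
  list(kept = kept, excluded = excluded)
}

#' Coefficient of efficiency (Nash-Sutcliffe)
#'
#' `E = 1 - sum((obs - mod)^2) / sum((obs - mean(obs))^2)`: 1 for a perfect
#' model, 0 for the observation-mean predictor, negative when worse than the
#' mean.
#'
#' @param obs,mod numeric vectors of equal length >= 2.
#' @return scalar E.
#' @export
coefficient_of_efficiency <- function(obs, mod) {
  if (length(obs) != length(mod)) stop("'obs' and 'mod' lengths differ")
  if (length(obs) < 2) stop("need at least 2 observations")
  ss <- sum((obs - mean(obs))^2)
  if (ss == 0) stop("zero observed variance: E undefined")
  1 - sum((obs - mod)^2) / ss
}

#' Model-equivalent SOC at observation depths
#'
#' Maps a model steady state to a profile's observation layers: the mineral
#' pool density (DOC + MIC + ENZ + mSOC) linearly interpolated at each
#' layer's midpoint depth (constant extrapolation beyond the node range).
#'
#' @param state pool state.
#' @param grid layer grid.
#' @param profile SOC profile.
#' @return numeric vector of gC m^-3, one per observation layer.
#' @export
model_equivalent_stock <- function(state, grid, profile) {
  mineral <- rowSums(state[, MINERAL_POOLS, drop = FALSE])
  mid_m <- (profile$layers$upper_cm + profile$layers$lower_cm) / 2 / 100
  stats::approx(grid$node_depth, mineral, xout = mid_m, rule = 2)$y
}

#' Read / write profile tables
#'
#' CSV schema: `site_id, lon, lat, upper_cm, lower_cm, soc_gC_kg, bd_g_cm3,
#' coarse_frag_pct` (missing values empty).  The writer emits the same
#' schema plus derived columns when present.
#'
#' @param file CSV path.
#' @return `read_profiles` returns a list of `soilcue_profile`.
#' @export
read_profiles <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("site_id", "upper_cm", "lower_cm", "soc_gC_kg")
  if (!all(need %in% names(df))) {
    stop("profile table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$bd_g_cm3)) df$bd_g_cm3 <- NA_real_
  if (is.null(df$coarse_frag_pct)) df$coarse_frag_pct <- NA_real_
  if (is.null(df$lon)) df$lon <- NA_real_
  if (is.null(df$lat)) df$lat <- NA_real_
  lapply(split(df, df$site_id), function(d) {
    soc_profile(d$site_id[1], d$upper_cm, d$lower_cm, d$soc_gC_kg,
                d$bd_g_cm3, d$coarse_frag_pct, d$lon[1], d$lat[1])
  })
}

#' @rdname read_profiles
#' @param profiles list of profiles.
#' @export
write_profiles <- function(profiles, file) {
  rows <- lapply(profiles, function(pr) {
    cbind(site_id = pr$site_id, lon = pr$lon, lat = pr$lat, pr$layers)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' @export
print.soilcue_profile <- function(x, ...) {
  cat("<soilcue_profile> site ", x$site_id, ": ", nrow(x$layers),
      " layers to ", max(x$layers$lower_cm), " cm",
      if (length(x$qc_flags)) paste0(" [", paste(x$qc_flags, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}
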