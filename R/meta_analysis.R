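# CUE-SOC meta-analysis stage: descriptive statistics of a multi-study
# incubation table and linear mixed-effects regressions of SOC content on
# CUE, climate and depth with study-level random effects.

#' Descriptive statistics of a CUE-SOC meta table
#'
#' Isotope-stratified sample means and variances of CUE, plus pairwise
#' Pearson correlations among the fixed-effect predictors (CUE, MAT,
#' depth) with degrees of freedom `n - 2` and two-sided p values.
#'
#' @param table meta table with columns `cue, mat_C, depth_cm,
#'   isotope_method` (see [generate_meta_table()]).
#' @param var_denominator `"n-1"` (sample variance, default) or `"n"`.
#' @return list with `by_method` (data.frame method, n, mean_cue, var_cue)
#'   and `correlations` (data.frame pair, r, df, p).
#' @export
descriptive_cue_stats <- function(table, var_denominator = c("n-1", "n")) {
  var_denominator <- match.arg(var_denominator)
  strata <- split(table$cue, table$isotope_method)
  if (any(vapply(strata, length, 1L) < 2)) {
    stop("each isotope stratum needs at least 2 records")
  }
  by_method <- do.call(rbind, lapply(names(strata), function(m) {
    x <- strata[[m]]
    v <- stats::var(x)
    if (var_denominator == "n") v <- v * (length(x) - 1) / length(x)
    data.frame(method = m, n = length(x), mean_cue = mean(x), var_cue = v)
  }))
  vars <- list(cue = table$cue, mat = table$mat_C, depth = table$depth_cm)
  pairs <- utils::combn(names(vars), 2)
  correlations <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- vars[[pairs[1, k]]]
    b <- vars[[pairs[2, k]]]
    ct <- stats::cor.test(a, b)
    data.frame(pair = paste(pairs[1, k], pairs[2, k], sep = "-"),
               r = unname(ct$estimate), df = unname(ct$parameter),
               p = ct$p.value)
  }))
  list(by_method = by_method, correlations = correlations)
}

#' Mixed-effects CUE-SOC regression
#'
#' Fits `SOC ~ CUE + MAT + depth` with study-level random effects by
#' restricted maximum likelihood (lme4): random intercepts with common
#' slopes (default) or random CUE slopes, optionally adding the CUE x MAT
#' interaction.  Reports the partial coefficients with Wald standard
#' errors, z statistics and two-sided normal-approximation p values, a
#' convergence flag, and variance-inflation factors of the main-effect
#' design.
#'
#' @param table meta table (`soc_gC_kg, cue, mat_C, depth_cm,
#'   source_study`).
#' @param structure `"random-intercept"` or `"random-slope"`.
#' @param include_interaction add the CUE x MAT term.
#' @param isotope_stratified fit each isotope stratum separately as well.
#' @return list of class `soilcue_meta_fit`: `coefficients` (data.frame),
#'   `converged`, `vif`, `random_sd` (study and residual sds), `model`
#'   (the merMod), and optionally `strata` (per-isotope fits).
#' @export
fit_mixed_effects <- function(table, structure = c("random-intercept",
                                                   "random-slope"),
                              include_interaction = FALSE,
                              isotope_stratified = FALSE) {
  structure <- match.arg(structure)
  if (length(unique(table$source_study)) < 2) stop("need >= 2 studies")
  fixed <- "soc_gC_kg ~ cue + mat_C + depth_cm"
  if (include_interaction) fixed <- paste(fixed, "+ cue:mat_C")
  rand <- if (structure == "random-intercept") "(1 | source_study)" else
    "(1 + cue | source_study)"
  form <- stats::as.formula(paste(fixed, "+", rand))

  fit <- lme4::lmer(form, data = table, REML = TRUE)
  conv <- length(fit@optinfo$conv$lme4$messages) == 0

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), z = unname(z),
                      p = 2 * stats::pnorm(-abs(z)))

  # VIF of the main-effects design
  X <- table[, c("cue", "mat_C", "depth_cm")]
  vif <- vapply(seq_along(X), function(j) {
    r2 <- summary(stats::lm(X[[j]] ~ ., data = X[-j]))$r.squared
    1 / (1 - r2)
  }, 1)
  names(vif) <- names(X)

  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(coefficients = coefs, converged = conv, vif = vif,
              random_sd = stats::setNames(vc$sdcor, vc$grp), model = fit)
  if (isotope_stratified) {
    out$strata <- lapply(split(table, table$isotope_method), function(d) {
      tryCatch(fit_mixed_effects(d, structure, include_interaction),
               error = function(e) e$message)
    })
  }
  class(out) <- "soilcue_meta_fit"
  out
}

#' @export
print.soilcue_meta_fit <- function(x, ...) {
  cat("<soilcue_meta_fit> converged:", x$converged, "\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Read a meta table CSV
#'
#' Schema: `source_study, lon, lat, isotope_method, depth_cm, mat_C, cue,
#' soc_gC_kg, mbc_gC_kg, non_mbc_gC_kg`.
#'
#' @param file CSV path.
#' @return data.frame of class `soilcue_meta`.
#' @export
read_meta_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("source_study", "isotope_method", "depth_cm", "mat_C", "cue",
            "soc_gC_kg")
  if (!all(need %in% names(df))) {
    stop("meta table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$cue <= 0 | df$cue >= 1)) stop("cue must lie in (0, 1)")
  if (any(df$soc_gC_kg <= 0)) stop("soc_gC_kg must be > 0")
  class(df) <- c("soilcue_meta", "data.frame")
  df
}
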