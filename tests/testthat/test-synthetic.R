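# synthetic_data: determinism, scenario structure, profile noise, meta table.

test_that("worlds regenerate bit-for-bit under the same seed", {
  a <- generate_world(12, seed = 3, "neutral")
  b <- generate_world(12, seed = 3, "neutral")
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$params, b$params)
  expect_identical(a$truth$soc_top1m, b$truth$soc_top1m)
  c <- generate_world(12, seed = 4, "neutral")
  expect_false(identical(a$params, c$params))
  expect_error(generate_world(5, 1), "n_sites")
  expect_error(generate_world(12, 1, "bogus"), "arg")
})

test_that("true parameters stay inside prior bounds; covariates span 5 categories", {
  w <- world_small()
  defs <- param_definitions()
  for (j in seq_len(ncol(w$params))) {
    expect_true(all(w$params[, j] >= defs$lower[j] - 1e-12))
    expect_true(all(w$params[, j] <= defs$upper[j] + 1e-12))
  }
  expect_equal(ncol(w$covariates) - 1, 60)
  expect_setequal(unique(w$categories$category),
                  c("soil_structural", "soil_chemical", "climatic",
                    "vegetation", "geographic"))
})

test_that("cue-dominant scenario: CUE varies most; cold sites are more efficient", {
  w <- world_small()
  g <- w$grid
  idx <- which(w$truth$feasible)
  expect_gt(length(idx), 50)
  mets <- vapply(idx, function(i) {
    p <- microbial_params(values = w$params[i, ])
    mo <- environmental_modifier(w$forcings[[i]], p, g)
    unlist(component_system_metrics(w$truth$states[[i]], p, mo, g,
                                    w$forcings[[i]]))
  }, numeric(7))
  cv2 <- apply(mets, 1, function(x) stats::var(x) / mean(x)^2)
  expect_equal(names(which.max(cv2)), "cue_system")

  cold <- w$mat < stats::quantile(w$mat, 0.25)
  hot <- w$mat > stats::quantile(w$mat, 0.75)
  expect_gt(mean(w$params[cold, "eta_DOC"]), mean(w$params[hot, "eta_DOC"]))
})

test_that("profiles: noiseless equals truth; lognormal noise is mean-one", {
  w <- fixture("world_tiny", function() generate_world(12, seed = 8,
                                                       "cue-dominant"))
  p0 <- generate_profiles(w, noise_cv = 0, seed = 5)
  i <- which(w$truth$feasible)[1]
  pr <- p0[[i]]
  mineral <- rowSums(w$truth$states[[i]][, c("DOC", "MIC", "ENZ", "mSOC")])
  mid <- (pr$layers$upper_cm + pr$layers$lower_cm) / 2 / 100
  expect_equal(pr$layers$stock_gC_m3,
               approx(w$grid$node_depth, mineral, xout = mid, rule = 2)$y)

  # 1,000 noisy replicates of one layer average to truth within 1 percent
  vals <- vapply(1:1000, function(s)
    generate_profiles(w, noise_cv = 0.1, seed = 10000 + s)[[i]]$layers$stock_gC_m3[1],
    1)
  truth1 <- vapply(1:1000, function(s)
    generate_profiles(w, noise_cv = 0, seed = 10000 + s)[[i]]$layers$stock_gC_m3[1],
    1)
  expect_lt(abs(mean(vals / truth1) - 1), 0.01)
})

test_that("QC violations are generated at the configured rate and recovered", {
  w <- fixture("world_tiny2", function() generate_world(40, seed = 9,
                                                        "neutral"))
  profs <- generate_profiles(w, noise_cv = 0.05, seed = 6,
                             qc_violation_rate = 0.4)
  r <- qc_filter_profiles(profs)
  expect_gt(length(r$excluded), 0)
  # excluded iff the structural rules say so - bookkeeping is exact
  for (pr in r$excluded) {
    expect_true(nrow(pr$layers) < 3 || max(pr$layers$lower_cm) <= 50)
  }
  for (pr in r$kept) {
    expect_true(nrow(pr$layers) >= 3 && max(pr$layers$lower_cm) > 50)
  }
})

test_that("meta table: determinism, structure, configured effects", {
  m1 <- generate_meta_table(seed = 2)
  m2 <- generate_meta_table(seed = 2)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 132)
  expect_equal(length(unique(m1$source_study)), 16)
  expect_true(all(m1$cue > 0 & m1$cue < 1))
  expect_true(all(m1$soc_gC_kg > 0))
  # the configured CUE-MAT copula is negative
  expect_lt(cor(m1$cue, m1$mat_C), 0)

  # tau = sigma = 0 makes the table exactly linear in the fixed effects
  m0 <- generate_meta_table(effects = list(tau = 0, sigma = 0), seed = 3)
  fit <- lm(soc_gC_kg ~ cue + mat_C + depth_cm, data = m0)
  expect_equal(unname(coef(fit)), c(18, 40, -0.3, -0.15), tolerance = 1e-6)
  expect_error(generate_meta_table(n_studies = 1), "n_studies")
})

test_that("write_world emits the full text bundle", {
  d <- file.path(tempdir(), "world_out")
  w <- fixture("world_tiny", function() generate_world(12, seed = 8,
                                                       "cue-dominant"))
  files <- write_world(w, d, noise_cv = 0.1, seed = 4)
  expect_true(all(file.exists(files)))
  cov <- read.csv(file.path(d, "covariates.csv"))
  expect_equal(nrow(cov), 12)
  profs <- read_profiles(file.path(d, "profiles.csv"))
  expect_equal(length(profs), 12)
  unlink(d, recursive = TRUE)
})
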