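---
title: "soilcue: model, inference and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{soilcue: model, inference and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the engineering decisions behind
`soilcue`: the pool model and its steady states, the environmental
modifier shapes, the assimilation and upscaling protocols, what the
synthetic world does and does not emulate, and the numerical choices a
maintainer would want to know about.

## 1. The microbially explicit pool model

The state is a vector of eight carbon pools per soil layer: four litter
pools (coarse woody debris CWD, metabolic ML, cellulose CL and lignin LL
litter) and four mineral-soil pools (dissolved organic carbon DOC,
microbial biomass MIC, extracellular enzymes ENZ, mineral-associated
organic carbon mSOC), all in gC m^-3.  The dynamics are the standard
matrix form

    dX/dt = B I + A xi K X + V X

with plant input `I` (gC m^-2 yr^-1) allocated over pools and depth by
`B`, a transfer matrix `A` (unit diagonal blocks of -1; off-diagonal
diagonal blocks holding the carbon transfer fractions; the DOC <- ENZ
block is 1 because all enzyme carbon returns to DOC), baseline
decomposition rates `K`, a multiplicative environmental modifier `xi`
per layer, and a tridiagonal diffusion operator `V` (bioturbation,
cryoturbation, leaching) acting on the litter pools.

Two rates are state dependent (Michaelis-Menten, with the modifier
scaling the half-saturation constant):

* DOC assimilation: `k_DOC = v_max_assim x_MIC / (K_m_assim xi + x_DOC)`
* mSOC depolymerization: `k_mSOC = v_max_decom x_ENZ / (K_m_decom xi + x_mSOC)`

Microbial carbon use efficiency (CUE) enters through the growth
fractions of `A`: the DOC-pathway CUE is `eta_DOC = a_MIC,DOC` directly;
each litter pathway's CUE is its growth fraction renormalized by the
non-microbial bypass, e.g. `eta_ML = a_MIC,ML / (1 - a_DOC,ML)`.

## 2. Steady states: analytic forms and their domain of validity

Because no mineral pool feeds back into the litter pools, the litter
subsystem is linear and block lower-triangular; its steady state is four
tridiagonal solves (`litter_steady_state()`).

The mineral subsystem is layer-local (no transport on mineral pools,
matching the printed steady-state separation; a configuration that
extends `V` to all pools would require the numerical solver throughout).
Solving the four balances gives closed forms (`soil_steady_state()`).
One detail matters: the familiar closed form for microbial biomass,
`x_MIC = (u_MIC + eta (u_mSOC + u_DOC)) / ((1 - eta) k_MIC xi)`, is
exact only under *full recycling* — every unit of carbon leaving MIC
returning to DOC directly or via ENZ and mSOC, and mSOC decomposing
entirely to DOC.  For general transfer fractions the balance-derived
form is

    x_MIC = (u_MIC + eta (u_DOC + a_DOC,mSOC u_mSOC)) / ((1 - eta c) k_MIC xi),
    c = a_DOC,MIC + a_ENZ,MIC + a_DOC,mSOC a_mSOC,MIC,

which reduces to the familiar one when `c = 1` and `a_DOC,mSOC = 1`.
`soilcue` implements the general form; the independent ODE solver
(`integrate_to_steady_state()`) is the authority, and the analytic state
is verified as an exact fixed point of the right-hand side.

**Feasibility.**  The closed forms are meaningful only when enzymatic
capacity exceeds the incoming flux in every layer: `v_max_decom xi
x_ENZ > F_S` (and analogously for DOC uptake).  Violations mean the ODE
has no steady state in the positive orthant (a pool grows without
bound); such parameter sets are flagged infeasible and rejected during
assimilation, never clipped.

**The capacity ratio.**  Writing `f` for the microbial throughput per
unit input and `q = v_max_decom a_ENZ,MIC / k_ENZ`, the mSOC pool obeys
`x_mSOC = K_m_decom xi rho / (1 - rho)` with
`rho = (u_mSOC/f + a_mSOC,MIC) / q`.  This single expression organises
most of the package's behaviour: mSOC scales with `K_m_decom` and `xi`,
diverges as `rho -> 1`, and `rho` falls as CUE rises (more biomass means
more enzymes), which is the priming pathway.

## 3. Environmental modifier

The rate modifier is `xi = xi_T xi_W xi_D xi_NO`, with shapes chosen to
be monotone and bounded (the source framework delegates these to a land
model; the shapes here are a design decision):

* temperature: `xi_T = Q10^((T - 25)/10)`, reference 25 degC;
* moisture: `xi_W = w / (w + psi_half)` on relative water availability
  `w` in [0, 1], clamped to [0, 1];
* depth: `xi_D = exp(-z / z_tau)`;
* nutrient-oxygen: a supplied scalar, default 1, applied to all pools
  (whether it should skip the litter pools is unstated; uniform
  application is the default here).

`xi_total` is floored at 1e-10.  The exponential node-depth grid places
its deepest layers at tens to hundreds of metres, where `exp(-z/z_tau)`
underflows; without the floor the litter operator would be singular.
The floor is far below any rate that matters: those layers receive
`~beta_root^(100 z)` of the input, which underflows double precision
itself.

## 4. Vertical grid and the oracle's domain

The default 20-layer grid follows the exponential node formula
`z_i = 0.025 (exp(0.5 (i - 0.5)) - 1)` m.  Its deepest layers are
physically formal (hundreds of metres): analytically they are harmless
(closed forms evaluate to ~0 carbon), but no forward integrator can
resolve their dynamics — DOC relaxation times there reach 1e5-1e12
years, beyond double precision for any solver.  The analytic-numeric
equivalence tests therefore run on a uniform 20-layer, 2 m column,
where the pseudo-transient Newton oracle converges to machine
precision; on the exponential grid the analytic state is verified as a
fixed point of the right-hand side (residual ~1e-13 relative to the
input flux).  `integrate_to_steady_state()` itself is a
linearised-implicit-Euler continuation with the analytic Jacobian, row
and column equilibration, a small-ridge fallback for transiently
singular Jacobians, projected (positivity-preserving) Newton steps, and
convergence on *both* the residual and the Newton increment — the
residual alone is blind to slow pools, whose tiny rates map large state
errors to tiny time derivatives.

## 5. System-level metrics

`component_system_metrics()` implements the seven summaries.  Notes:

* `k_system` uses the printed two-term form (litter and mineral groups
  normalized separately); the single-normalization variant is available
  via `variant = "single"` for comparison.
* `v_system` weights the per-layer transport outflow rate by *litter*
  carbon: the transport operator acts on litter pools only, so
  total-carbon weighting would measure profile shape, not transport.
* `xi_system` uses `xi_T xi_W xi_D` only (no nutrient term), weighted
  by total layer carbon.
* `b_system` evaluates `[mean_z exp(ln(1 - Y_z)/D_z)]^5` with node
  depths in cm, the fraction of input allocated below 5 cm; under the
  asymptotic root law it equals `beta_root^5` exactly.

## 6. CUE-SOC regimes

`classify_cue_soc_regime()` sweeps `eta_DOC` holding everything else
fixed and classifies the steady-state top-1 m SOC response by Spearman
rank correlation with a dead band (|rho| < 0.2 is "null"; monotonicity,
not linearity, is the claim).  The documented regions
(`regime_presets()`) follow from the capacity-ratio algebra of section
2: a strong lignin-to-mSOC bypass with fast microbial/enzyme turnover
is priming-dominated (negative); no bypass with slow microbial turnover
is entombing-dominated (positive, carried by biomass and necromass); a
weak bypass balances the two (null).  The positive region violates the
10 percent microbial-biomass cap used in assimilation — biomass *is*
the growing store there — so the data-assimilation world is
priming-flavoured (see section 8).

## 7. Assimilation protocol

Per profile: uniform priors on the free parameters; a test phase with
independent per-coordinate Gaussian random-walk proposals (sd a fixed
fraction of each prior range; candidates outside bounds rejected); a
formal phase with multivariate Gaussian proposals at the classic
`2.38^2/d` scaling, covariance re-estimated every `adapt_every`
iterations from the accumulating formal samples, started from the
test-phase acceptances.  The likelihood is independent Gaussian per
observed layer with proportional sd (`sigma = c obs`, default
`c = 0.3`; additive and log-space variants are configurable), the
model-equivalent being the mineral-pool density interpolated at layer
midpoints.  Parameter sets are rejected outright (-Inf) when
structurally invalid, infeasible at steady state, or when profile-total
microbial biomass exceeds 10 percent of mineral SOC.  Acceptance-ratio
control is post hoc: if the formal ratio leaves [0.10, 0.50] the
proposal scale is multiplied by 0.25 (or 4) and the phase rerun once.
Three chains, 50 percent burn-in, posterior means as point estimates,
mean Gelman-Rubin <= 1.05 and Nash-Sutcliffe E > 0 as the downstream
filters.  Identical seeds give bit-identical chains.

**Scaled-down protocol.**  The package default (2,000 test / 5,000
formal iterations) is the desk-scale setting; the full protocol
(20,000 / 50,000) is one configuration flag away.  At desk scale the
free-parameter mask must be small for honest convergence: the recovery
and acceptance tests free `eta_DOC` plus shape and litter parameters
(`k_ML, K_m_assim, beta_root`) that do not share CUE's leverage on
profile magnitude.  With magnitude-degenerate parameters
(`v_max_decom`, `k_MIC`, litter growth fractions) free as well, the
posterior develops ridges that 5,000 iterations cannot traverse; the
full 23-parameter mask remains the package default for full-length
runs.  For noiseless recovery tests the proportional error is set to
`c = 0.15`: with exact observations the error term represents model
error only, and 0.3 (tuned to real-profile scatter) over-disperses the
posterior.

## 8. The synthetic world

`generate_world()` draws 60 covariates (5 categories of 12) from a
Gaussian copula (within-category correlation 0.5, across 0.15), derives
MAT in [5, 19] degC and MAP in [600, 1400] mm yr^-1 from the first
climatic covariates, NPP of roughly 350-700 gC m^-2 yr^-1, and builds
per-site true parameters as bounded logistic functions of designated
covariates plus small (0.5 percent of prior range) noise.

In the `"cue-dominant"` scenario, `eta_DOC` spans ~0.15-0.65, driven by
a soil-structural covariate and (weakly, negatively) by MAT, with the
litter growth fractions co-varying; all other parameter fields are
nearly uniform.  Design constraints that shaped the base values:

* **Feasibility everywhere.**  The capacity ratio must stay below 1 in
  every layer, including lignin-enriched deep zones.  Bioturbation is
  set small (2e-5 m^2 yr^-1) so the deep flux mix stays
  allocation-driven rather than lignin-pure.
* **The 10 percent microbial-biomass cap.**  Microbial biomass scales
  as input/(k_MIC xi) while mSOC scales as K_m_decom xi — cold sites
  push the ratio up quadratically in 1/xi.  The climate envelope,
  `k_MIC = 18 yr^-1` and `K_m_decom = 18,000 gC m^-3` keep the maximum
  site at ~9 percent.
* **Consequence: a negative CUE-SOC field.**  Under the cap, mineral
  SOC is capacity-limited and CUE acts through the priming channel, so
  high-CUE (cold) sites store *less* carbon in this world — the
  geographic pattern is inverted relative to the global observational
  one.  The world emulates the structural properties the pipeline needs
  (CUE dominating spatial parameter variance; cold sites more
  efficient; depth-declining profiles with multiplicative noise), not
  the global map.

Observation profiles are the true mineral density at randomized layer
midpoints times lognormal noise with the mean-one correction
(`meanlog = -sdlog^2/2`), so replicate means converge to truth.  What a
green test on this world establishes is that the *machinery* (solver,
sampler, network, rankings) recovers a known truth of realistic
structure — not that the model is right about any real soil.

## 9. Upscaling network

The multilayer perceptron is implemented in base R on BLAS matrix
operations (no deep-learning dependency is available or needed at this
scale): ReLU hidden layers (default 256, 512, 512, 256), 20 percent
dropout, Adadelta, minibatch 32, inputs and targets min-max normalized
to [0, 1], early selection on validation loss, and the composite
`L1 x L2` objective — ratio loss times mean squared error — whose
gradient is `RL * dMSE + MSE * dRL`.  The ratio-loss denominator is
floored at 1e-3 on the normalized scale (targets near 0 are routine
after normalization).  Bootstrap uncertainty resamples rows with
replacement (default 200 members at full scale) and reports 2 sigma
across members; the best-guess member is always trained on all rows and
is the one used for maps and the permutation analysis.  Tests use
smaller hidden layouts and epoch caps: at a few hundred training sites
the full architecture is massively over-parameterized and adds only
runtime.

## 10. Sensitivity and permutation analyses

The flattening experiment replaces one component's parameter columns by
their across-site means and reports the summed absolute top-1 m SOC
deviation and the drop in Nash-Sutcliffe explained variation, computed
against the observations (here, synthetic truth).  Plant input, being a
forcing, is perturbed by +/- two across-site standard deviations with a
seeded coin flip per site.  The proportional-response analysis scales
one component's parameters by a factor grid spanning 1 (clipping to
prior bounds, flagged) and reports percent changes of total SOC and of
the component's system metric; `lambda_for_soc_change()` interpolates
readouts such as "the scale factor at which SOC rises 10 percent".

Permutation importance follows the grouped form: each covariate
category's (normalized) columns are replaced by U(0, 1) draws — not
shuffles, though a shuffle mode exists for comparison — and the ratio
of component-grouped MSE (permuted over intact, against the
data-assimilation targets, on the normalized scale) is averaged over
repetitions.  A category with no influence gives PI ~ 1 with
Monte-Carlo error shrinking as 1/sqrt(n_perm).

## 11. Meta-analysis stage

`fit_mixed_effects()` delegates to lme4 (REML): SOC content on CUE, MAT
and measurement depth with study random intercepts (random CUE slopes
and the CUE x MAT interaction as options), Wald standard errors and
normal-approximation p values, plus variance-inflation factors of the
main-effects design.  This stage is supporting analysis; the bespoke
numerics live in the model, solver and sampler modules.  The synthetic
meta table reproduces the structure of a 132-record, 16-study
compilation with a negative CUE-MAT correlation (~-0.24) and
study-level intercept noise; sample variances use the n-1 denominator
(the n denominator is available as an option).

## 12. Known limitations

* Steady-state assumption throughout; no transient assimilation.
* The exponential grid's deep layers are formal; reported quantities
  (top-1 m stocks, metrics) never depend on them.
* Mixed-effects p values are Wald/normal approximations.
* The desk-scale MCMC frees a low-dimensional parameter subset; full
  23-parameter posteriors need the full iteration budget.
* The synthetic world's CUE-SOC relationship is negative (section 8);
  regime analysis, not the world, demonstrates the positive and null
  regimes.
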