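---
title: "Models and methods behind dyecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dyecomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dyecomp` supports experiments that validate a fluorescent mitochondrial label
as a paternity marker in broadcast spawners: a paired dyed-vs-undyed analysis
of sperm motility, a paired binomial mixed model of competitive fertilisation
share, and a simulation-based power analysis of that design. This vignette is
the package's account of the statistics: the models and their assumptions,
the parameters that matter, what the synthetic-data generators do and do not
emulate, the numerical choices, and the limitations we know about.

```{r setup}
library(dyecomp)
```

## 1. Paired motility analysis

Each of `n` males (default 18) contributes one dyed and one undyed CASA
summary: motile/total cell counts and seven kinematics — VAP, VSL, VCL (µm/s),
STR = VSL/VCL, LIN = VAP/VCL (ratios in [0, 1]), ALH (µm), BCF (Hz). The
pipeline is the classical one for highly correlated trait panels:

1. Percent motile (`100 * motile/total`) is compared by a paired *t*-test
   (df = n − 1). Percentages are left untransformed; with ~80% motility and
   n = 18 the paired differences are close enough to normal that a transform
   would only obscure units.
2. Per-male differences **undyed − dyed** are formed for each trait. The
   direction fixes all downstream signs and matches the convention of
   reporting how much the *un*dyed sample exceeds the dyed one.
3. Shapiro–Wilk screening of each difference column (flag at p ≤ α). A
   flagged nonnegative trait is square-root transformed **at the raw-value
   stage and then re-differenced** — differences can be negative, so
   transforming differences is not meaningful — and the column is
   re-screened. BCF (a count-like beat frequency) is the typical candidate.
4. PCA of the 7 difference columns **on the correlation matrix**: trait
   differences mix µm/s, Hz and dimensionless ratios, so covariance-PCA would
   just rank units. Consequences used as invariants in the tests: eigenvalues
   sum to 7, loadings (variable–component correlations, eigenvector ×
   √eigenvalue) are bounded by 1, and scores have exactly zero column means.
   Components with eigenvalue > 1 are retained (Kaiser criterion; the
   threshold is configurable because it is a convention, not a law).
   Each component is oriented so its largest-magnitude loading is positive —
   eigenvector signs are arbitrary and this makes output stable across
   linear-algebra backends.
5. One-sample *t*-tests of the retained score columns against zero.

**A structural caveat the package refuses to hide:** scores from a centred
PCA have mean *exactly* zero, so step 5 cannot reject for any input — the
*t* statistics it produces are numerically ~10⁻¹⁶. The procedure is
reproduced as practised, and the result object carries a
`structural_zero_mean` note. A test of the composite dye effect with actual
power would test the trait-difference mean vector directly (e.g. per-trait
paired *t*-tests, as the percent-motile step does, or a multivariate test);
we keep the score tests because the workflow is the point, but we flag them.

## 2. The competitive fertilisation model

Each focal/rival/female triplet is crossed three ways: (A) focal male dyed,
(B) rival dyed, (C) both undyed. Scoring labelled and fertilised eggs gives
the focal male's dyed success *X* = labelled_A/fertilised_A, the rival's dyed
success *Y*, and the overall fertilisation rate *Z* = fertilised_C/scored_C.
If the dye is inert and every egg were fertilised, *X* = 1 − *Y*; since
fertilisation is incomplete, the usable null identity is *X = Z − Y*.

**Share convention.** We model the focal male's *share of fertilised eggs*:
the dyed observation is `k = labelled_A` over `m = fertilised_A`; the undyed
observation is the share implied by *Z − Y*, i.e. `1 − Y` with *Y* the
rival's share of fertilised eggs in B, converted to counts over
`m = fertilised_C` (round-half-even; the rounding rule is fixed so results
are reproducible). This is the only construction under which *X* and *Z − Y*
are commensurate proportions with denominator *Z*. A variant treating *Y* as
a proportion of all scored eggs (`share = (Z − Y)/Z`) is available via
`share_convention = "scored"`; both are tested. A pair with *Z < Y* would
imply negative undyed success; it is truncated to 0 and **flagged, not
dropped** — dropping would silently break the paired design.

The two observations per pair are modelled as binomial with a logit link,
a fixed dye effect and a pair random intercept:

$$k_{ij} \sim \mathrm{Bin}(m_{ij}, p_{ij}), \qquad
\mathrm{logit}\, p_{ij} = \beta_0 + \beta_1 x_{ij} + u_i, \qquad
u_i \sim N(0, \sigma_u^2),$$

with \(x = 1\) for the dyed observation. The OLRE variant adds an independent
\(e_{ij} \sim N(0, \sigma_{obs}^2)\) per observation to absorb
overdispersion.

### Laplace likelihood and fitting

The marginal likelihood integrates each pair's random intercept; the
integral is approximated by Laplace's method at the conditional mode, found
by a safeguarded Newton iteration (the penalized objective is strictly
concave, so Newton with per-group step-halving converges; inner tolerance
1e-10 on the gradient, hard stop at 100 iterations with a named-group
error). At \(\sigma_u = 0\) the expression reduces *exactly* to the binomial
GLM log-likelihood, so the boundary is continuous. For the OLRE variant the
per-pair integral is over \((u_i, e_{i1}, e_{i2})\) jointly; the negated
Hessian is an arrowhead matrix, so the Newton step and log-determinant are
computed by a Schur complement, vectorized across pairs.

The outer optimization is box-constrained quasi-Newton (`optim` L-BFGS-B,
`factr = 1e4`, `pgtol = 1e-8`) over \((\beta_0, \beta_1, \log\sigma)\), from
empirical-logit starting values; \(\sigma\) is log-parameterized with box
\([10^{-4}, 20]\). A fit that lands on the lower box is refit exactly at
\(\sigma_u = 0\) (Newton-polished on the exact binomial likelihood to
machine precision) and flagged `boundary`. Complete separation in an arm is
detected and warned about; the box constraints keep estimates finite.
The test suite cross-checks estimates, likelihood, conditional modes and
SEs against `lme4::glmer` (Laplace and nAGQ = 25) and an adaptive
Gauss–Hermite oracle built independently in the helpers.

### Inference, dispersion, degrees of freedom

The dye effect is tested with a Wald *t*: \(t = \beta_1/\mathrm{se}(\beta_1)\),
with the SE from the inverse observed information of the fixed effects at
the optimum (variance components held at their estimates — the conventional
mixed-model Wald SE, and well-defined at boundary fits where the joint
Hessian is singular in the \(\log\sigma\) direction). Residual degrees of
freedom default to `n_obs − n_fixed − 1` — observations minus two fixed
effects minus the pair-level variance component; 20 − 2 − 1 = 17 in the
10-pair design — and are configurable, since df conventions for GLMMs are
genuinely contested. A Wald *Z* p-value is always reported alongside.

Dispersion is the sum of squared residuals at the *conditional* fit (fixed
effects + conditional modes, + OLRE modes where present) over residual df,
in **both** flavours — deviance-based and Pearson — because published values
are often computed either way without saying which; reporting both costs
nothing and avoids a silent choice.

**Calibration caveat (measured by this package's own test suite):** with
observation-level noise in the data, the base model's Wald *t* with
model-based SEs is anticonservative — in the suite's null calibration at the
overdispersed generator preset it rejects ~3× the nominal 5%, while the
OLRE variant is within Monte-Carlo error of nominal. The dispersion report
is printed precisely so that users notice when the base model is not to be
trusted; the OLRE fit is computed by default in `dye_effect_analysis()`.

## 3. Synthetic-data generators

The generators exist so that every stage of the pipeline is runnable and
property-testable from a seed. They emulate the *statistical observation
model* only — no sperm trajectories, chemoattraction, gamete aging or
polyspermy; those belong to the wet lab, not the likelihood.

**Motility** (`motility_gen_config()`): per male, base values of the five
free kinematics (VAP, VSL, VCL, ALH, BCF) are drawn from a multivariate
normal (default means 62/48/95 µm/s, 3.6 µm, 35 Hz; SDs 10/9/14/0.7/5;
equicorrelation 0.6 — CASA kinematics are strongly positively correlated).
Dyed and undyed measurements share the male's base values plus correlated
within-male noise (`noise_frac = 0.35` of the between-male SD), and the dyed
measurement adds the configured `dye_effect` (default zero, the inert-dye
null). STR and LIN are then *derived* as VSL/VCL and VAP/VCL with VCL taken
as the max of the three velocities — deriving the ratios is the only way to
guarantee the kinematic ordering and [0, 1] invariants for every seed, which
is why the configuration covariance is 5×5 rather than 7×7. Motile counts
are binomial over a Poisson total, centred on 149 motile cells per sample.

**Fertilisation** (`fertilisation_gen_config()`): per pair, an overall
fertilisation probability \(z_i\) is drawn from a Beta rescaled to
(0.46, 0.94) with mean 0.733 (concentration 4: spread over most of the
range); the focal male's undyed share is
\(\mathrm{logistic}(\mathrm{logit}(0.5) + u_i + e)\) with pair SD `pair_sd`
and per-trial noise `obs_sd`. Dyeing subtracts `dye_delta` **on the
probability scale** (a "specified decrease in probability" is the natural
description of a dye penalty; a logit-scale option exists behind
`dye_scale = "logit"`), clamped to [0.001, 0.999] to avoid degenerate
binomials. Egg counts are binomial throughout; all count invariants hold by
construction for every seed.

Two regimes matter:

- **Power preset (the defaults):** 10 pairs, 100 eggs per observation,
  baseline share 0.5, *pure binomial* noise. The 100-egg default is a
  reverse-calibration: with 10 pairs, a 17-df *t* at α = 0.05 and pure
  binomial sampling, the closed-form normal approximation
  \(\Phi(\delta/\sqrt{2p(1-p)/(mn)} - t_{crit})\) puts power at ≈ 0.72 for
  δ = 0.06 and ≈ 0.85 for δ = 0.07 — the regime the power module targets.
- **Realistic preset** (`preset = "realistic"`): 50 eggs per trial,
  `obs_sd = 0.42`, `pair_sd = 0.25`, mimicking an observed overdispersed
  dataset. Across seeds this reproduces a paired-difference s.e.m. of
  ≈ 0.057 (suite-measured mean 0.0566) and the qualitative
  overdispersion-to-underdispersion reversal (base Pearson dispersion > 1,
  OLRE < 1). Its *average* base-model Pearson dispersion is ≈ 1.6, not the
  ≈ 3 one might expect from the naive inflation factor \(1 + (m-1)\rho\):
  that formula ignores both that the binomial denominators are fertilised
  (not scored) egg counts and that the pair intercept and fixed effects
  absorb roughly half of the logit noise. The suite verifies the scaling:
  at the same noise level the preset's dispersion grows with the egg count
  (it roughly doubles again by 200 eggs per trial), so dispersion near 3
  and a paired-difference s.e.m. near 0.057 are signatures of *different*
  egg counts — not jointly attainable at 50 eggs. We keep the preset and
  document the tension rather than retrofit it.

One non-obvious property of the reciprocal design, derived from the
generative equations and checked Monte-Carlo in the suite: a dye penalty δ
depresses the focal male's share in cross A *and* the rival's share in cross
B, so the implied undyed share (1 − Y) is biased *up* by δ and the measured
dyed-minus-undyed contrast centres on **−2δ**. The reciprocal design is thus
twice as sensitive to a real dye effect as a naive one-trial comparison —
whereas the power simulation below models a contrast of exactly δ, making
its power estimates conservative in this respect.

## 4. Power analysis

`power_curve()` draws, for each effect size δ in the grid (default 0.01–0.10
by 0.01), `n_sims = 1000` paired experiments — per pair one undyed binomial
at share 0.5 and one dyed at 0.5 − δ over 100 eggs — refits the Laplace GLMM
and counts two-sided Wald *t* rejections at α = 0.05 (17 df). Replicates
whose fit fails are excluded from the denominator, reported in
`n_converged`, and a row is flagged if exclusions exceed 1% (at these
settings they are essentially zero; a failed fit is never counted as
significant). Each replicate's seed derives from the master seed by an
exact-in-doubles multiplicative hash (`mix_seed`), so curves are bit-identical
across runs and independent of loop order. Monte-Carlo error is
\(\sqrt{\hat p(1-\hat p)/n}\).

`minimum_detectable_effect()` first isotonic-smooths the curve (true power is
monotone in δ; raw estimates wiggle within Monte-Carlo noise) and returns the
bracketing grid interval for the target (default 0.8), erroring with a
direction when the curve never crosses. The closed-form approximation above
is kept as `power_normal_approx()` — an analytic cross-check, never the
primary path.

## 5. Numerical choices and degenerate inputs, in one place

- Inner Newton: gradient tolerance 1e-10, ≤ 100 iterations, per-group step
  halving (≤ 40); non-convergence is an error naming the group.
- Outer optimizer: L-BFGS-B, `factr = 1e4`, `pgtol = 1e-8`, boxes
  \(|\beta| \le 20\), \(\sigma \in [10^{-4}, 20]\); likelihood at the
  optimum is asserted not worse than at the start.
- σ = 0 fits are Newton-polished on the exact binomial likelihood.
- Share clamp 0.001/0.999; round-half-even for derived undyed counts.
- Zero-variance difference columns, constant Shapiro–Wilk columns, pairs
  with Z = 0 or no fertilised eggs, single-treatment males, duplicate or
  incomplete crosses: all are reported errors (or logged exclusions), never
  silent drops.
- Test-suite problem sizes: 1000-replicate power runs at the two headline
  effect sizes, 200-replicate parameter-recovery and type-I studies,
  60-seed generator calibration summaries — sizes at which Monte-Carlo error
  is small relative to the assertions being made.

## 6. Known limitations

- The Laplace approximation's likelihood error is O(1/m) per group; with
  ~20-egg denominators it can reach ~0.02 log-units (the suite measures the
  gap against a 51-node adaptive quadrature oracle and its decay with m).
  Estimates are essentially unaffected at the denominators used here, but
  likelihood-ratio comparisons on very small trials should use more eggs.
- Exactly one grouping factor plus optional OLRE; no crossed/nested designs,
  no non-logit links, no more than two competing males.
- The generators emulate summary statistics, not mechanisms: real CASA data
  have male-specific noise structure and the real fertilisation process has
  gamete-aging and density effects the observation model deliberately
  omits. Passing tests certify the statistical machinery, not those
  biological simplifications.
- Wald inference at 17 df is a convention; users who prefer other df
  policies or SE inflation by √dispersion can configure both
  (`wald_test(df = )`; the dispersion report provides the factor).
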