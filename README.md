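# dyecomp

Statistical toolkit for **dye-based sperm competition experiments** in
broadcast-spawning invertebrates. In species with doubly uniparental
mitochondrial inheritance (blue mussels and many other bivalves), one male's
sperm can be labelled with a vital mitochondrial dye and his competitive
fertilisation success read directly off fluorescent eggs. Before the label can
be trusted, two validation analyses are needed, and `dyecomp` implements both
as a reusable, seeded, fully tested pipeline:

1. **Motility**: does dyeing change sperm behaviour? A paired dyed/undyed
   comparison of CASA (computer-assisted sperm analysis) summaries — percent
   motile plus seven kinematic traits (VAP, VSL, VCL, STR, LIN, ALH, BCF) —
   via a paired *t*-test, Shapiro–Wilk screening with a targeted square-root
   transform, principal components of the per-male trait differences
   (correlation matrix, eigenvalue > 1 retention), and one-sample *t*-tests
   on retained component scores.
2. **Competitive fertilisation**: does dyeing change fertilisation success
   under competition? Reciprocal crosses per focal/rival/female triplet —
   (A) focal dyed, (B) rival dyed, (C) both undyed — give the focal male's
   dyed success *X*, the rival's dyed success *Y*, and the overall
   fertilisation rate *Z*; under no dye effect *X = Z − Y*. The paired
   dyed/undyed shares are modelled as binomial counts with a logit link,

   logit Pr(focal egg) = β₀ + β₁·dye + uᵢ,  uᵢ ~ N(0, σᵤ²) per pair,

   fitted by maximizing the **Laplace-approximated marginal likelihood**
   (implemented in-package, cross-checked against `lme4` and adaptive
   Gauss–Hermite quadrature in the test suite), with Wald *t* inference,
   deviance/Pearson dispersion diagnostics, and an observation-level
   random-effect (OLRE) variant for overdispersion.

A **simulation-based power analysis** completes the design loop: paired
binomial experiments at a grid of dye effect sizes, each refit with the GLMM,
give the power curve and the minimum detectable effect. **Synthetic-data
generators** for both experiment types make every stage runnable and testable
without any laboratory data.

## Worked example

```r
library(dyecomp)

# -- motility: 18 males, dyed vs undyed, no simulated dye effect
mot <- generate_motility(seed = 1)
motility_analysis(mot)
```

```
Percent motile (paired t, undyed - dyed): t = -0.1622, df = 17, two-sided p = 0.873 ...
PCA of paired trait differences (correlation matrix)
                        PC1   PC2   PC3  ...
vap                    0.73  0.64 -0.18
...
Eigenvalue             3.99  1.60  0.90
Cumulative % variance 57.00 79.89 92.75
retained (eigenvalue > threshold):  PC1, PC2
One-sample t-tests on retained PC scores:
 PC1: t = 0, df = 17, two-sided p = 1 ...
```

The percent-motile test finds no dye effect (none was simulated). Two
components pass the eigenvalue > 1 criterion; note the ~10⁻¹⁶-scale *t*
statistics on PC scores — centred PCA scores have mean exactly zero, so this
step of the classical workflow cannot reject by construction (the report says
so explicitly).

```r
# -- fertilisation: 10 reciprocal-cross triplets, overdispersed regime
fert <- generate_fertilisation(fertilisation_gen_config(preset = "realistic"),
                               seed = 1)
dye_effect_analysis(assemble_pairs(fert))
```

```
Competitive fertilisation, 10 pairs (0 flagged Z < Y)
  overall fertilisation rate Z: mean 0.672 +/- 0.042 s.e.m., range 0.500-0.840
  dyed - undyed share: mean -0.047 +/- 0.067 s.e.m., range -0.275-0.411
Base model Wald t: t = -1.347, df = 17, two-sided p = 0.1956 (estimate -0.208, SE 0.1544)
  residual deviance 32.34 on 17 df (dispersion 1.90); Pearson X2 30.46 (dispersion 1.79)
OLRE model Wald t: t = -0.7495, df = 17, two-sided p = 0.4638 (estimate -0.2013, SE 0.2685)
  residual deviance 7.21 on 17 df (dispersion 0.42); Pearson X2 6.67 (dispersion 0.39)
```

No dye effect on the share of fertilisations (β₁'s Wald *t* at 17 df is not
significant); the base model is overdispersed (dispersion ≈ 1.9) and the OLRE
variant absorbs it into underdispersion — the dispersion report prints both
flavours so the choice is never silent.

```r
# -- power of the 10-pair design
curve <- power_curve(power_config(delta_grid = c(0.06, 0.07)), seed = 1)
curve
#   delta power      mc_se n_converged n_sims flagged
# 1  0.06 0.703 0.01444960        1000   1000   FALSE
# 2  0.07 0.835 0.01173776        1000   1000   FALSE
minimum_detectable_effect(curve, 0.8)   # crossing between 0.06 and 0.07
```

A dye-induced decrease of 0.06 in fertilisation probability is detected in
~70% of simulated experiments, 0.07 in ~84%; 80% power falls between the two.

A thin command-line wrapper over the same functions ships in `inst/cli/`:
`dyecomp simulate-data|motility|fertilisation|power --config cfg.yaml --seed 1
--out dir`.

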