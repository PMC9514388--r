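---
title: "Modelling the perception-space of facial expressions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the perception-space of facial expressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gewmask)
```

## The measurement model

A Geneva Emotion Wheel (GEW) response is a single click on a circular
instrument: 16 emotion terms arranged clockwise in 22.5° segments, four
intensity circles per segment, neutrality at the centre. The package
reduces each click to polar coordinates and from them derives three
indices per condition:

* **bias** — circular mean of the centred errors
  `wrap(response angle − correct angle)` with the wrap convention
  `(-180°, 180°]`, positive = clockwise;
* **uncertainty** — circular variance `1 − R̄` (Fisher's uncorrected
  definition; no small-sample correction), identically
  `1 − I₁(κ)/I₀(κ)` under a Von Mises(μ, κ) model;
* **perceived intensity** — mean Euclidean pixel distance of the click
  from the wheel centre.

The *correct angle* of an emotion is the centre of its segment, computed
by dividing the wheel into equal parts. Angles are degrees clockwise
from 12 o'clock in `[0, 360)`; screen y is inverted before any angle is
computed, so wheel angles are geometric. Two conventions worth stating
because every downstream number depends on them: the wrap interval is
half-open with `+180` kept and `−180` mapped to `+180` (one
representative for the antipode), and a click exactly on a segment
boundary belongs to the clockwise-following segment.

The published descriptions of this instrument do not fix which emotion
sits at which angle, so the layout is *declared, not assumed*: any
16-label clockwise order can be passed to `gew_geometry()` or read from
YAML with `read_geometry()`. The default places the six basic emotions
in distinct segments with *interest* between happiness and surprise,
consistent with the well-replicated happiness → interest/surprise
confusion pattern; no analysis in the package depends on the specific
layout, only on its consistency. The neutral-zone radius defaults to
half the innermost ring radius and is configurable; clicks outside the
outer ring are legal and kept as recorded.

## The inferential model

Both angular indices are modelled jointly in one **location-scale Von
Mises mixed regression**, fitted by `gewls()`:

    θ_ij ~ VonMises(μ_ij, κ_ij)
    μ_ij     = 2·atan(x_ij' β_loc + u_j)     u_j ~ N(0, σ_loc²)
    log κ_ij = z_ij' β_scale + v_j           v_j ~ N(0, σ_scale²)

The half-tangent link maps the unbounded location predictor onto
`(-π, π)`; the log link keeps the concentration positive. Perceived
intensity uses the Gaussian analogue (identity mean link, log link on
the residual SD, homoscedastic by default). Participant intercepts sit
on *both* predictors by default (`random_scale = FALSE` gives the
location-only variant): per-participant differences in dispersion are
exactly what the uncertainty index measures, so omitting them by default
would push that heterogeneity into the fixed effects.

Priors are weakly informative and configurable through `gew_priors()`:
zero-centred normals with scale 1 on location-link and log-concentration
coefficients (on those scales, ±2 SD spans biases beyond ±150° and κ
from 0.14 to 7.4), half-normal(0.5) on the random-effect SDs. The
Gaussian branch auto-scales from the response (`2.5·(sd + |mean|)` on
means, log-SD prior centred at `log(sd(y))`) because pixel radii live on
a scale of hundreds.

### Sampling

No general-purpose probabilistic-programming backend is assumed: the
sampler is an **adaptive Metropolis-within-Gibbs** scheme written in
C++ — one coordinate at a time with per-coordinate step sizes adapted in
batches of 50 during warmup toward 0.44 acceptance, frozen afterwards so
the kept chain is Markov. Two details matter for correctness and
mixing:

* linear predictors are updated incrementally, so a coordinate move
  costs only the observations it touches;
* after each sweep an interweaved **non-centred rescaling move**
  proposes `log σ → log σ + δ` with all random effects scaled by
  `exp(δ)` jointly. The random-effect prior and the transformation
  Jacobian cancel analytically, leaving a cheap likelihood-plus-
  hyperprior decision. Without it the centred funnel stalls the
  hyperparameter coordinates (split-R̂ up to 2.9 on benchmarks; ~1.1
  with it).

Defaults: 4 chains, 1000 warmup + 1000 kept draws, seed-derived chain
seeds (`seed + chain − 1`), split-R̂ and autocorrelation ESS per
parameter, convergence flagged (not silently fixed) when any R̂ > 1.05,
pointwise log-likelihoods stored for cross-validation.

### The fast approximate mode

`method = "map"` replaces MCMC by posterior-mode optimisation with a
Laplace approximation, used throughout the test suite's simulation
studies. The joint mode of a hierarchical posterior is degenerate in the
centred parameterisation (σ → 0 with all effects collapsed), so the
optimiser works in the non-centred parameterisation `u = σ·z`, where the
mode is interior, with an analytic gradient; random-effect log-SDs are
then held at their mode and the remaining parameters drawn from the
conditional Gaussian — the plug-in treatment familiar from classical
mixed-model software. Characterisation against MCMC and REML oracles on
matched data: fixed-effect point estimates agree with `lme4::lmer()` to
two decimals; *contrast* posteriors (the quantities the analysis
reports) match MCMC closely because the remaining approximation error
lies along the `β + σ·z̄` ridge, which cancels in cell differences;
absolute single-cell HPDIs are conservative (wider than MCMC). Final
inference should use MCMC; the MAP mode is for calibration studies and
quick checks.

## Contrasts and decisions

`cell_posteriors()` maps draws to per-cell parameters (random effects at
zero); contrasts are computed **drawwise** and only then summarised:
mask deltas on bias and intensity (null 0), mask *ratios* on the
circular-variance scale (null 1; ratios are the conventional comparison
for variance-like quantities, and the transformed 0–1 scale is the one
the uncertainty index is reported on), and full-vs-subtle second-order
versions of both. Drawwise computation is not a stylistic choice: for
skewed variance posteriors the median of the ratio is not the ratio of
medians (a regression test pins this), and bias deltas are wrapped per
draw so cells near ±180° cannot produce spurious 360° jumps. A contrast
is flagged significant exactly when its null value lies outside the 95%
HPDI — the package applies no multiplicity correction, matching the
decision rule it implements.

`hpdi()` returns the shortest contiguous window containing
`⌈mass·S⌉` sorted draws; width ties go to the lowest window. Degenerate
(constant) draw vectors give a zero-width interval; a perfectly
antipodal angular sample has no mean direction and raises an error
rather than returning 0.

## Model comparison and null evidence

`psis_loo()` implements Pareto-smoothed importance sampling LOO: per
observation, the largest 20% of importance log-weights are replaced by
expected order statistics of a generalised Pareto distribution fitted to
the exceedances (Zhang–Stephens profile posterior), truncated at the raw
maximum; tail-shape k̂ > 0.7 is flagged. `model_probabilities()`
converts LOO results to **pseudo-BMA+** weights via a seeded Bayesian
bootstrap (1000 Dirichlet replicates). Stacking-style 0/1 collapse is
avoided deliberately: probability pairs reported for models separated by
a few elpd units with large SEs (e.g. 0.72/0.28 for an elpd gap of ~17
at SE ~196) are only reproducible by an SE-aware scheme, which
pseudo-BMA+ is; plain exp-elpd weights would give ~1/0.

`savage_dickey_bf01()` computes log Bayes factors for point nulls as
posterior over prior density at the null, with a normal approximation by
default (exact when the posterior is Gaussian, which holds well for the
trait coefficients) and a kernel estimator as the cross-check; both are
validated against the conjugate normal–normal closed form within 5%.
Positive values favour the null.

## Trait models

`fit_trait_model()` regresses each index on a mean-centred trait score
(TAS-20 or AQ), a **sum-coded** mask factor (`contr.sum`, so the trait
main effect is the slope at the average of the two mask conditions and
the interaction is half the masked-minus-unmasked slope difference) and
their product, optionally on the subtle-expression subset only. One Von
Mises fit yields the bias results (location terms) and the uncertainty
results (scale terms); a Gaussian fit on the radius yields the intensity
results. The displayed emotion enters as a cell-means nuisance factor by
default (`include_emotion = FALSE` removes it): the emotions differ
strongly in all three indices, and although the design is balanced the
nuisance term keeps the trait slopes interpretable when subsets or
unbalanced real data are analysed. Each reported coefficient carries its
posterior median, SD, 95% HPDI and Savage-Dickey logBF₀₁.

## The synthetic-cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture. It
reproduces the design exactly — per participant, 10 identities × 6
emotions × 2 mask × 2 intensity = 240 emotional trials, each cell
appearing exactly once, plus 20 neutral and 14 catch trials in 2 blocks
of 137 with 7 catch each; block composition is drawn once per cohort
(cells split evenly across blocks) and fixed across participants, with
within-block order a per-participant seeded permutation. Responses
follow the analysis' forward model: centred errors from
`VonMises(μ_cell + u_j, κ_cell · exp(v_j))`, radii from a truncated
Gaussian per cell, neutral trials from a configurable low-radius,
high-dispersion model (neutral trials are excluded from all models — no
generating parameters exist for them in the literature the defaults are
calibrated to — but remain available descriptively).

Generator defaults are the package's declaration of realistic study
conditions: cell biases between −22° and +29° with a disgust bias
(~18°) only under a mask, circular variances 0.16–0.53 roughly doubling
under a mask, intensities 118–212 px lower under a mask and for subtle
expressions, participant SDs of 4° (location) and 0.2 (log-κ), TAS
14.9 ± 6.62 and AQ 52.1 ± 8.53 (matching the reporting scale of the
instruments as printed, without reinterpreting it), and catch accuracy
Beta(24, 1) clamped to ≥ 0.76 for clean participants. Identities are 10
abstract labels (5 "F", 5 "M"). All of it round-trips through YAML
(`write_truth()` / `read_truth()`).

Two deliberate deviations from the most literal reading of the design:

* **catch flags** default to Bernoulli draws per trial
  (`simulate_responses()`), but cohorts use a *quota* model —
  `round(accuracy × 14)` correct flags, randomly placed — because with
  only 14 catch trials per session Bernoulli noise makes the realised
  accuracy cross the 0.75 exclusion boundary for participants assigned
  near it, and exclusion fixtures (139 simulated participants with 10
  failing → exactly 129 retained) must be exact;
* the exclusion boundary itself **retains** a participant at exactly
  75% (the rule excludes strictly-below-threshold accuracy).

What passing tests on this generator do *not* show about real data: the
generator draws independent Von Mises errors within cells, so it cannot
expose misfit from multimodal confusion patterns (a mass of responses on
a distant segment rather than a shifted unimodal cloud), response styles
that vary within a session, or any dependence between angular error and
radius. Conclusions about such structure need the model-comparison and
posterior-predictive machinery on real data, not the recovery suite.

## Numerical choices

* Bessel ratios `I₁/I₀` use exponentially-scaled Bessel functions, with
  the asymptotic expansion `1 − 1/(2κ) − 1/(8κ²) − …` taking over at
  κ > 700 where the scaled ratio loses accuracy; the transform is exact
  at the uniform limit (`kappa_to_circvar(0)` is identically 1).
* `kappa_mle()` and `circvar_to_kappa()` invert the ratio by monotone
  root finding to 1e-12; a resultant length of numerically 1 signals
  infinite concentration with a warning instead of a fake large number.
* The MAP gradient is analytic (C++) and finite-difference-verified to
  ~1e-8; the Laplace Hessian falls back to diagonal regularisation if a
  numerical Hessian is not positive definite.
* Von Mises sampling uses Best–Fisher rejection, vectorised in batches,
  reducing to uniform draws below κ = 1e-8.
* Problem sizes in the test suite are chosen for tight oracles at
  desk scale: parameter recovery at 40 participants × 40 trials
  (posterior medians within ±3° / ±15%), HPDI calibration over 60
  prior-drawn replicates, PSIS-LOO vs. 30 exact refits, type-I rate of
  the HPDI rule over 150 null fits, and kappa-MLE recovery averaged over
  replicates of n = 5000 (a *single* n = 5000 MLE carries ~1.5% relative
  sampling error, so per-draw 2% recovery is not a meaningful check).

## Known limitations

* The original deployed wheel's label order, Italian term mapping and
  "up" direction are not published; results depending on label
  *identity* (e.g. which neighbour absorbs a bias) require the true
  layout in the geometry config.
* Only one grouping factor (participant) is supported; stimulus-identity
  random effects are not implemented.
* MAP-mode absolute cell intervals are conservative (see above).
* PSIS-LOO is computed from full-data posteriors; observations with
  k̂ > 0.7 are flagged but not refitted.
* The real-data path expects precomputed catch-correctness flags (or a
  tolerance rule supplied upstream); scoring raw catch clicks against
  instruction text is out of scope.
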