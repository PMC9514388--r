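# gewmask

Perception-space analysis of facial-expression recognition on the Geneva
Emotion Wheel (GEW), built for experiments that cross the displayed
emotion with face-mask occlusion and expression intensity (full vs.
subtle morphs).

## The scientific problem

When an observer judges the emotion of a face on the GEW — a circular
instrument with 16 emotion terms arranged around its rim and neutrality
at the centre — every single click carries three pieces of information:

- **bias**: the circular mean of the angular errors
  `θ = response angle − correct angle`, wrapped to `(-180°, 180°]`. A
  non-zero bias is a *systematic* confusion, e.g. masked disgust read as
  anger (a clockwise shift toward the anger segment);
- **uncertainty**: the circular variance of those errors,
  `1 − R̄ = 1 − I₁(κ)/I₀(κ)` under a Von Mises model with concentration
  κ — 0 when all responses coincide, 1 when they are uniform around the
  wheel;
- **perceived intensity**: the Euclidean pixel distance of the click
  from the wheel centre.

Inference uses a Bayesian **location-scale Von Mises mixed regression**:
the angular error for trial *i* of participant *j* is

    θ_ij ~ VonMises(μ_ij, κ_ij)
    μ_ij = 2·atan(x_ij' β_loc  + u_j)        (half-tangent link)
    log κ_ij = x_ij' β_scale + v_j           (log link)

with participant random intercepts `u_j`, `v_j` on both predictors, so
bias and uncertainty are modelled *jointly* over Mask × Emotion ×
Expression-Intensity cells. Perceived intensity uses the analogous
Gaussian mixed model. Posterior contrasts follow the conventions for
these measures — differences for bias and intensity
(`Δ Mask = Mask_yes − Mask_no`, null 0), ratios for the variance-like
uncertainty (`Ratio Mask = Mask_yes / Mask_no`, null 1), second-order
versions for the intensity interaction — each summarised by the
posterior median and 95% highest-posterior-density interval (HPDI), with
an effect called significant when the null value falls outside the
interval. Model comparison uses PSIS-LOO cross-validation with
pseudo-BMA+ weights; evidence for null trait effects (TAS-20 alexithymia
and autism-quotient covariates) is quantified by Savage-Dickey Bayes
factors.

Everything is testable without any external data: a synthetic-cohort
generator reproduces the full experimental design (240 emotional + 20
neutral + 14 catch = 274 trials in two blocks of 137) and simulates
clicks from the same Von Mises forward model the analysis assumes.

## Worked example

```r
library(gewmask)

cohort <- simulate_cohort(20, seed = 42, n_low_catch = 2)
kept   <- apply_exclusion(cohort, threshold = 0.75)   # catch-trial rule
tab    <- prepare_model_table(kept$trials)
fit    <- gewls(error_deg ~ 0 + emotion:mask:intensity, data = tab,
                family = "vonmises", method = "map", seed = 42)
results_table(fit)
```

This prints (`method = "map"` is the fast approximate mode; seed 42):

```
retained: 18 of 20
   emotion   parameter                  mask_yes                   mask_no                 contrast significant
     anger        bias -25.577 [-48.080, -3.125] -22.750 [-45.480, -0.169]  -3.053 [-10.551, 4.655]       FALSE
   disgust        bias   15.517 [-8.635, 38.606]   2.543 [-21.124, 26.391]  12.783 [5.131, 19.569]*        TRUE
      fear        bias   3.817 [-21.602, 26.837]   4.428 [-18.457, 29.287]   -0.387 [-9.539, 9.061]       FALSE
 happiness        bias   7.131 [-15.740, 30.216]   2.597 [-20.918, 26.236]   4.817 [-2.434, 10.591]       FALSE
   sadness        bias   20.475 [-1.098, 45.775]    26.991 [3.047, 48.552]  -6.957 [-15.611, 3.436]       FALSE
  surprise        bias   0.218 [-24.897, 23.195]  -0.923 [-26.529, 20.118]   1.315 [-5.776, 8.305]        FALSE
     anger uncertainty      0.541 [0.409, 0.658]      0.388 [0.268, 0.509]   1.390 [1.159, 1.637]*        TRUE
   disgust uncertainty      0.550 [0.424, 0.673]      0.277 [0.172, 0.378]   1.977 [1.575, 2.439]*        TRUE
      fear uncertainty      0.547 [0.414, 0.656]      0.583 [0.459, 0.696]    0.936 [0.809, 1.050]       FALSE
 happiness uncertainty      0.507 [0.383, 0.637]      0.224 [0.150, 0.324]   2.233 [1.763, 2.748]*        TRUE
   sadness uncertainty      0.602 [0.483, 0.706]      0.534 [0.404, 0.643]    1.132 [0.995, 1.305]       FALSE
  surprise uncertainty      0.564 [0.441, 0.679]      0.256 [0.166, 0.359]   2.193 [1.716, 2.757]*        TRUE
```

Reading it: each row gives the posterior median and 95% HPDI of a cell
parameter under the masked / unmasked condition and their contrast. In
this simulated cohort the mask roughly doubles response uncertainty for
surprise, happiness and disgust (ratios ≈ 2, asterisked) but not for
fear, and only disgust shows a mask-induced bias shift (+12.8°, toward
its clockwise neighbours) — the qualitative pattern the generator's
defaults encode. `method = "mcmc"` runs the full sampler (4 chains,
split-R̂ and ESS diagnostics, pointwise log-likelihoods for
`psis_loo()` / `loo_compare()`); `fit_trait_model()` adds centred TAS/AQ
covariates with sum-coded mask interactions, and `run_pipeline()` drives
the whole workflow (simulate → preprocess → indices → fit → contrasts →
compare → traits → report) from a YAML config, writing CSV/JSON
artifacts plus a manifest with the seed and config hash.

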