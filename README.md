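# spatfcox

Spatial summary functions of multiplex tissue images as functional
covariates in additive Cox survival models.

## What this is for

Multiplex imaging platforms (mIHC, MIBI, CODEX, IMC) record, for every cell
in a tissue section, its coordinates, a phenotype label (tumor, stroma,
immune, ...) and continuous marker intensities. Each subject's image is a
*marked point pattern*, and the spatial arrangement of cell types — tumor
cells clustering among themselves versus stromal or immune cells mixing in —
may carry prognostic information beyond age, stage, or cell counts.
`spatfcox` is for biostatisticians and imaging scientists who want to test
that hypothesis with survival data: it turns each image into
distance-indexed summary curves and feeds those curves, whole, into a Cox
model rather than collapsing them to a single score.

Two summaries are built in:

* the **mark connection function** between types *i* and *j*,

      mcf_ij(r) = lambda_i lambda_j g_ij(r) / (lambda_dot g(r)),

  reported by default in its normalised form `g_ij(r)/g(r)` whose
  random-labeling baseline is exactly 1 (below 1: same-type clustering,
  "compartmentalized" tissue; above 1: cross-type mixing). Pair correlations
  are estimated by Epanechnikov-kernel smoothing of translation-corrected
  pair distances;

* the **cross-type Moran's I profile** of a continuous mark m,

      I_m^ij(r) = sum_{s in i} sum_{t in j, |d(s,t)-r|<=delta}
                  (m_s - mean_i)(m_t - mean_j)
                  / [ sum_s (m_s - mean_pool)^2 + sum_t (m_t - mean_pool)^2 ],

  the distance-banded cross-type covariance of marker expression.

The regression stage is the **additive functional Cox model**: with scalar
covariates `Z_i` and a curve `X_i(s)` on a common distance grid scaled to
[0, 1],

    log lambda_i(t) = log lambda_0(t) + Z_i' beta + \int F(s, X_i(s)) ds,

where `F(s, x) = sum_jk theta_jk B_j(s) B_k(x)` is a penalized
tensor-product cubic regression spline surface. Coefficients maximize the
Breslow-ties penalized partial log-likelihood by Newton–Raphson with step
halving; each margin's smoothing parameter is selected by maximizing the
Laplace approximate marginal likelihood; the cumulative baseline hazard
comes from the Breslow estimator. A functional-principal-component
simulation engine (`run_mse_experiment()`) compares the predictive accuracy
of scalar-only, functional-only, and combined models on held-out subjects,
and seed-deterministic generators of two-type clustered point patterns and
whole synthetic cohorts make every stage testable without data.

## Worked example

A synthetic 80-subject cohort in which mixed tumor–stroma architecture is
harmful (hazard multiplier `exp(2 (m - 0.5))` for mixing parameter `m`):

```r
library(spatfcox)
set.seed(1)
cohort <- simulate_cohort_end_to_end(cohort_sim_config(n = 80, link_coef = 2))
grid   <- common_reference_grid(cohort$patterns, n_points = 30)
curves <- lapply(cohort$patterns, mark_connection,
                 i = "tumor", j = "stroma", grid = grid)
X   <- curves_to_matrix(curves, grid)
fit <- fit_afcm(cohort$survival$time, cohort$survival$event,
                curves = X, s_grid = as.numeric(grid))
fit
#> additive functional Cox model fit
#>   subjects: 80 (59 events)
#>   functional term: 5 x 5 tensor spline, lambda = (10, 0.1)
#>   max |penalized score|: 1.64e-13
```

The first subject (mixing 0.27, fairly compartmentalized) has normalised
mcf values 0.512, 0.835, 0.968 at r = 10.3, 51.7, 103.4 microns: well below
1 at short range — tumor and stromal cells keep to their own clusters — and
approaching the random-mixing baseline only at large distances. The fitted
surface (`evaluate_surface(fit)`, here ranging from −0.11 to +0.13 on the
log-hazard scale) is positive where curves sit near 1 at moderate
distances, i.e. the model attributes higher mortality to mixed
architecture, recovering the simulated link. Surfaces are identified only
up to components additive in distance (those integrate to a
subject-independent constant), so read them as contrasts across curve
values at a fixed distance; `surface_spearman()` compares fitted and
reference surfaces on exactly the identifiable part.

Calibration of the summaries themselves can be checked with
`mcf_envelope()`, which ranks an observed curve against label-permutation
simulations with a simultaneous 95% envelope.

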