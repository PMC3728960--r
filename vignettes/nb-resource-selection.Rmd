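---
title: "Counting GPS fixes in sampling units: the NB2 resource-selection model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting GPS fixes in sampling units: the NB2 resource-selection model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbrsf)
```

## The model

`nbrsf` estimates how strongly animals select habitat from GPS telemetry, by
turning the location stream into *counts on equal-size circular sampling
units*. For unit $i$ with covariates $x_{1i},\dots,x_{pi}$ and count $t_i$
(the number of recorded fixes inside its disc), the model is a log-link NB2
negative binomial regression

$$
t_i \sim \mathrm{NB2}(u_i,\ \theta), \qquad
\log u_i = \ln T + \beta_0 + \beta_1 x_{1i} + \dots + \beta_p x_{pi},
$$

with variance $u + u^2/\theta$. The fixed offset $\ln T$ — the log of the
total number of recorded fixes — rescales the response so that
$\exp(\beta_0 + \sum_j \beta_j x_{ji})$ is the *relative frequency* of use of
a unit: an estimate of the probability that any one fix lands there. That is
what makes the fitted object a resource selection *probability* function
(RSPF) rather than only a function proportional to use. Dropping the offset
recovers a model for raw counts.

Two properties of the sampling design make the NB likelihood appropriate:

* Units either do not overlap (systematic design) or may overlap with
  multi-counting (random design with replacement). In both cases the unit
  counts are **not** constrained to sum to $T$, so they can be treated as
  independent overdispersed counts rather than a multinomial vector.
* Units share one radius, so a unit's count is comparable across space.

Temporal correlation between consecutive fixes is *not* an obstacle: the
response lives on the units, which carry no time stamp. What does matter is
that all animals are sampled on the same fix schedule.

## Sampling designs

`random_units()` draws centers uniformly (with replacement) over the region;
`systematic_units()` lays a square lattice with a seeded random origin and
requires `spacing >= 2 * radius` so discs cannot overlap. Hexagonal lattices
would serve equally well but are not implemented. Centers must lie inside
the region; the discs themselves may cross the boundary, since covariates
are routinely measured on footprints extending past a study-area fence.
A location exactly on a disc boundary is counted inside (closed disc): the
event has probability zero under any continuous location distribution, and
a fixed rule keeps counting exact and testable.

One practical caveat found while validating the estimator on synthetic data:
when the generating intensity is zero outside the fence, units whose discs
cross the fence lose part of their footprint, and because that loss
correlates with boundary-distance covariates it biases their coefficients.
If the available space truly ends at a fence, prefer unit centers at least
one radius inside it, or model the truncation explicitly.

## Fitting and diagnostics

`fit_nb2()` maximizes the joint likelihood by alternating

1. iteratively reweighted least squares for $\beta$ at fixed $\theta$
   (weights $u/(1 + u/\theta)$), and
2. a one-dimensional profile maximum-likelihood step for $\theta$ on the log
   scale (which enforces $\theta > 0$),

until the log-likelihood changes by less than $10^{-8}$ (at most 100 outer
iterations; non-convergence is a structured error, never a silent partial
fit). Starting values are the Poisson-regression coefficients and the
method-of-moments dispersion $\max(0.01,\ \bar y^2 / (s^2 - \bar y))$. The
pmf is evaluated with log-gamma arithmetic. Near the Poisson limit
($\theta \to \infty$) the log-likelihood carries floating-point noise of
order $\varepsilon\, n\, \theta$ from log-gamma cancellation, so the
convergence test adds that allowance to the tolerance; estimates in that
regime are indistinguishable from a Poisson fit (and are checked against one
in the tests).

Reported standard errors are inverse-Fisher-information SEs for $\beta$ at
the optimum, conditioning on $\hat\theta$ (the convention of standard NB
fitters, against which the implementation is cross-checked). Two diagnostics
accompany every fit:

* `gof_deviance_ratio()` — residual deviance over $n - (p+1)$; values
  substantially above 1 point to groupings (panel structure) or other
  violations. This is informal: no reference distribution is attached.
* `expected_zero_proportion()` — the average fitted probability of an empty
  unit, $(1/n)\sum_i (\hat\theta/(\hat\theta + \hat u_i))^{\hat\theta}$, to
  be compared with the observed zero fraction. We average per-unit zero
  probabilities rather than evaluating at the overall mean count; for
  realistic fits the two differ little, but the per-unit average is the
  quantity the data actually constrain. A large gap flags zero inflation;
  no hurdle or zero-inflated model is fit here.

## Among-animal inference

GPS counts are panel data: fixes cluster within animals, ML standard errors
are anti-conservative, and the *animal* is the experimental unit. The
endorsed path is `bootstrap_by_animal()`: resample the $m$ animals with
replacement (default $B = 1000$ replicates), pool the drawn animals' counts
(a twice-drawn animal counts twice), recompute the replicate offset
$\ln T_b$ from the replicate's own pooled fix total, and refit. The SD of
the replicate coefficients is the SE; the central 90% (default) of the
replicate distribution is the confidence interval, with type-7
(linear-interpolation) percentiles, fixed and documented. Replicates that
fail to converge are dropped with a warning and counted in `n_failed`; more
than 20% failures aborts. Using each replicate's own $T_b$ (rather than the
original $T$) keeps every replicate a coherent relative-frequency model;
only the intercept is sensitive to the choice.

Within-animal fixes are never resampled — doing so would pretend the fixes
were independent, which is exactly the assumption the method avoids.
Whether the unit sample itself should be re-drawn per replicate is a design
choice; here the units are held fixed and only animals are resampled, so the
intervals describe among-animal uncertainty on the given design.

`two_stage()` is the alternative: fit each animal separately (offset
$\ln T_a$), average coefficients with equal weight, and use the spread
across animals for the SE of the mean. Because each animal's intercept
absorbs its own normalization, the average describes geometric-mean
selection — an RSF, not an RSPF. Animals whose counts cannot support a fit
are excluded with a warning and listed, never silently dropped.

`rate_ratio(b, delta)` converts a coefficient into
$100(\exp(b\,\delta) - 1)$, the percent change in expected relative use per
`delta` change in the covariate. Field usage often labels $\exp(b)$ an
"odds ratio"; under a log link it is strictly a rate ratio, and that is the
quantity computed.

## Prediction, profiles, maps

`predict_units()` evaluates $\exp(\hat\beta_0 + \sum_j \hat\beta_j x_j)$ —
the training offset is *excluded*, which is precisely what puts predictions
on the relative-frequency scale. Mapping at a finer grid than the modeling
sample is valid (`prediction_surface()`), and map units may overlap, so raw
predictions need not sum to 1; `rescale = "unit_sum"` renormalizes to a
probability vector and `"max1"` to a 0–1 habitat-quality score. Prediction
units must share the modeling radius, and covariates outside the modeled
range trigger a warning (not an error — mapping grids routinely poke
slightly past the sampled units, but extrapolated predictions deserve
suspicion).

`marginal_profile()` sweeps one covariate across its observed range —
never beyond — holding the others at their observed medians, evaluates
every bootstrap replicate on the grid, and reports the per-point median and
central-percentile envelope, all jointly divided by the overall maximum so
the display peaks at exactly 1.

## The synthetic herd

`sim_spec()` / `simulate_locations()` generate GPS data with known truth:
each animal $a$ receives coefficients $\beta_a = \beta + N(0, \sigma)$ and
places its fixes independently over a 25-m lattice with probability
proportional to $\exp(\beta_a' x)$, jittered within cells and stamped on an
hourly schedule. Covariate surfaces are smooth *deterministic* functions
(gradients, radial distances, sinusoids), so every true marginal response
curve is known in closed form. Three deliberate simplifications, and what
they imply about the tests:

* **No movement model.** Fixes are i.i.d. given the animal; real telemetry
  is serially correlated. The estimator is insensitive to this by
  construction, so passing tests say nothing about movement behavior — only
  about selection estimation.
* **Intercept heterogeneity is non-identified at the location level** (it
  cancels in the per-animal normalization), so among-animal (panel)
  heterogeneity is carried by slope SDs.
* **Conditioning on exactly $T_a$ fixes per animal** makes landscape-scale
  placement multinomial rather than Poisson. When the units absorb most of
  the fixes the induced negative correlation attenuates slopes noticeably
  (we measured ~15% attenuation with discs covering 75% of the region,
  vanishing by ~40% coverage), which is the empirical footprint of the
  Poisson-sampling approximation the method relies on. Validation worlds
  therefore use designs covering well under half the region.

`elk_spec()` is the calibrated default: 10 animals, 500 hourly fixes each,
a 9 × 9 km fenced area, ~500 systematic 200-m units, and four modeled
covariates (distance to perimeter roads, percent slope, distance to the
central cover–forage edge, soil depth). A fifth fine-scale sinusoid,
`forage`, shapes the true intensity but is excluded from the default model
formula: real counts always carry structure the fitted covariates miss, and
this unmodeled patchiness is what gives the synthetic counts realistic
residual overdispersion. The among-animal coefficient SDs are deliberately
large (e.g. 0.9 on the road-distance response): that is the magnitude a
ten-animal bootstrap SE of ~0.28 implies, and it is what makes bootstrap
SEs exceed ML SEs in the default herd, as they do in real panel telemetry.
With the patchiness coefficient fixed at 3.0 the seeded end-to-end run
produces ~30–40% empty units and a fitted dispersion
$\hat\theta \approx 0.45$–0.6 with a deviance ratio near 1 — the regime a
mid-size elk telemetry study occupies. `simulate_counts()` is the
corresponding distribution-level generator (NB2 counts directly on a unit
table), used as the exact oracle for the fitter.

```{r elk, eval = FALSE}
spec <- elk_spec()
sim <- simulate_locations(spec, seed = 42)
units <- systematic_units(spec$region, spacing = 400, radius = 200, seed = 43) |>
  add_surface_covariates(spec$surfaces[spec$model_covariates]) |>
  count_locations(sim$locations)
fit <- fit_nb2(units, spec$model_covariates,
               offset_log_total = log(nrow(sim$locations)))
glance(fit)
```

## Numerical and design choices, in one place

* Closed-disc counting (`distance <= radius`); fixed for exactness.
* Square systematic lattice; random design uses rejection sampling against
  the polygon boundary, which is exactly uniform on the polygon.
* Alternating ML with log-likelihood tolerance $10^{-8}$ plus the
  Poisson-limit noise allowance described above; $\theta$ searched on
  $\log\theta \in [\log 10^{-4}, \log 10^{8}]$.
* Type-7 percentile convention for all bootstrap intervals.
* Every function that consumes randomness takes an explicit seed and is
  bit-reproducible; file outputs contain no timestamps, so identical
  configuration and seed give byte-identical files.
* The deviance uses $2\sum_i [y_i \ln(y_i/\hat u_i) - (y_i + \hat\theta)
  \ln((y_i+\hat\theta)/(\hat u_i+\hat\theta))]$ with $y\ln y := 0$ at
  $y = 0$.

## Validation problem sizes

The shipped test suite exercises, among others: parameter recovery over 100
seeded replicates of 1000 units; Wald coverage over 300 replicates of 400
units; bootstrap-interval coverage over 200 seeded replicates of a
10-animal, 81-unit homogeneous world at $B = 200$; the bootstrap-vs-ML SE
comparison over 30 replicates of an 8-animal heterogeneous world at
$B = 100$; and the end-to-end elk-scale run above. These sizes were chosen
so each study is statistically informative (binomial error on a coverage
estimate at $n = 200$ is about two percentage points) while the whole suite
stays comfortably runnable on a laptop.

## Limitations

* No zero-truncated, hurdle, or zero-inflated NB fitting: the fit report
  prints observed vs expected zero proportions so the user can judge, but
  accommodating excess zeros is out of scope.
* $\theta$ is a scalar; modeling dispersion as a function of covariates is
  not supported. NB1 is provided as a variance formula only.
* Coordinates are planar meters; no geographic CRS handling, no GIS raster
  or vector ingestion — covariates arrive as columns.
* No mixed-effects or GEE alternatives; the bootstrap and the two-stage
  average are the supported inference paths.
* Fix-rate failure (detection < 1) and habitat-induced fix bias are assumed
  away; with poor fix success the counts need upstream correction.
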