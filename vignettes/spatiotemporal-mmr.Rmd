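---
title: "Bayesian spatio-temporal CAR modelling of areal maternal mortality"
author: "stmmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian spatio-temporal CAR modelling of areal maternal mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmmr)
```

## The problem

State-level maternal mortality ratios (MMR, maternal deaths per 100,000 live
births) form short panels: a handful of areas, a handful of rolling reporting
periods, small-ish counts. Raw comparisons across states confound three
sources of variation — where a state is (spatially structured risk shared
with its neighbours), idiosyncratic state effects, and when the estimate was
made (a strong national decline with state-specific departures from it).
Disease-mapping methods address exactly this: treat the observed ratio as a
Poisson count, borrow strength across neighbouring areas through a
conditional autoregressive (CAR) prior, and separate a common temporal trend
from area-specific trend deviations.

`stmmr` implements that model for an N-area by T-period count panel on a
contiguity graph, together with the surrounding workflow: a synthetic-data
generator, exceedance-probability hot-spot classification, DIC model
comparison, per-area trend regressions and heatmap standardisation, and a
reproducible pipeline driver.

## The model

Observed counts are modelled as

$$O_{it} \sim \mathrm{Poisson}(E_{it}\,\rho_{it}), \qquad
\log \rho_{it} = \alpha + s_i + u_i + \sum_k \beta_k x_{ik}
  + (\gamma + \delta_i)\,\mathrm{time}_t$$

with

* $\alpha$ — overall log risk level;
* $s_i$ — spatially structured area effect, intrinsic CAR (ICAR) prior:
  conditionally, $s_i$ is Normal around the mean of its graph neighbours
  with variance $1/(\tau_s n_i)$;
* $u_i$ — unstructured heterogeneity, iid $N(0, 1/\tau_u)$ (together with
  $s_i$ this is the usual convolution/BYM decomposition);
* $\gamma$ — common linear trend per unit of time score;
* $\delta_i$ — area-specific deviation from the common trend, ICAR prior
  with precision $\tau_\delta$; positive $\delta_i$ means locally rising
  risk;
* $\beta_k$ — coefficients of time-constant area-level covariates.

Three model variants are predefined: model 1 is the purely spatio-temporal
baseline; model 2 adds six maternal-health indicators (anaemia, low BMI,
short birth interval, contraception, caesarean section, birth order > 3);
model 3 adds eleven health-system indicators (ANC, PNC, institutional
delivery, health index, accreditation, NQAS certification, government and
out-of-pocket health expenditure, JSY coverage, population, skilled birth
attendance). `model = "custom"` accepts any covariate set.

When the observed quantity is already a standardised ratio (as MMR is), the
expected counts are taken as $E_{it} = 1$ (`expected = "unit"`, the
default). When raw counts and denominators are available,
`expected = "internal"` applies classical per-period internal
standardisation $E_{it} = P_{it}\,\sum_i O_{it} / \sum_i P_{it}$, which
preserves period totals exactly.

### Priors and identifiability

The source analyses in this literature typically leave hyperpriors and
constraints unstated, so the package fixes and documents them:

* intrinsic CAR (unit adjacency weights, no autocorrelation parameter) for
  $s$ and $\delta$, with sum-to-zero constraints per connected component —
  the canonical reading in disease mapping;
* $\tau_s, \tau_u, \tau_\delta \sim \mathrm{Gamma}(1, 0.0005)$ (shape/rate),
  a widespread weakly-informative default; override via `hyperparams()`;
* $\alpha, \gamma, \beta_k \sim N(0, 1000^2)$, vague and proper;
* islands (areas with no neighbours) get $s_i = 0$; their variation is
  absorbed by $u_i$;
* the ICAR log-kernel uses the exponent $(n - c)/2$ on $\tau$, where $c$ is
  the number of connected components (the rank deficiency of the
  pairwise-difference precision).

Time scores default to centered coding ($1..T$ minus its mean), which
decorrelates $\alpha$ and $\gamma$; `time_coding = "raw"` is available.
Covariates are z-standardised by default, so $\beta_k$ and
$\exp(\beta_k)$ refer to a one-standard-deviation change — the scale on
which published coefficient magnitudes for percentage covariates are
plausible. Both choices are surfaced in `model_spec()`.

## Inference

Posterior sampling is by adaptive Metropolis-within-Gibbs
(`run_mcmc()`; the `stmmr()` fit function wraps it):

* fixed effects: adaptive random-walk Metropolis, Robbins–Monro scaling
  toward 0.44 acceptance, frozen at the end of burn-in so detailed balance
  holds for retained draws;
* precisions: conjugate Gamma full conditionals (Gibbs);
* latent fields $s$, $u$, $\delta$: site-wise updates vectorised over
  greedy graph-colour classes (areas in one class share no edge, so their
  full conditionals are independent). Each site gets two moves per sweep —
  an independence proposal from its ICAR/iid prior full conditional (whose
  acceptance ratio is the pure likelihood ratio) and an adaptive
  random-walk refresh. The composition keeps mixing healthy whether the
  prior or the likelihood dominates;
* after every sweep the mean of $s$ is transferred into $\alpha$ and the
  mean of $\delta$ into $\gamma$ — on a connected graph this is an exact,
  likelihood-invariant reparameterisation onto the constrained space. On
  disconnected graphs the residual per-component centring is the standard
  projection and is approximate; island areas stay at 0.

Several published analyses of this model family use integrated nested
Laplace approximations instead of MCMC. The model, not the approximation
engine, is the substantive content; posterior summaries from the two
engines can differ at the second decimal.

Defaults are 4 chains of 20,000 sweeps, 10,000 burn-in, thinning 5. A seed
is mandatory and drives all randomness; identical seeds give bitwise
identical draws and reports. Acceptance rates per update type are kept in
`fit$draws$meta`; a post-adaptation scalar rate outside [0.05, 0.95]
triggers a warning.

### Post-inference summaries

* `spatial_risk()`: $\hat\rho_i = \exp(\hat s_i)$, exp of the posterior
  mean (not the mean of exp) — the conventional reporting transform, and
  the same arithmetic as the relative-risk column of
  `summarize_draws()` (`rr = exp(mean)`).
* `exceedance_prob()`: $p_i = P(\rho_i > 1 \mid Y)$, the fraction of
  retained draws with $s_i > 0$.
* `classify_areas()`: "hot" iff $p_i$ strictly exceeds the threshold
  (default 0.5); a tie at the threshold is "cold" because the rule is a
  strict inequality.
* `interaction_trend_summary()`: posterior mean and equal-tailed 95%
  interval of each $\delta_i$; direction is "rising" for strictly positive
  means, so an exactly zero mean reports "declining" — the boundary is
  fixed and documented rather than left to floating-point chance.
* `compute_dic()`: $\mathrm{DIC} = \bar D + p_D$ with
  $p_D = \bar D - D(\bar\theta)$ evaluated at the posterior means of the
  full latent field, so the effective parameter count includes the random
  effects — the convention used in disease mapping. The log-factorial term
  of the likelihood is retained, making DIC values absolute and comparable
  across models on the same data.

## The synthetic-data generator

`simulate_panel()` is the forward process of the model itself: draw $s$ and
$\delta$ from the ICAR prior (sampling the positive-eigenvalue subspace of
the graph Laplacian and centring per component), $u$ iid normal, optionally
generate standardised Gaussian covariates with a chosen correlation with
$s$, then draw Poisson counts. Defaults target the magnitudes seen in
state-level MMR tables: $\alpha = \log 100$ with unit expected counts puts
area mean counts in roughly the 20–250 band; $\gamma = -0.121$ is a
realistic common decline per period; $\tau_s = \tau_\delta = 10$,
$\tau_u = 100$ are fixture choices (published analyses state no generative
values for precisions).

What the generator does *not* emulate: survey sampling error in the source
estimates (SRS/NFHS design effects), rolling-window overlap between
adjacent reporting periods, time-varying covariates, and district-level
geography. Passing recovery tests on generated data therefore demonstrates
that the implementation inverts its own forward model at realistic sizes —
not that the substantive conclusions of any particular real-data analysis
are correct.

## Verification design and problem sizes

The test suite checks every layer against an independent route, at sizes
chosen to keep a full run inside a few minutes:

* the Poisson likelihood against per-cell `dpois`; trend fits against
  closed-form normal equations; z-scaling and internal standardisation
  against their algebraic identities;
* the ICAR kernel against a Brook's-lemma reconstruction from full
  conditionals on every labelled graph with up to 4 nodes;
* the sampler against a dense 4-dimensional grid-integration posterior on
  a 2-area, 2-time baseline problem with fixed precisions and the iid term
  switched off (`fixed_tau` and the component switches in `model_spec()`
  exist precisely to make such reduced fits expressible); marginal
  posterior means agree to well under 0.02;
* parameter recovery on the 19-state contiguity graph (T = 5, expected
  counts 100): 95% intervals for $\gamma$ cover the truth at the nominal
  rate over 20 replicate fits, trend-deviation signs are recovered for
  areas with $|\delta_i| \ge 0.05$, and contiguous blocks of elevated
  spatial risk are flagged hot;
* DIC ordering over 20 replicates in which the area heterogeneity is
  generated by a single standardised covariate ($\beta = 0.5$) with no
  latent fields in the truth. This design is deliberate: an area-level
  covariate and the unstructured heterogeneity term are nearly
  exchangeable, so when a large independent iid field is superimposed the
  DIC gap between the two candidate models shrinks toward its Monte Carlo
  noise. That is a known limitation of DIC for exchangeable area-level
  effects, not of the implementation; the comparison has power when the
  covariate genuinely drives the heterogeneity.

One further reproduction check: the relative-risk transform applied to the
published posterior means of the two covariate models reproduces the
published relative-risk column, which pins the reporting convention
`rr = exp(posterior mean)`. One row of that published table (the ANC row)
prints a relative risk equal to $\exp(-0.5)$ against a printed mean of
$-0.050$ — mutually inconsistent, presumably a typesetting slip — and is
excluded from the check.

## Numerical choices and edge cases

* Linear predictors are clipped at $\pm 700$ before exponentiation (with a
  warning counter) to avoid overflow in pathological states.
* `zscale_columns()` maps constant columns to zeros; it needs at least two
  rows.
* `fit_area_trend()` uses a $t_{T-2}$ slope interval (normal intervals are
  badly anti-conservative at T = 5); a constant response returns slope 0
  and $r^2 = 0$ by convention; an exact linear fit returns a zero-width
  interval.
* Counts must be integers: a real-valued "observed" column is rejected
  rather than silently rounded, forcing explicit preprocessing.
* Reports are written with numbers at 6 significant digits and re-read
  losslessly; CSV and JSON are supported, anything else is an error.

## Limitations

* The Poisson treatment of MMR values follows the source convention of
  fitting standardised ratios with $E = 1$; the ratios are estimates with
  their own sampling error, which the model does not propagate.
* Proper CAR and Leroux-type priors, random-walk temporal effects and
  time-varying covariates are out of scope.
* DIC comparisons between models that differ only in exchangeable
  area-level terms have limited resolution (see above); large DIC
  differences are meaningful, small ones are not.
* On disconnected graphs the per-component centring is the standard
  approximate projection; results for island areas rest entirely on the
  unstructured term.
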