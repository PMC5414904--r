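---
title: "Methods: spatial interpolation of survey-cluster indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial interpolation of survey-cluster indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustermaps)
```

## The problem

Household surveys in low- and middle-income countries report indicators
such as literacy, child stunting and modern-contraception use as binomial
proportions at a few hundred GPS-located sampling clusters. Published
cluster coordinates are randomly displaced for anonymity — up to 2 km in
urban strata, up to 5 km in rural strata, and up to 10 km for a random 1 %
of rural clusters — and the indicators are wanted as continuous 1 × 1 km
maps with honest uncertainty. `clustermaps` implements the complete
interpolation workflow on a planar metric grid, together with a synthetic
survey-world generator that makes every stage testable against known
ground truth.

All coordinates are planar metres. Geographic (lon/lat) inputs must be
pre-projected; the 1 km analysis grid is metric in nature and none of the
statistical machinery needs CRS handling. Grids are row-0-at-top with
pixel-centre registration, and rasters travel as ESRI ASCII grids (exact
decimal text, NODATA-aware).

## The observation model

Cluster proportions $y(s_i)$ at locations $s_i$ follow

$$y(s) = X(s)^\top\beta + v(s) + e(s),$$

with $v$ a zero-mean stationary Gaussian process and
$e(s) \sim N(0, \sigma_e^2)$ uncorrelated noise. $v$ has Matérn $\nu = 1$
covariance

$$C(d) = \sigma_v^2\,(\kappa d)\,K_1(\kappa d), \qquad
  \kappa = \sqrt{8}/\text{range},$$

the two-dimensional $\alpha = 2$ member of the SPDE–Matérn family
($\nu = \alpha - d/2$). $\nu$ is fixed at 1: it is the standard choice for
this model class and is not reliably estimable from cluster data anyway.
Under the $\sqrt{8\nu}/\kappa$ convention the correlation at one range is
$\sqrt{8}K_1(\sqrt{8}) \approx 0.14$.

A Gaussian likelihood is used on the proportions themselves rather than a
binomial one: every validation metric in the workflow (MSE, RMSE, MAE,
pseudo-R², bias) is computed on the proportion scale, and the Gaussian
treatment makes the trivial-model identities exact. A logit-transform
option with a delta-method back-transform exists
(`fitGP(..., logitTransform = TRUE)`) but is not the default.

### Fitting

Hyperparameters $(\sigma_v^2, \text{range}, \sigma_e^2)$ maximize the
profile log marginal likelihood — $\beta$ is concentrated out by
generalized least squares at each evaluation — using bounded multi-start
L-BFGS-B over log-parameters (default three starts spanning
low/moderate/high spatial fractions of the response variance and
domain/2 … domain/10 ranges). This is empirical Bayes: predictive standard
deviations therefore omit hyperparameter uncertainty, which is the price
of avoiding a full posterior integration; they also omit the uncertainty
of $\hat\beta$ (plug-in kriging). Covariance algebra is dense Cholesky:
with at most a few thousand clusters there is no need for sparse
approximations, and the SPDE is treated as the *definition* of the Matérn
field, not as a numerical scheme to replicate.

Prediction at new sites is conditional-Gaussian kriging. The reported
uncertainty is latent-only by default (`includeNugget = FALSE`), matching
the smooth uncertainty maps this workflow is used to draw; the nugget can
be added for predictive coverage of new observations. Reported means are
clamped to $[0, 1]$.

## The neural network

The second interpolator is a single-hidden-layer feed-forward network
written directly from its defining equations: node $j$ receives
$s_j = \sum_i W_{ij} x_i + b_j$ and emits the logistic
$1/(1 + e^{-s_j})$; hidden and output nodes both use the logistic, so the
output is automatically a proportion in $(0, 1)$. Training is full-batch
gradient descent with momentum on the mean squared error, with analytic
backpropagated gradients (verified against central finite differences in
the tests). Weights initialize Uniform(−0.5, 0.5). The hidden size is
chosen from {2, 4, 8, 16} by repeated random 70/30 sub-sampling within the
training data (ten repeats by default), and the final fit is the best of
several seeded restarts by training MSE; diverging restarts are counted
and skipped. Since a trained network is deterministic, map uncertainty
comes from an ensemble of seeded (optionally bootstrap) refits: the
surface reports the across-member mean and standard deviation.

Two baselines anchor every comparison: the trivial mean model (predicts
the training mean everywhere; its in-sample MSE equals the observed
variance, pinning pseudo-R² at exactly zero) and ordinary least squares on
the standardized covariates.

## Displacement-aware covariate extraction

Because reported cluster coordinates are displaced, covariates are not
read at the point but summarized over a disc of the stratum-specific
displacement cap: the mean over all cells whose *centres* fall within
2 km (urban) or 5 km (rural) of the reported location, ignoring missing
cells; an empty buffer falls back to the nearest non-missing cell, and a
cluster with no usable value in some layer is dropped and logged.
Cell-centre membership is unambiguous and consistent with the grid
resolution. For nonlinear models the same buffers are sampled by Monte
Carlo — uniform points in the disc, nearest-cell lookup — either averaged
per cluster or kept as replicate rows (the network path), mirroring the
linear-vs-nonlinear distinction in how displacement error is propagated.
Design-matrix columns are z-score standardized with the constants stored,
so grid prediction can feed raw covariate cells to any fitted model.

## Covariate selection

Multicollinearity is filtered by the variance inflation factor
$\mathrm{VIF}_j = 1/(1 - R_j^2)$, $R_j^2$ from regressing column $j$ on
all others plus an intercept. Filtering is iterative-greedy — remove the
largest-VIF covariate, recompute, repeat until all VIF < 3 (ties by column
order) — because one-shot removal over-prunes under shared collinearity.
Exact collinearity is reported as `+Inf`.

The jackknife sensitivity analysis is a greedy backward
leave-one-covariate-out search. A covariate set is scored by the mean
held-out pseudo-R² over ten random 70/30 splits (same splits for every
candidate, so comparisons are paired); at each round the best single
deletion is applied whenever it does not reduce the score by more than a
tolerance of 0.005, which prunes covariates whose contribution is
indistinguishable from zero while keeping any covariate whose removal
measurably hurts. The tolerance is in explained-variance units; 0.005 is
half a percentage point of explained variance, well below any practically
relevant difference. The underlying survey literature describes the
jackknife covariate selection only by intent ("the most appropriate
combination of covariates"), not procedure; covariate-wise backward
selection is the adopted interpretation, and the parsimony-direction rule
(delete when score-neutral) is what makes a pure-noise covariate reliably
removable — requiring a strict score *increase* would almost never trigger
at realistic sample sizes, since dropping one noise regressor improves
expected held-out R² by only about $\sigma^2/(n\,\mathrm{var}(y))$.

## Validation protocol

Splits are uniform random partitions, 70/30 train/test by default, with an
automatic switch to 60/20/20 train/validation/test above a configurable
cluster-count threshold (default 2000), the scheme used for large surveys.
The metric suite on an evaluation set:

* MSE, RMSE ($\mathrm{RMSE}^2 = \mathrm{MSE}$ to machine precision), MAE;
* explained variance (pseudo-R²) $1 - \mathrm{MSE}/\mathrm{var(obs)}$;
* bias $(\overline{\mathrm{pred}} - \overline{\mathrm{obs}})/\sigma_{obs}$
  — sign-preserving systematic over/under-prediction, invariant under
  common shifts and positive scalings;
* the trivial-model MSE, i.e. var(obs).

Variances are population (divide-by-$n$) throughout, so the trivial mean
model evaluated in-sample scores exactly zero explained variance and the
printed-table identity $1 - \mathrm{MSE}/\mathrm{MSE(mean)}$ is exact.
var(obs) is computed on the evaluation subset (not the full dataset),
which is what makes that identity hold. If the observations are constant,
explained variance and bias are undefined and reported as NA sentinels.
Model selection ranks by explained variance (descending), then RMSE, then
MAE — deterministic.

## The synthetic survey world

The generator emulates the full observation chain:

1. **Covariate fields** — stationary Gaussian random fields with isotropic
   Gaussian correlation, produced by FFT filtering of white noise
   (wrap-around boundary) and standardized per layer, plus optional
   deterministic distance-to-random-point layers mimicking accessibility
   covariates.
2. **Latent surface** — $p(s) = g^{-1}(\beta_0 + \sum_i \beta_i
   \mathrm{cov}_i(s) + v(s))$ with $v$ a Matérn $\nu = 1$ field simulated
   by two-dimensional circulant embedding (FFT of the covariance kernel on
   an enlarged torus; negative embedding eigenvalues are clamped to zero,
   so the realized correlation is approximate but the tested statistical
   properties — marginal variance within Monte-Carlo tolerance — hold).
   The logit link is the default (guarantees $p \in (0,1)$); the identity
   link with clamping is available.
3. **Clusters** — true locations uniform over non-missing cells (uniform
   point within the chosen cell), stratum from an urban mask,
   $n_{pos} \sim \mathrm{Binomial}(m, p(\text{true cell}))$. The urban
   mask defaults to the top quartile of a designated urbanization
   covariate, since real urban/rural status comes from census geography
   that has no synthetic counterpart.
4. **Displacement** — uniform angle and radius $\sim U[0, L]$ with
   $L = 2$ km urban / 5 km rural, and a simple-random 1 % of rural
   clusters (count = round(0.01 · n_rural)) flagged and displaced with
   $L = 10$ km. Only the caps are documented for the real procedure; the
   uniform-radius law is the simplest cap-respecting choice and yields
   mean displacement $L/2$, which the tests check.

Everything is bit-reproducible under a master seed; per-stage seeds are a
pure hash of (master seed, stage name), so changing one stage never
perturbs earlier ones.

What the generator does *not* emulate: multistage enumeration-area
sampling weights, anthropometric z-score computation (clusters are
simulated directly at the proportion level), covariate measurement error,
and the intra-urban heterogeneity that real 1 km covariates miss. Passing
tests therefore demonstrate correctness of the machinery under the stated
generative model, not mapping accuracy on any real survey.

## Default study conditions and problem sizes

The bundled demo (`demoConfig()`) is a 60 × 60 km country on the 1 km
grid: four random fields (10 km correlation) plus one distance layer,
$\beta = (-0.5, 0.8, -0.6, 0.4, 0.3, 0)$ on the logit scale (the last
covariate deliberately uninformative), spatial variance 0.3, range 15 km
(a quarter of the domain), 400 clusters of 25 respondents — sample sizes
typical of a national survey's cluster count and cluster size. Tests use
smaller worlds (25–60 cells square, 30–400 clusters) and 20-replicate
simulation batches for parameter-recovery checks; these sizes give stable
Monte-Carlo behaviour at interactive runtimes.

## Numerical choices and edge cases

* VIF with exact collinearity → `+Inf` sentinel; a single covariate always
  passes the filter.
* GP optimization bounds: $\sigma^2$ components in
  $[10^{-6}, 10^{3}] \times \mathrm{var}(y)$, range in
  $[10^{-3}, 10^{2}] \times$ domain diameter; non-finite likelihood at all
  starts raises an error suggesting rescaling.
* Predictive variances are floored at zero before taking square roots.
* Interdecile-range uncertainty maps use $2\,q_{0.9}\,\mathrm{sd} =
  2.5631\,\mathrm{sd}$ of the Gaussian predictive distribution.
* Resampling: `mean_aggregate` averages source cells by centre membership
  (conserves the global mean exactly on nested grids); `bilinear`
  renormalizes weights over non-missing neighbours; `nearest` on the
  identical grid is the identity.
* Zero-variance observation vectors make pseudo-R² and bias undefined →
  NA sentinels with a warning, never silent zeros.

## Known limitations

Predictive uncertainty omits hyperparameter and $\hat\beta$ uncertainty
(empirical Bayes, plug-in kriging). The Gaussian likelihood ignores the
binomial mean–variance relationship, so very small clusters are weighted
like large ones. The circulant-embedding simulator is approximate when
the range is large relative to the domain. Covariate selection explores
single deletions only. None of these affect the validation arithmetic,
which is purely empirical.
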