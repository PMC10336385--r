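---
title: "Estimating fleet-wide harbour porpoise bycatch from electronic monitoring data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fleet-wide harbour porpoise bycatch from electronic monitoring data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Harbour porpoises (*Phocoena phocoena*) drown in set gillnets. A small part
of a gillnet fleet carries electronic monitoring (EM) — GPS plus cameras
whose footage is reviewed to census every bycatch event — while the rest of
the fleet reports only effort (logbooks, sales notes, monthly declarations).
The quantity of management interest is the fleet-wide total bycatch per year
and area, together with its uncertainty, and whether it exceeds sustainable
removal limits for the affected population.

`embycatch` implements two estimators on a common data resolution (one row =
one vessel fishing day in one ICES statistical rectangle), plus the
surrounding harmonization, standardization and assessment steps:

1. a **stratified ratio estimator**: mean bycatch per fishing day (BPUE) per
   quarter and ICES area from the EM subset, multiplied by the fleet's
   fishing days in the same strata, with a non-parametric bootstrap interval;
2. a **model-based estimator**: a negative-binomial mixed model fitted to
   the EM fishing days, used to predict every fleet fishing day and to sum
   predictions on the natural scale with a bias correction.

## The model

For fishing day $i$, the bycatch count $y_i$ is NB2,

$$y_i \sim \mathrm{NB}(\mu_i, \theta), \qquad
\mathrm{Var}(y_i) = \mu_i + \mu_i^2/\theta,$$

with log link

$$\log \mu_i = x_i^\top \beta + b_{v(i)} + b_{y(i)} + s_{g(i)}(\ell_i).$$

The fixed effects $x_i$ are the operational and ecological covariates a
fleet logbook can supply: mesh-size class (three levels, reference
"<120 mm"), vessel-length class (five levels, reference "<8 m"), population
(assessment unit derived from the ICES area), log net-length, log
soak-time, log mean rectangle depth, and the mesh-class by log-soak-time
interaction. $b_v$ and $b_y$ are iid Gaussian vessel and year intercepts.
$s_g(\cdot)$ is a zero-mean Gaussian random field over rectangle centroids,
realized independently for each temporal group $g$ (by default each quarter
within each year, up to 44 groups over an eleven-year series), with shared
exponential covariance

$$\mathrm{Cov}\{s(\ell), s(\ell')\} = \sigma_s^2 \exp(-d(\ell,\ell')/\rho),$$

where $d$ is the great-circle distance in kilometres (the source material
does not state a metric; haversine kilometres is the natural choice at this
scale) and $\rho$ the range. Positions are rectangle centroids because
effort is only reported at rectangle resolution.

### Fitting

The marginal likelihood integrates over all latent effects $u$. We maximize
its Laplace approximation

$$\log L(\beta,\theta,\sigma) \approx
\log f(y \mid \hat u) - \tfrac12 \hat u^\top \Sigma^{-1} \hat u
- \tfrac12 \log|\Sigma| - \tfrac12 \log|H|,$$

with $\hat u$ the conditional mode found by an inner Newton solver and
$H = Z^\top W Z + \Sigma^{-1}$ the negative joint Hessian in $u$. The
implementation exploits the fixed sparsity pattern of $H$ (block structure
of the intercept terms plus one dense block per spatial group) with a cached
symbolic Cholesky factorization, so one likelihood evaluation costs a few
milliseconds at $n \approx 2000$, $q \approx 700$ latents.

The outer optimization is two-stage: first the fixed effects are profiled
out (the inner Newton runs jointly over $(\beta, u)$, solved by Schur
complement on $\beta$) and a bounded quasi-Newton search runs over the 3–5
log-scale dispersion/variance/range parameters only; the result is then
polished by a full-dimension L-BFGS-B pass on the exact Laplace objective,
because the profile step ignores the $\beta$-dependence of
$\tfrac12\log|H|$. Convergence is declared when the scaled gradient
max-norm of the marginal objective over *all* parameters (fixed effects
included) is below $10^{-3}$. Initial values: Poisson-GLM $\beta$,
$\log\theta = 0$, SDs $0.1$, $\rho$ at the median pairwise centroid
distance. Fits that end near the lower variance boundary are restarted from
perturbed starts and flagged.

Verification of this machinery is dual-route: the objective is checked
against a closed-form Gaussian linear-mixed-model marginal (Laplace is
exact there), against 1-D numerical quadrature for a one-intercept count
toy, and whole fits are checked against independent engines (`MASS::glm.nb`
without random effects, `glmmTMB` with intercept random effects). The
quadrature comparison at $10^{-3}$ requires a toy in the
information regime where the Laplace error is genuinely that small (the
error shrinks with the conditional information per group; we use counts
around 150 with $\theta = 30$ and ten observations per group). Model
structures are compared with AICc, $-2\ell + 2k + 2k(k+1)/(n-k-1)$, with
$k$ counting fixed effects, dispersion, and variance/range parameters.

### Bias-corrected aggregation

A total over fleet rows, $T = \sum_i \mu_i$, is a convex function of the
Gaussian latents, so the plug-in $\sum_i \exp(x_i\hat\beta + z_i\hat u)$
*underestimates* $E[T \mid y]$. We report

$$\hat T = \sum_i \exp\!\big(x_i\hat\beta + z_i\hat u
 + \tfrac12 z_i^\top Q z_i + \tfrac12\sigma^2_{\mathrm{new}}\big),$$

with $Q = H^{-1}$ the Laplace posterior covariance of $u$ and
$\sigma^2_{\mathrm{new}}$ the summed prior variances of random-effect
levels unseen at fit time (unmonitored vessels, unfished rectangle-group
combinations). This matches a Monte-Carlo average over the Gaussian
posterior to well under 1%. Uncertainty comes either from a delta-method SE
under the joint Gaussian approximation of $(\beta, u)$ (conditional on the
variance parameters, log-normal interval), or — the reporting default — a
parametric bootstrap that draws $(\beta, u)$ jointly from that Gaussian,
draws unseen levels from their priors, and recomputes group totals per
draw. The draw scheme deliberately conditions on the estimated variance
parameters; their sampling uncertainty is not propagated, which makes the
intervals anti-conservative when variance parameters are poorly determined.
Replicate counts are configurable; production-scale runs would use 1e5,
tests use hundreds to thousands.

### Standardized effort and standardized BPUE

On the link scale the prediction splits into an effort-related part
(intercept, mesh, vessel class, net-length, soak-time, the interaction, and
the vessel intercept) and a porpoise-related part (population, depth, year
intercept, spatial field). Freezing the porpoise part at a constant
(default: its median over the prediction rows) and summing predictions
gives the *standardized effort* index — proportional to the bycatch the
observed effort would inflict at constant porpoise density. Freezing the
effort part instead gives *standardized BPUE*, a relative porpoise-density
index over years and space. Both are relative: only ratios between entries
are meaningful, and the product of the two parts reproduces the plug-in
prediction up to one global constant, exactly. Whether depth belongs with
the effort or the porpoise group is genuinely arguable (depth selects both
fishing grounds and porpoise habitat); it sits in the porpoise group by
default and the grouping is an ordinary argument.

### Pinger scenarios

The mandatory acoustic-deterrent scope is shipped as an editable rules
table (area x vessel classes x mesh classes x quarters), not hard-coded
law. Scenario `all_effort` predicts over the whole fleet (no pinger
effect); `pinger_removed` drops all rows matching a rule, i.e. full
compliance and 100% efficacy — a deliberate lower bound on bycatch under
the regulation. Removal can only shrink a group total, which is asserted
property-style over random rule sets.

## The stratified comparator

BPUE is summed bycatch over summed fishing days per quarter x ICES-area
stratum; the raised total multiplies by fleet days in the same strata. When
the EM subset *is* the fleet, the raised total equals the observed count
exactly — a census identity the tests assert. The bootstrap resamples EM
fishing-day rows with replacement within stratum (the resampling unit is
not dictated by the method's sources; vessel-level block resampling is
available as an option), recomputing the raised total per replicate and
taking the percentile 2.5/97.5% interval. Fleet strata without EM
observations are a hard error by default, or zero-filled on request.
Coverage is verified by simulation: across 500 Poisson fleets the 95%
interval covers the true total within 92–98%.

## The synthetic fleet

Real effort and EM data of this kind are confidential (vessel identities,
positions), so the package carries a generator that emulates the fleet at
the level the model assumes — it *is* the generative model of the GLMM, with
known parameters:

* fleet structure: 100 vessels (17 EM-monitored, i.e. an `em_fraction` of
  0.17, drawn stratified over vessel classes so the monitored subset is
  representative), years 2010–2020, 33 fishing days per vessel-year,
  15 rectangles spanning the five ICES areas of the region;
* covariates: mesh classes with probabilities (0.40, 0.40, 0.20),
  vessel-class shares (0.15, 0.30, 0.25, 0.20, 0.10) allocated by largest
  remainder, log-normal soak-time (median 20 h) and net-length (median
  2000 m), fixed rectangle depths;
* parameters: intercept −7.35 (calibrated so the marginal bycatch rate is
  ≈0.085 porpoises per fishing day, the order observed in monitored
  gillnet fleets of this region), moderate positive mesh/soak/net effects,
  $\theta = 1$, $\sigma_{\mathrm{vessel}} = 0.4$, $\sigma_{\mathrm{year}} =
  0.3$, $\sigma_s = 0.6$, $\rho = 40$ km.

What it does **not** emulate: reporting errors, trip structure (rows are
independent given the latents), effort trends over years, target-species
dynamics, pinger usage behaviour, or any misspecification of the NB2/log
link. Passing tests therefore demonstrate that the estimators are correct
*under the assumed model*, not that the model is right for any real fleet.

## Numerical choices

* Spatial correlation matrices get a $10^{-8}$ diagonal jitter before
  Cholesky factorization; duplicate positions are therefore equal only to
  about $\sqrt{2\times10^{-8}}$.
* Mesh-class boundaries are "<120 mm" $=[0,120)$, "120–200" $=[120,200]$,
  ">200 mm" $=(200,\infty)$; vessel classes are half-open on the left.
  Landings-weight ties between meshes keep the larger mesh.
* Rounding of abundances, minimum population estimates and removal limits
  is half-away-from-zero, applied to each quantity independently — the
  convention that reproduces every printed cell of the assessment table.
* $N_{\min} = N / \exp(z\sqrt{\ln(1+CV^2)})$ with $z = 0.842$ (the 20th
  percentile); $z$ is an argument, validated by exact reproduction of the
  published $N_{\min}$ values.
* All randomness flows from explicit integer seeds; refitting the same data
  reproduces estimates to $10^{-8}$.

## Problem sizes used in the checks

The parameter-recovery study refits 50 fleets of ~2057 rows (17 vessels,
11 years, 11 days per vessel-year, all monitored — the scale of a realistic
monitored fleet) with the full generative structure; fixed-effect means are
required within 2 Monte-Carlo SE of truth and dispersion/variance
components within 15% relative bias of the mean. At a bycatch rate of
~0.085 events per day each dataset carries only ~200 events, and the
maximum-likelihood sampling distributions of the variance-type parameters
are then boundary-piled: a minority of fits collapse $\sigma_v$ or
$\sigma_y$ to zero or push $\theta$ to its Poisson limit (the latent terms
and the NB2 dispersion compete for the same overdispersion), and vessel
intercepts are partially confounded with the vessel-class fixed effects
when only 17 vessels span 5 classes. Mean-based bias summaries of such
distributions can sit far from the truth even when the likelihood machinery
is exact, so parts of that check are expected to fail at this information
level; the suite asserts them anyway rather than summarizing differently.
The spatial range $\rho$ is reported but not held to a bias band: with 44
groups over 15 rectangles its profile likelihood is nearly flat and its
estimate regularly runs to the search bounds — a known property of range
parameters under sparse information. Bootstrap-coverage and
residual-calibration checks use 500 replicates at $B = 5000$ and 20
replicates at 250 simulations respectively.

## Known limitations

* Prediction intervals condition on the estimated variance parameters.
* The Laplace approximation is unchecked beyond the toy regimes above for
  very low counts with strong spatial fields; a quadrature upgrade per
  group would be the natural extension.
* The stratified estimator inherits the usual ratio-estimator small-sample
  bias in strata with very few EM rows.
* Pinger rules ship as a plausible simplification of the EU scope and must
  be reviewed against the legal text before operational use.

## A minimal run

```r
library(embycatch)
cfg <- sim_config(n_vessels = 40, years = 2014:2016,
                  n_days_per_vessel_year = 25, em_fraction = 0.4, seed = 1)
res <- run_pipeline(run_config(
  out_dir = tempfile("run"), sim = cfg, true_params = true_params(),
  model_spec = bycatch_model_spec(random = "year"),
  B_stratified = 2000, B_prediction = 500,
  surveys = data.frame(year = 2020, density = 0.41, CV = 0.2), seed = 1
))
res$comparison        # stratified vs model-based totals
res$limits            # PBR / mPBR removal limits
```
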