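---
title: "Harmonizing covariance site effects: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing covariance site effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covbat)
```

## The model

Multi-site feature matrices — here written as subjects $j = 1,\dots,n_i$
at sites $i = 1,\dots,M$ with $p$ continuous features — are modeled as

$$ y_{ijv} = \alpha_v + x_{ij}^T\beta_v + \gamma_{iv} + \delta_{iv}\,e_{ijv}, $$

where $x_{ij}$ are covariates whose associations must survive
harmonization (diagnosis, age, sex, ...), $\gamma_{iv}$ and $\delta_{iv}$
are per-feature site effects on mean and scale, and the error vectors
$e_{ij} \sim N(0, \Sigma_i)$ may differ in covariance across sites.

The location-scale (ComBat) stage estimates $\alpha_v, \beta_v$ jointly
with site indicators by least squares, standardizes by the pooled residual
scale $\hat\sigma_v$, and shrinks the per-site moments of the standardized
data with method-of-moments empirical Bayes: a normal prior across
features for the location effects and an inverse-gamma prior for the
squared scale effects. Posterior means $\gamma^*_{iv}, \delta^*_{iv}$ are
computed by iterating the two conditional posterior means (each has a
closed form given the other) until the largest absolute change falls below
$10^{-4}$, capped at 100 sweeps. The joint posterior has no closed form,
so some iteration scheme must be chosen; conditional-mean iteration is the
scheme used by the location-scale harmonization literature this package
follows.

The covariance stage operates on the covariate-adjusted residuals
$e^{ComBat}_{ij}$: a PCA of the pooled residuals (sample covariance,
denominator $n-1$, computed via SVD so the $p \times p$ matrix is never
formed when $n < p$) yields scores $\xi_{ijk}$; for the leading $K$
components each site's score mean and variance is matched to the pooled
mean and variance; residuals are rebuilt from the adjusted scores and the
fitted mean surface $\hat\alpha_v + x_{ij}^T\hat\beta_v$ is re-added.
Because covariates are removed *before* the PCA, the score adjustment is
unconditional — covariate structure lives in the re-added surface, not in
the scores.

## Parameters that matter

* **`pct_var` (default 0.95) / `n_pc`** — how many leading components are
  harmonized. $K$ is the smallest count whose eigenvalues cumulatively
  explain `pct_var` of residual variance. Useful guidance is 0.90–0.95,
  the larger value for larger within-site samples: harmonizing excess
  components overfits per-site score moments estimated from few subjects
  and can *increase* site detectability (see "Known limitations").
  `n_pc = 0` reduces CovBat to ComBat exactly.
* **`eb`** (default `TRUE`) — empirical-Bayes shrinkage of the per-feature
  site effects. Disable for small $p$ (across-feature moments are then
  noisy) or when exact per-site moment matching is wanted; with
  `eb = FALSE` the harmonized per-site means and variances match the
  pooled values to machine precision.
* **`score_eb`** (default `FALSE`) — apply the empirical-Bayes machinery
  at the score level, treating the $K$ score columns as features. The
  score model $\xi_{ijk} = \mu_{ik} + \rho_{ik}\epsilon_{ijk}$ mirrors the
  feature-level model, so shrinkage is defensible; it is off by default
  because principal-component scores are ordered, heteroscedastic, and
  non-exchangeable, which makes pooling moments across "features" (here:
  components) hard to justify. Direct moment matching is the operative
  description of the method and is exact.
* **`min_site_size`** (default 3) — sites with fewer subjects are
  rejected rather than silently dropped.

## Numerical conventions

* $\hat\sigma_v$ is the pooled standard deviation of residuals after
  removing intercept, covariates, and site means, with denominator $n$.
  Per-site variances of the standardized data use denominator $n_i$. With
  these conventions standardization is exactly self-consistent: a
  single-site fit yields $\hat\delta^2 \equiv 1$, harmonizing a
  single-site dataset is the identity, and non-EB fit+transform is
  idempotent — all to machine precision rather than $O(1/n)$.
* Inverse-gamma parameterization: shape $a$ / scale $b$ with mean
  $b/(a-1)$; moment inversion $a = m^2/s^2 + 2$, $b = m(a-1)$. Stated
  explicitly because the other common parameterization silently changes
  results.
* Eigenvector signs are fixed by making each column's largest-magnitude
  element positive, so fitted models serialize and reload bit-stably.
* Components whose eigenvalue is below $10^{-12} \lambda_1$ are never
  adjusted (their score SDs are numerically zero).
* Zero-variance features are an error, not a silent drop — dropping would
  change the PCA dimensions downstream.
* Idempotence and exact covariate preservation hold in the forms stated
  above (no covariates, or scale adjustment disabled). With covariates
  *and* scale site effects, per-site rescaling perturbs the within-site
  orthogonality of residuals to covariates, so a refit on harmonized data
  recovers $\hat\beta$ only up to sampling order $O(1/\sqrt n)$ — a
  property of the location-scale model itself, not of this
  implementation.

## What the synthetic generator emulates

The real data this method targets (multi-site cortical thickness tables)
are not redistributable, so the package generates study-shaped synthetic
data. Defaults follow the simulation conditions of the evaluation this
package reproduces:

* three sites, binary "diagnosis" with prevalence 0.25, diagnosis effect
  $-0.5$ on the first $\lfloor p/4\rfloor$ features of each hemisphere
  (about half of all features);
* mean site effects $\gamma_{iv} \sim N(0, 0.1^2)$; scale site effects
  $\delta_{iv}$ from site-specific inverse-gammas IG(46, 50), IG(51, 50),
  IG(56, 50) (mean scale factors ≈ 1.11, 1.00, 0.91);
* a surrogate base correlation $S$ with bilateral block structure:
  within-hemisphere exponential decay (0.5 per index step) and a
  homotopic cross-hemisphere block equal to 0.4 times the
  within-hemisphere block. This construction is positive definite by
  design and mimics the qualitative features of a bilateral atlas
  (strong local correlation, elevated mirror-pair correlation). Baseline
  means are uniform in a plausible cortical-thickness range (2.2–3.6 mm).

Covariance site effects come in two flavors:

* **eigen-shift ("simple")**: site $i$'s error covariance is
  $S + c_i \sum_{k\le K_0} \lambda_k \phi_k \phi_k^T$ with severities
  $(-1/2, 0, 1/2)$, which cancel in the pooled covariance;
* **complex**: per-subject covariance $S + x_{ij}\Psi + \Omega_i$,
  eigenvalue-floored at $10^{-12}$ and rescaled to exactly unit diagonal
  so covariance effects never touch marginal variances. The $\Omega_i$
  are image-like smoothed random symmetric fields: high effective rank,
  off-diagonal amplitude comparable to the diagonal, indefinite (so the
  floor repair is genuinely exercised), with mutually distinct leading
  eigenvectors that also differ from $S$'s. The diagnosis-covariance
  coupling uses $\Psi = -\tfrac34 \Omega_3$, confounding site 3 with
  diagnosis. Design toggles zero the appropriate effects (`combat`: no
  covariance effects; `dx_mean`: no $\Psi$; `cov_only`: no mean/variance
  effects at all).

What the generator does **not** emulate: the spatial layout of a real
atlas beyond the 1-D index metaphor (real region adjacency is a graph,
not a line), non-Gaussian measurement error, covariate imbalance across
sites, age/sex covariates, and the specific correlation profile of any
real scanner. Passing the packaged experiments therefore demonstrates
the method's behavior under its own model assumptions plus controlled,
known covariance perturbations — not performance on any particular real
dataset, whose printed results depend on its own (restricted) correlation
structure.

## Experimental conditions used by the packaged studies

The replicate studies run by the tests and by `scripts/acceptance.R` use
three sites of 250 subjects and 62 features with 100 replicates (one
random 50/50 split and one random-forest fit per replicate and arm),
which reproduces the evaluation protocol's orderings stably while keeping
a full study in the minutes range; the covariance-recovery trend uses
per-site sizes 25–2,000, and the MANOVA null calibration uses 1,000
replicates at $n = 200$, $p = 5$. The random forest is a probability
forest with 500 trees and $\sqrt p$ candidate features per split,
single-threaded and explicitly seeded so studies are exactly
reproducible; any classifier exposing `fit`/`score` can be substituted.
Before site detection the diagnosis is residualized out of the features
by per-feature linear models fit on the *full* dataset, mirroring the
evaluation protocol this harness reproduces; a train-only option exists
for users who consider the full-data fit a leak.

## Known limitations

* Small samples with many features ($n_i \approx 25$, $p \gtrsim 48$)
  are a regime where harmonizing covariance can *inflate* site
  detection: per-site score moments are then poorly estimated and the
  adjustment imprints site-specific estimation noise. The study report
  exposes per-replicate AUCs and counts the replicates where the
  covariance-harmonized arm exceeds the location-scale arm
  (`site_auc_covbat_above_combat`) precisely so this regime is visible,
  not masked.
* MANOVA with Pillai's trace is robust to covariance inhomogeneity — in
  these synthetic conditions both harmonization arms drive the site
  rejection rate to zero, so MANOVA does not separate them; the ML
  detection experiments are the sensitive instrument here.
* Site effects whose structure lies far outside the pooled residual
  eigenspace are only partially removed; the method assumes the
  meaningful covariance structure is captured by the full-data
  components.
* Out-of-sample application (`covbat_apply`) freezes every parameter,
  including per-site score moments. New subjects must come from sites
  seen at fit time; re-estimating moments on new data is rejected by
  design because it would leak test-set information into ML evaluations.
* Covariates enter linearly; nonlinear covariate effects are out of
  scope, as are longitudinal/functional extensions and missing-data
  handling beyond rejection.
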