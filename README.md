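# covbat

Harmonization of mean, variance, and **covariance** site effects in
multi-site feature matrices.

## The problem

Multi-site studies of derived imaging measurements (for example the 62
regional cortical thickness values of a bilateral atlas) carry systematic
scanner and site effects. The widely used ComBat model removes per-feature
site effects in mean and variance: writing `y_ijv` for feature `v` of
subject `j` at site `i`,

    y_ijv = alpha_v + x_ij' beta_v + gamma_iv + delta_iv e_ijv

with protected covariates `x_ij`, mean site effects `gamma_iv`, variance
site effects `delta_iv`, and errors `e_ijv`. ComBat estimates
`alpha, beta` by least squares, shrinks per-site location/scale effects by
method-of-moments empirical Bayes (normal prior on `gamma`, inverse-gamma
prior on `delta^2`), and residualizes:

    y^ComBat = (y - alpha - x'beta - gamma*) / delta* + alpha + x'beta

This leaves the *covariance* of the error vectors `e_ij ~ N(0, Sigma_i)`
site-dependent, which multivariate (machine-learning) analyses exploit: a
classifier can often tell which scanner produced a subject's data even
after ComBat. CovBat closes that gap:

1. take ComBat residuals `e^ComBat` (covariates removed);
2. PCA of the pooled residuals: `e^ComBat_ij = sum_k xi_ijk phi_k`;
3. for the leading `K` components (smallest number explaining `pct_var`
   of variance, default 95%), model the scores as
   `xi_ijk = mu_ik + rho_ik eps_ijk` and match every site's score mean and
   variance to the pooled values;
4. reconstruct residuals from adjusted scores and re-add
   `alpha + x'beta`.

The package also ships a synthetic multi-site generator (site effects in
mean, variance, and covariance — eigenvalue shifts or complex high-rank
shift matrices, with optional diagnosis effects on covariance) and an
evaluation harness: within-site covariance Frobenius distances,
random-forest site/diagnosis detection AUC, and MANOVA with Pillai's
trace.

## Worked example

```r
library(covbat)

# three sites, 100 subjects each, 20 features; site effects in mean,
# variance, and the leading eigenvalue of the correlation structure
cfg <- sim_config("simple", n_i = 100, p = 20, seed = 5)
ds  <- simulate_dataset(cfg)
X   <- matrix(ds$x, ncol = 1, dimnames = list(NULL, "diagnosis"))

res <- covbat_harmonize(ds$Y, ds$site, X, pct_var = 0.95)
res$model$K
#> [1] 16

# mean pairwise within-site covariance distance, before and after
pd <- function(Y) {
  w <- within_site_covariances(Y, ds$site, X = ds$x)
  mean(c(frobenius_distance(w[[1]], w[[2]]),
         frobenius_distance(w[[1]], w[[3]]),
         frobenius_distance(w[[2]], w[[3]])))
}
cm <- combat_fit(ds$Y, ds$site, X)
round(c(raw    = pd(ds$Y),
        combat = pd(combat_transform(cm, ds$Y, ds$site, X)),
        covbat = pd(res$harmonized)), 2)
#>    raw combat covbat
#>   4.42   3.15   2.68
```

Raw data show the largest between-site covariance discrepancy; ComBat
shrinks the part driven by marginal variances; CovBat additionally aligns
the principal-component score variances, giving the smallest distances.
`simulation_study()` repeats this comparison (plus detection AUCs and
MANOVA rejection rates) over independently simulated replicates.

A command-line wrapper is installed at
`system.file("cli", "covbat", package = "covbat")` with subcommands
`harmonize`, `simulate`, `evaluate`, and `study`.

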