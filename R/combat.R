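#' Least-squares stage of the ComBat location-scale model
#'
#' Fits, for every feature, the linear model
#' \deqn{y_{ijv} = \alpha_v + x_{ij}^T \beta_v + \gamma_{iv} + \delta_{iv} e_{ijv}}
#' by least squares with site indicators, under the identification constraint
#' that the \eqn{n_i/n}-weighted mean of the site effects is zero for every
#' feature (so \eqn{\alpha_v} is the grand covariate-adjusted mean). Residuals
#' are standardized by the pooled residual standard deviation
#' \eqn{\hat\sigma_v} (denominator \eqn{n}), and per-site moments of the
#' standardized data give the raw location (\code{gamma_hat}) and scale
#' (\code{delta2_hat}) site effects. Per-site variances use denominator
#' \eqn{n_i} so that standardization is exactly moment-matched (a single-site
#' fit yields \code{delta2_hat} identically 1).
#'
#' @param Y numeric matrix, subjects x features.
#' @param site site labels, one per subject (coerced to factor).
#' @param X optional numeric covariate matrix (no intercept column), whose
#'   associations are preserved by harmonization.
#' @param min_site_size smallest admissible number of subjects per site.
#' @return an object of class \code{combat_naive}: \code{alpha_hat} (p),
#'   \code{beta_hat} (c x p), \code{sigma_hat} (p), \code{gamma_hat} (M x p),
#'   \code{delta2_hat} (M x p), \code{standardized} (n x p), plus bookkeeping
#'   (\code{site_levels}, \code{n_i}, \code{covariate_names}).
#' @seealso [estimate_eb()], [combat_fit()]
#' @export
fit_naive <- function(Y, site, X = NULL, min_site_size = 3L) {
  Y <- .as_feature_matrix(Y)
  n <- nrow(Y)
  p <- ncol(Y)
  site <- .as_site(site, n, min_site_size)
  X <- .as_design(X, n)
  M <- nlevels(site)
  n_i <- as.numeric(table(site))

  # full site-indicator block plus covariates (no explicit intercept: the
  # site indicators span it)
  D_site <- diag(M)[as.integer(site), , drop = FALSE]
  colnames(D_site) <- levels(site)
  design <- cbind(D_site, X)
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    dropped <- colnames(design)[qd$pivot[seq.int(qd$rank + 1L, ncol(design))]]
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  B <- qr.coef(qd, Y)                       # (M + c) x p
  site_coef <- B[seq_len(M), , drop = FALSE]
  beta_hat <- B[-seq_len(M), , drop = FALSE]
  if (ncol(X) == 0) beta_hat <- matrix(numeric(0), 0, p, dimnames = list(NULL, colnames(Y)))

  w <- n_i / n
  alpha_hat <- as.numeric(crossprod(w, site_coef))  # weighted grand mean
  names(alpha_hat) <- colnames(Y)
  resid_full <- Y - design %*% B                    # covariate- and site-adjusted
  sigma_hat <- sqrt(colMeans(resid_full^2))         # pooled, denominator n
  if (any(sigma_hat < 1e-12)) {
    stop(sprintf("zero-variance feature(s): %s",
                 paste(colnames(Y)[sigma_hat < 1e-12], collapse = ", ")), call. = FALSE)
  }

  stand_mean <- matrix(alpha_hat, n, p, byrow = TRUE)
  if (ncol(X) > 0) stand_mean <- stand_mean + X %*% beta_hat
  Z <- sweep(Y - stand_mean, 2, sigma_hat, "/")

  gamma_hat <- matrix(0, M, p, dimnames = list(levels(site), colnames(Y)))
  delta2_hat <- matrix(0, M, p, dimnames = list(levels(site), colnames(Y)))
  for (i in seq_len(M)) {
    zi <- Z[site == levels(site)[i], , drop = FALSE]
    gamma_hat[i, ] <- colMeans(zi)
    delta2_hat[i, ] <- colMeans(sweep(zi, 2, gamma_hat[i, ], "-")^2)  # denominator n_i
  }
  if (any(delta2_hat <= 0)) {
    stop("a site has zero within-site variance for some feature", call. = FALSE)
  }

  structure(list(
    alpha_hat = alpha_hat,
    beta_hat = beta_hat,
    sigma_hat = sigma_hat,
    gamma_hat = gamma_hat,
    delta2_hat = delta2_hat,
    standardized = Z,
    site_levels = levels(site),
    n_i = stats::setNames(n_i, levels(site)),
    covariate_names = colnames(X),
    min_site_size = as.integer(min_site_size)
  ), class = "combat_naive")
}

#' Empirical-Bayes shrinkage of site effects
#'
#' Method-of-moments empirical Bayes for the site effects: for each site the
#' standardized mean shifts \code{gamma_hat[i, ]} are assumed drawn from a
#' normal prior and the variance ratios \code{delta2_hat[i, ]} from an
#' inverse-gamma prior; hyperparameters are matched to the across-feature
#' moments, and posterior means are computed by iterating the two conditional
#' posterior means until the largest absolute change falls below \code{tol}.
#'
#' Inverse-gamma parameterization: shape \eqn{a}, scale \eqn{b} with mean
#' \eqn{b/(a-1)}; moment inversion \eqn{a = m^2/s^2 + 2}, \eqn{b = m (a - 1)}
#' from the across-feature mean \eqn{m} and variance \eqn{s^2} of
#' \code{delta2_hat[i, ]}.
#'
#' @param naive a \code{combat_naive} fit.
#' @param tol convergence threshold on the maximum absolute parameter change.
#' @param max_iter maximum number of conditional-mean sweeps per site.
#' @return list with \code{hyper} (per-site prior mean/variance for gamma and
#'   shape/scale for delta^2), \code{gamma_star} (M x p posterior-mean location
#'   effects) and \code{delta_star} (M x p posterior scale effects on the
#'   standard-deviation scale).
#' @export
estimate_eb <- function(naive, tol = 1e-4, max_iter = 100L) {
  stopifnot(inherits(naive, "combat_naive"))
  p <- ncol(naive$gamma_hat)
  if (p < 2) stop("empirical Bayes needs at least 2 features for across-feature moments", call. = FALSE)
  M <- nrow(naive$gamma_hat)
  gamma_star <- naive$gamma_hat
  delta_star <- sqrt(naive$delta2_hat)
  hyper <- list(
    gamma_prior_mean = numeric(M), gamma_prior_var = numeric(M),
    delta_prior_shape = rep(NA_real_, M), delta_prior_scale = rep(NA_real_, M)
  )
  for (i in seq_len(M)) {
    g_hat <- naive$gamma_hat[i, ]
    d2_hat <- naive$delta2_hat[i, ]
    n_i <- naive$n_i[i]
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    m <- mean(d2_hat)
    s2 <- stats::var(d2_hat)
    hyper$gamma_prior_mean[i] <- g_bar
    hyper$gamma_prior_var[i] <- t2
    if (s2 == 0) {
      # degenerate across-feature spread: prior is a point mass, posterior
      # shrinkage is undefined; use the raw estimates for this site
      warning(sprintf("site %s: across-feature variance of delta2_hat is zero; using raw estimates",
                      naive$site_levels[i]))
      gamma_star[i, ] <- (t2 * n_i * g_hat + d2_hat * g_bar) / (t2 * n_i + d2_hat)
      delta_star[i, ] <- sqrt(d2_hat)
      next
    }
    a <- m^2 / s2 + 2
    b <- m * (a - 1)
    hyper$delta_prior_shape[i] <- a
    hyper$delta_prior_scale[i] <- b

    g_old <- g_hat
    d_old <- d2_hat
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      g_new <- (t2 * n_i * g_hat + d_old * g_bar) / (t2 * n_i + d_old)
      # sum of squares about the current posterior-mean location
      sum2 <- n_i * d2_hat + n_i * (g_hat - g_new)^2
      d_new <- (0.5 * sum2 + b) / (n_i / 2 + a - 1)
      change <- max(abs(g_new - g_old), abs(d_new - d_old))
      g_old <- g_new
      d_old <- d_new
      if (change < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      stop(sprintf("empirical Bayes did not converge for site %s (last max change %.3g)",
                   naive$site_levels[i], change), call. = FALSE)
    }
    gamma_star[i, ] <- g_old
    delta_star[i, ] <- sqrt(d_old)
  }
  list(hyper = hyper, gamma_star = gamma_star, delta_star = delta_star)
}

#' Fit the ComBat harmonization model
#'
#' Convenience wrapper running [fit_naive()] and, when \code{eb = TRUE},
#' [estimate_eb()]. With \code{eb = FALSE} the site effects are the raw
#' moment estimates (\code{gamma_star = gamma_hat},
#' \code{delta_star = sqrt(delta2_hat)}), giving exact per-site moment
#' matching after [combat_transform()].
#'
#' @inheritParams fit_naive
#' @param eb apply empirical-Bayes shrinkage of site effects (default TRUE).
#' @return an object of class \code{combat_model}.
#' @examples
#' set.seed(1)
#' Y <- matrix(rnorm(60), 20, 3)
#' site <- rep(c("a", "b"), each = 10)
#' fit <- combat_fit(Y, site, eb = FALSE)
#' Yh <- combat_transform(fit, Y, site)
#' @export
combat_fit <- function(Y, site, X = NULL, eb = TRUE, min_site_size = 3L) {
  naive <- fit_naive(Y, site, X, min_site_size)
  if (eb) {
    post <- estimate_eb(naive)
    hyper <- post$hyper
    gamma_star <- post$gamma_star
    delta_star <- post$delta_star
  } else {
    hyper <- NULL
    gamma_star <- naive$gamma_hat
    delta_star <- sqrt(naive$delta2_hat)
  }
  structure(list(
    naive = naive,
    hyper = hyper,
    gamma_star = gamma_star,
    delta_star = delta_star,
    eb_enabled = isTRUE(eb),
    covariate_names = naive$covariate_names
  ), class = "combat_model")
}

#' @noRd
#' Common checks + standardized data for applying a fitted combat model.
.combat_standardize <- function(model, Y, site, X) {
  stopifnot(inherits(model, "combat_model"))
  Y <- .as_feature_matrix(Y)
  nv <- model$naive
  if (!identical(colnames(Y), names(nv$alpha_hat))) {
    stop("feature names do not match the fitted model", call. = FALSE)
  }
  n <- nrow(Y)
  site <- factor(site)
  unknown <- setdiff(levels(site), nv$site_levels)
  if (length(unknown)) {
    stop(sprintf("unknown site label(s): %s; refit the model including them",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  site <- factor(site, levels = nv$site_levels)
  # rank was checked at fit time; frozen coefficients apply to any X,
  # including a single subject
  X <- .as_design(X, n, check_rank = FALSE)
  if (!identical(colnames(X), nv$covariate_names) &&
      !(ncol(X) == 0 && length(nv$covariate_names) == 0)) {
    stop("covariate columns do not match the fitted model", call. = FALSE)
  }
  stand_mean <- matrix(nv$alpha_hat, n, ncol(Y), byrow = TRUE)
  if (ncol(X) > 0) stand_mean <- stand_mean + X %*% nv$beta_hat
  Z <- sweep(Y - stand_mean, 2, nv$sigma_hat, "/")
  list(Z = Z, stand_mean = stand_mean, site = site)
}

#' ComBat-harmonized residuals
#'
#' Removes the estimated site effects and the fitted intercept/covariate
#' surface, returning the residuals
#' \eqn{e^{ComBat}_{ijv} = (y_{ijv} - \hat\alpha_v - x_{ij}^T\hat\beta_v -
#' \hat\sigma_v \gamma^*_{iv}) / \delta^*_{iv}} that feed the covariance
#' harmonization stage.
#'
#' @inheritParams combat_transform
#' @return n x p numeric matrix of residuals (overall column means near zero).
#' @export
combat_residuals <- function(model, Y, site, X = NULL) {
  st <- .combat_standardize(model, Y, site, X)
  idx <- as.integer(st$site)
  Zadj <- (st$Z - model$gamma_star[idx, , drop = FALSE]) / model$delta_star[idx, , drop = FALSE]
  sweep(Zadj, 2, model$naive$sigma_hat, "*")
}

#' Apply ComBat harmonization
#'
#' Returns \eqn{y^{ComBat}} : the site location/scale effects are removed from
#' the standardized data and the fitted intercept and covariate effects are
#' added back, so covariate associations estimated at fit time are preserved
#' unchanged.
#'
#' @param model a fitted \code{combat_model}.
#' @param Y data to harmonize (feature names must match the fit).
#' @param site site labels (levels must be a subset of those seen at fit).
#' @param X covariates matching the fit (same columns).
#' @return harmonized matrix, same shape and dimnames as \code{Y}.
#' @export
combat_transform <- function(model, Y, site, X = NULL) {
  st <- .combat_standardize(model, Y, site, X)
  idx <- as.integer(st$site)
  Zadj <- (st$Z - model$gamma_star[idx, , drop = FALSE]) / model$delta_star[idx, , drop = FALSE]
  out <- sweep(Zadj, 2, model$naive$sigma_hat, "*") + st$stand_mean
  dimnames(out) <- dimnames(Y)
  out
}
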