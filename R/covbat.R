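#' Eigendecompose harmonization residuals
#'
#' Principal components analysis of the pooled residual matrix: eigenpairs of
#' the sample covariance (denominator n - 1), computed through the singular
#' value decomposition of the column-centered residuals so the p x p
#' covariance is never formed when n < p. The stored column means (which are
#' near zero for ComBat residuals) are re-added at reconstruction.
#'
#' Eigenvector signs are fixed by making the largest-magnitude element of
#' each column positive, so decompositions serialize and round-trip
#' reproducibly.
#'
#' @param E n x p residual matrix with column means near zero.
#' @param center_tol warn when a column mean exceeds this fraction of the
#'   column SD (default 1e-6). The harmonization pipeline disables the
#'   warning for its own residuals, whose means are nonzero only at the
#'   order of the empirical-Bayes shrinkage; recentering handles them.
#' @return object of class \code{residual_pca}: \code{components} (p x q,
#'   orthonormal columns), \code{eigenvalues} (length q, non-increasing),
#'   \code{scores} (n x q), \code{center} (length p), \code{rank_q},
#'   \code{explained_fraction} (cumulative).
#' @export
residual_pca <- function(E, center_tol = 1e-6) {
  E <- .as_feature_matrix(E, "E")
  n <- nrow(E)
  p <- ncol(E)
  if (n < 2) stop("need at least 2 rows to estimate a covariance", call. = FALSE)
  sds <- apply(E, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant column(s) in residuals: %s",
                 paste(colnames(E)[sds == 0], collapse = ", ")), call. = FALSE)
  }
  center <- colMeans(E)
  off <- abs(center) / sds
  if (is.finite(center_tol) && any(off > center_tol)) {
    warning(sprintf("%d residual column(s) have mean exceeding %g of their SD; PCA recenters them",
                    sum(off > center_tol), center_tol))
  }
  q <- min(n, p)
  Ec <- sweep(E, 2, center, "-")
  sv <- svd(Ec, nu = q, nv = q)
  eigenvalues <- sv$d[seq_len(q)]^2 / (n - 1)
  components <- sv$v
  # sign convention: largest |entry| of each eigenvector is positive
  for (k in seq_len(q)) {
    j <- which.max(abs(components[, k]))
    if (components[j, k] < 0) components[, k] <- -components[, k]
  }
  scores <- Ec %*% components
  dimnames(components) <- list(colnames(E), paste0("PC", seq_len(q)))
  colnames(scores) <- paste0("PC", seq_len(q))
  structure(list(
    components = components,
    eigenvalues = eigenvalues,
    scores = scores,
    center = stats::setNames(center, colnames(E)),
    rank_q = q,
    explained_fraction = cumsum(eigenvalues) / sum(eigenvalues)
  ), class = "residual_pca")
}

#' Choose the number of principal components to harmonize
#'
#' Either the smallest K whose eigenvalues cumulatively explain at least
#' \code{pct_var} of the total variance, or a fixed count clipped to
#' \code{[0, q]}. Guidance from the method's evaluation: components explaining
#' 90--95\% of variance, the larger fraction for larger within-site samples.
#'
#' @param eigenvalues non-negative eigenvalues, descending.
#' @param pct_var target cumulative variance fraction in (0, 1].
#' @param k_fixed fixed component count (exclusive with \code{pct_var}).
#' @return integer K.
#' @export
select_k <- function(eigenvalues, pct_var = NULL, k_fixed = NULL) {
  if (any(eigenvalues < 0) || all(eigenvalues == 0)) {
    stop("eigenvalues must be non-negative and not all zero", call. = FALSE)
  }
  if (is.null(pct_var) == is.null(k_fixed)) {
    stop("give exactly one of `pct_var` and `k_fixed`", call. = FALSE)
  }
  q <- length(eigenvalues)
  if (!is.null(k_fixed)) {
    return(as.integer(min(max(k_fixed, 0L), q)))
  }
  if (pct_var <= 0 || pct_var > 1) stop("`pct_var` must be in (0, 1]", call. = FALSE)
  frac <- cumsum(eigenvalues) / sum(eigenvalues)
  as.integer(which(frac >= pct_var - 1e-12)[1L])
}

#' @noRd
#' Estimate per-site score adjustment parameters for components 1..K.
.estimate_score_adjustment <- function(dec, site, K, mode, eval_floor = 1e-12) {
  stopifnot(inherits(dec, "residual_pca"))
  n <- nrow(dec$scores)
  site <- .as_site(site, n, min_site_size = 2L)
  K <- as.integer(K)
  if (K < 0 || K > dec$rank_q) stop("K must lie in [0, q]", call. = FALSE)
  mode <- match.arg(mode, c("direct", "eb"))
  M <- nlevels(site)
  skipped <- integer(0)
  if (K > 0) {
    skipped <- which(dec$eigenvalues[seq_len(K)] < eval_floor * dec$eigenvalues[1L])
  }
  active <- setdiff(seq_len(K), skipped)

  adj <- list(K = K, mode = mode, skipped = skipped, site_levels = levels(site))
  if (length(active) == 0) {
    adj$active <- active
    return(structure(adj, class = "score_adjustment"))
  }
  sc <- dec$scores[, active, drop = FALSE]
  if (mode == "eb") {
    if (length(active) < 2) {
      stop("score-level empirical Bayes needs at least 2 adjusted components", call. = FALSE)
    }
    adj$score_model <- combat_fit(sc, site, X = NULL, eb = TRUE, min_site_size = 2L)
  } else {
    pooled_mean <- colMeans(sc)
    pooled_var <- apply(sc, 2, stats::var)
    mu_hat <- matrix(0, M, length(active), dimnames = list(levels(site), colnames(sc)))
    rho_hat <- mu_hat
    for (i in seq_len(M)) {
      si <- sc[site == levels(site)[i], , drop = FALSE]
      mu_hat[i, ] <- colMeans(si)
      v_i <- apply(si, 2, stats::var)
      if (any(v_i == 0)) {
        k0 <- active[which(v_i == 0)[1L]]
        stop(sprintf("site %s has zero score variance on component %d",
                     levels(site)[i], k0), call. = FALSE)
      }
      rho_hat[i, ] <- sqrt(v_i / pooled_var)
    }
    adj$pooled_mean <- pooled_mean
    adj$pooled_var <- pooled_var
    adj$mu_hat <- mu_hat
    adj$rho_hat <- rho_hat
  }
  adj$active <- active
  structure(adj, class = "score_adjustment")
}

#' @noRd
#' Apply frozen score-adjustment parameters to a score matrix.
.apply_score_adjustment <- function(scores, site, adj) {
  if (length(adj$active) == 0) return(scores)
  site <- factor(site, levels = adj$site_levels)
  if (anyNA(site)) stop("unseen site label in score adjustment; refit the model", call. = FALSE)
  sc <- scores[, adj$active, drop = FALSE]
  if (adj$mode == "eb") {
    sc <- combat_transform(adj$score_model, sc, site)
  } else {
    idx <- as.integer(site)
    centered <- sc - adj$mu_hat[idx, , drop = FALSE]
    sc <- sweep(centered / adj$rho_hat[idx, , drop = FALSE], 2, adj$pooled_mean, "+")
  }
  scores[, adj$active] <- sc
  scores
}

#' Harmonize principal-component scores across sites
#'
#' For each of the leading K components, brings every site's score mean and
#' variance to the pooled mean and variance. In \code{mode = "direct"} the
#' per-site center \eqn{\hat\mu_{ik}} and scale ratio \eqn{\hat\rho_{ik}}
#' are the site sample mean and SD-to-pooled-SD ratio, and
#' \eqn{\xi^{CovBat} = (\xi - \hat\mu_{ik})/\hat\rho_{ik}} recentered to the
#' pooled mean; moment matching is exact. In \code{mode = "eb"} the ComBat
#' empirical-Bayes machinery is applied treating the K score columns as
#' features. Components with eigenvalue below \code{eval_floor} times the
#' leading eigenvalue are never adjusted.
#'
#' @param dec a \code{residual_pca} decomposition.
#' @param site site labels (each site needs >= 2 subjects).
#' @param K number of leading components to harmonize.
#' @param mode \code{"direct"} (default) or \code{"eb"}.
#' @param eval_floor relative eigenvalue threshold below which components are
#'   left untouched.
#' @return list with \code{scores} (adjusted n x q matrix) and
#'   \code{adjustment} (frozen parameters, class \code{score_adjustment}).
#' @export
adjust_scores <- function(dec, site, K, mode = c("direct", "eb"), eval_floor = 1e-12) {
  mode <- match.arg(mode)
  adj <- .estimate_score_adjustment(dec, site, K, mode, eval_floor)
  list(scores = .apply_score_adjustment(dec$scores, site, adj), adjustment = adj)
}

#' Project adjusted scores back to the residual space
#'
#' Reconstructs residuals as the sum of adjusted leading components and
#' untouched trailing components,
#' \eqn{e^{CovBat} = \sum_{k \le K} \xi^{CovBat}_k \hat\phi_k +
#' \sum_{l > K} \xi_l \hat\phi_l}, implemented as
#' \code{scores \%*\% t(components)} plus the stored column centers.
#'
#' @param dec a \code{residual_pca} decomposition.
#' @param adjusted_scores n x q matrix of (possibly adjusted) scores.
#' @return n x p residual matrix.
#' @export
reconstruct_residuals <- function(dec, adjusted_scores) {
  stopifnot(inherits(dec, "residual_pca"))
  if (!is.matrix(adjusted_scores) || ncol(adjusted_scores) != dec$rank_q) {
    stop(sprintf("adjusted scores must be a matrix with q = %d columns", dec$rank_q),
         call. = FALSE)
  }
  out <- adjusted_scores %*% t(dec$components)
  sweep(out, 2, dec$center, "+")
}

#' CovBat: harmonize mean, variance, and covariance site effects
#'
#' Full pipeline: (1) fit ComBat and take its covariate-adjusted residuals,
#' (2) PCA of the pooled residuals, (3) harmonize the mean and variance of
#' the leading K principal-component scores across sites, (4) reconstruct
#' residuals and re-add the fitted intercept and covariate effects. K is
#' chosen as the smallest count explaining \code{pct_var} of residual
#' variance (default 0.95) unless \code{n_pc} fixes it.
#'
#' @inheritParams combat_fit
#' @param pct_var cumulative variance fraction selecting K (default 0.95).
#' @param n_pc fixed number of components (overrides \code{pct_var}).
#' @param eb empirical-Bayes shrinkage in the ComBat stage (default TRUE).
#' @param score_eb use empirical Bayes for the score adjustment instead of
#'   direct moment matching (default FALSE).
#' @param eval_floor relative eigenvalue floor below which components are not
#'   adjusted.
#' @return list with \code{harmonized} (matrix like \code{Y}) and
#'   \code{model} (class \code{covbat_model}) for out-of-sample application.
#' @examples
#' set.seed(7)
#' Y <- matrix(rnorm(300), 60, 5)
#' site <- rep(c("a", "b", "c"), each = 20)
#' res <- covbat_harmonize(Y, site, pct_var = 0.95)
#' dim(res$harmonized)
#' res$model$K
#' @export
covbat_harmonize <- function(Y, site, X = NULL, pct_var = 0.95, n_pc = NULL,
                             eb = TRUE, score_eb = FALSE, min_site_size = 3L,
                             eval_floor = 1e-12) {
  Y <- .as_feature_matrix(Y)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  cm <- stage("combat", combat_fit(Y, site, X, eb = eb, min_site_size = min_site_size))
  E <- stage("residuals", combat_residuals(cm, Y, site, X))
  dec <- stage("pca", residual_pca(E, center_tol = Inf))
  K <- stage("select_k",
             if (is.null(n_pc)) select_k(dec$eigenvalues, pct_var = pct_var)
             else select_k(dec$eigenvalues, k_fixed = n_pc))
  adj <- stage("adjust_scores",
               .estimate_score_adjustment(dec, site, K,
                                          mode = if (score_eb) "eb" else "direct",
                                          eval_floor = eval_floor))
  model <- structure(list(
    combat = cm,
    decomposition = list(components = dec$components,
                         eigenvalues = dec$eigenvalues,
                         center = dec$center,
                         rank_q = dec$rank_q),
    adjustment = adj,
    pct_var = if (is.null(n_pc)) pct_var else NULL,
    K = K
  ), class = "covbat_model")
  harmonized <- stage("reconstruct", .covbat_transform(model, Y, site, X))
  list(harmonized = harmonized, model = model)
}

#' @noRd
#' Shared transform path for in-sample and out-of-sample application.
.covbat_transform <- function(model, Y, site, X) {
  cm <- model$combat
  E <- combat_residuals(cm, Y, site, X)
  st <- .combat_standardize(cm, Y, site, X)
  if (length(model$adjustment$active) == 0) {
    # no component adjusted: CovBat degenerates to ComBat exactly (no
    # projection round trip, so the equality is bitwise)
    return(E + st$stand_mean)
  }
  comp <- model$decomposition$components
  Ec <- sweep(E, 2, model$decomposition$center, "-")
  scores <- Ec %*% comp
  scores <- .apply_score_adjustment(scores, site, model$adjustment)
  out <- scores %*% t(comp)
  out <- sweep(out, 2, model$decomposition$center, "+") + st$stand_mean
  dimnames(out) <- dimnames(Y)
  out
}

#' Apply a fitted CovBat model to new subjects
#'
#' Applies all frozen parameters (intercepts, covariate coefficients, pooled
#' scales, site effects, eigenbasis, pooled score moments, per-site score
#' centers/scales) to new data without any re-estimation, so evaluation on
#' held-out subjects cannot leak information from the test set. New subjects
#' must come from sites seen at fit time.
#'
#' @param model a \code{covbat_model} from [covbat_harmonize()].
#' @param Y new data (feature names must match the fit).
#' @param site site labels for the new subjects.
#' @param X covariates matching the fit.
#' @return harmonized matrix, same shape as \code{Y}.
#' @export
covbat_apply <- function(model, Y, site, X = NULL) {
  stopifnot(inherits(model, "covbat_model"))
  Y <- .as_feature_matrix(Y)
  .covbat_transform(model, Y, site, X)
}
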