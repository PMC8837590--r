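#' Frobenius distance between two matrices
#'
#' \eqn{\sqrt{\sum (A - B)^2}}; the standard scalar summary of how far two
#' covariance matrices are apart.
#'
#' @param A,B numeric matrices of equal shape.
#' @return non-negative scalar.
#' @export
frobenius_distance <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("matrices must have the same shape", call. = FALSE)
  sqrt(sum((A - B)^2))
}

#' Residualize features on covariates
#'
#' Per-feature least-squares residuals of \code{Y} on an intercept plus
#' \code{X}, fit jointly across all subjects (all sites together). Used both
#' to remove demographic structure before comparing within-site covariances
#' and to remove the diagnosis signal before site-detection experiments.
#'
#' @param Y subjects x features matrix.
#' @param X covariate matrix (NULL = intercept only, i.e. column centering).
#' @return residual matrix, same shape as \code{Y}.
#' @export
residualize <- function(Y, X = NULL) {
  Y <- .as_feature_matrix(Y)
  X <- .as_design(X, nrow(Y))
  design <- cbind(`(Intercept)` = 1, X)
  qd <- qr(design)
  if (qd$rank < ncol(design)) stop("residualization design is rank deficient", call. = FALSE)
  Y - design %*% qr.coef(qd, Y)
}

#' Within-site covariance matrices of residualized data
#'
#' Residualizes jointly on the covariates, then returns each site's sample
#' covariance (denominator n_i - 1).
#'
#' @param Y subjects x features matrix.
#' @param site site labels.
#' @param X optional covariates removed before computing covariances.
#' @return named list of p x p covariance matrices, one per site.
#' @export
within_site_covariances <- function(Y, site, X = NULL) {
  Y <- .as_feature_matrix(Y)
  site <- .as_site(site, nrow(Y), min_site_size = 2L)
  R <- residualize(Y, X)
  lapply(stats::setNames(levels(site), levels(site)), function(s) {
    stats::cov(R[site == s, , drop = FALSE])
  })
}

#' Rank-based AUC (Mann-Whitney with midrank ties)
#'
#' Area under the ROC curve for scores against binary labels, computed as
#' the normalized Mann-Whitney U statistic with midrank tie handling:
#' ties contribute 1/2.
#'
#' @param scores numeric predictions (higher = more likely positive).
#' @param labels binary labels (logical, 0/1, or two-level factor; the
#'   second factor level / 1 / TRUE is the positive class).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Random-forest classifier specification
#'
#' The default classifier for detection experiments: a probability random
#' forest with conventional defaults (500 trees, sqrt(p) candidate features
#' per split), single-threaded for reproducibility. Any list with \code{fit}
#' and \code{score} functions of the same signatures can replace it.
#'
#' @param num_trees number of trees.
#' @param mtry candidate features per split (default floor(sqrt(p))).
#' @return list with elements \code{fit(x, y, seed)}, \code{score(model, x)},
#'   and \code{description}.
#' @export
rf_classifier <- function(num_trees = 500L, mtry = NULL) {
  list(
    fit = function(x, y, seed = 1L) {
      d <- as.data.frame(x)
      d$.label <- factor(y, levels = c(FALSE, TRUE))
      ranger::ranger(
        dependent.variable.name = ".label", data = d,
        num.trees = num_trees,
        mtry = if (is.null(mtry)) floor(sqrt(ncol(x))) else mtry,
        probability = TRUE, num.threads = 1L, seed = seed
      )
    },
    score = function(model, x) {
      stats::predict(model, data = as.data.frame(x), num.threads = 1L)$predictions[, "TRUE"]
    },
    description = sprintf("probability random forest (%d trees, mtry = %s)",
                          num_trees, if (is.null(mtry)) "sqrt(p)" else mtry)
  )
}

#' Split-sample label-detection experiment
#'
#' Quantifies how detectable a label (site, diagnosis, ...) is from the
#' features: for each repetition the sample is split at random into 50\%
#' training and 50\% validation halves, a classifier is trained on the
#' training half, and the validation half is scored by rank-based AUC.
#' When confounds are given they are residualized out of the features first
#' (fit on the full data by default, mirroring the evaluation protocol this
#' harness reproduces; set \code{train_only_residualization} for the
#' leakage-free variant). Splits that leave a training or validation half
#' without both classes are redrawn.
#'
#' @param Y subjects x features matrix.
#' @param labels binary label per subject.
#' @param confounds optional covariate matrix residualized out of \code{Y}.
#' @param n_reps number of repeated splits (default 100).
#' @param seed integer seed.
#' @param classifier a fit/score pair, see [rf_classifier()].
#' @param train_only_residualization fit the residualizing model on the
#'   training half only (default FALSE).
#' @param max_redraws redraw budget per repetition for degenerate splits.
#' @return object of class \code{detection_result}: \code{auc} (vector),
#'   \code{median}, \code{iqr}, \code{n_reps}, \code{classifier},
#'   \code{seed}.
#' @export
detection_experiment <- function(Y, labels, confounds = NULL, n_reps = 100L,
                                 seed = 1L, classifier = rf_classifier(),
                                 train_only_residualization = FALSE,
                                 max_redraws = 100L) {
  Y <- .as_feature_matrix(Y)
  n <- nrow(Y)
  lab <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(as.logical(labels))
  if (length(unique(lab)) < 2) stop("both label classes must be present", call. = FALSE)
  confounds <- if (is.null(confounds)) NULL else .as_design(confounds, n)
  if (!is.null(confounds) && !train_only_residualization) {
    Y <- residualize(Y, confounds)
  }
  aucs <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(child_seed(seed, r, stream = 1L))
    for (try in seq_len(max_redraws)) {
      idx <- sample.int(n, floor(n / 2))
      ok <- length(unique(lab[idx])) == 2 && length(unique(lab[-idx])) == 2
      if (ok) break
      if (try == max_redraws) stop("could not draw a split containing both classes", call. = FALSE)
    }
    Ytr <- Y[idx, , drop = FALSE]
    Yva <- Y[-idx, , drop = FALSE]
    if (!is.null(confounds) && train_only_residualization) {
      ctr <- confounds[idx, , drop = FALSE]
      fit <- qr(cbind(1, ctr))
      B <- qr.coef(fit, Ytr)
      Ytr <- Ytr - cbind(1, ctr) %*% B
      Yva <- Yva - cbind(1, confounds[-idx, , drop = FALSE]) %*% B
    }
    model <- classifier$fit(Ytr, lab[idx] == 1L, seed = child_seed(seed, r, stream = 2L))
    aucs[r] <- auc(classifier$score(model, Yva), lab[-idx])
  }
  structure(list(
    auc = aucs,
    median = stats::median(aucs),
    iqr = unname(stats::quantile(aucs, c(0.25, 0.75))),
    n_reps = as.integer(n_reps),
    classifier = classifier$description,
    seed = as.integer(seed)
  ), class = "detection_result")
}

#' MANOVA with Pillai's trace
#'
#' One-way multivariate analysis of variance: between-group (H) and
#' within-group (E) scatter matrices, Pillai's trace
#' \eqn{V = tr(H (H + E)^{-1})}, and the standard F approximation. Pillai's
#' trace is the statistic most robust to covariance inhomogeneity across
#' groups, which is exactly what unharmonized multi-site data exhibit.
#' Optionally residualizes on covariates first.
#'
#' @param Y subjects x features matrix.
#' @param group grouping factor (>= 2 levels, each with >= 2 subjects).
#' @param X optional covariates residualized out before testing.
#' @return object of class \code{manova_result}: \code{pillai},
#'   \code{approx_f}, \code{df} (numerator, denominator), \code{p_value},
#'   \code{group_variable}.
#' @export
manova_pillai <- function(Y, group, X = NULL) {
  group_variable <- deparse(substitute(group))[1L]
  Y <- .as_feature_matrix(Y)
  n <- nrow(Y)
  p <- ncol(Y)
  group <- factor(group)
  group <- droplevels(group)
  g <- nlevels(group)
  if (g < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2)) stop("every group needs at least 2 subjects", call. = FALSE)
  if (n - g < p) {
    stop(sprintf("n - groups (%d) < p (%d): too many features for the F approximation",
                 n - g, p), call. = FALSE)
  }
  if (!is.null(X)) Y <- residualize(Y, X)
  grand <- colMeans(Y)
  H <- matrix(0, p, p)
  E <- matrix(0, p, p)
  for (lev in levels(group)) {
    Yg <- Y[group == lev, , drop = FALSE]
    mg <- colMeans(Yg)
    H <- H + nrow(Yg) * tcrossprod(mg - grand)
    E <- E + crossprod(sweep(Yg, 2, mg, "-"))
  }
  HE <- H + E
  sol <- tryCatch(solve(HE, H), error = function(e) {
    stop("H + E is singular; reduce the number of features", call. = FALSE)
  })
  pillai <- sum(diag(sol))
  s <- min(p, g - 1)
  m_par <- (abs(p - g + 1) - 1) / 2
  n_par <- (n - g - p - 1) / 2
  df1 <- s * (2 * m_par + s + 1)
  df2 <- s * (2 * n_par + s + 1)
  approx_f <- ((2 * n_par + s + 1) / (2 * m_par + s + 1)) * (pillai / s) / (1 - pillai / s)
  p_value <- stats::pf(approx_f, df1, df2, lower.tail = FALSE)
  structure(list(
    pillai = pillai,
    approx_f = approx_f,
    df = c(df1, df2),
    p_value = p_value,
    group_variable = group_variable
  ), class = "manova_result")
}
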