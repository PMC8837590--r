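# Independent oracles used by the tests. These deliberately use brute-force
# formulations (explicit normal equations, dense eigensolvers, grid
# integration, exhaustive enumeration) so they share no code path with the
# implementation they check.

# Explicit normal-equations least squares: solve t(D) D b = t(D) y directly.
ls_oracle <- function(D, Y) {
  solve(crossprod(D), crossprod(D, Y))
}

# Conditional posterior means for one site/feature pair by 1-D numerical
# integration on fine grids, iterated to a tighter tolerance than the
# implementation. z is the standardized data for the feature at that site;
# hyperparameters are the method-of-moments values.
eb_grid_oracle <- function(z, g_bar, t2, a, b, tol = 1e-6, max_iter = 500L) {
  n <- length(z)
  ghat <- mean(z)
  g <- ghat
  d <- mean((z - ghat)^2)
  for (it in seq_len(max_iter)) {
    if (t2 > 0) {
      sd_lik <- sqrt(d / n)
      lo <- min(ghat - 8 * sd_lik, g_bar - 8 * sqrt(t2))
      hi <- max(ghat + 8 * sd_lik, g_bar + 8 * sqrt(t2))
      gg <- seq(lo, hi, length.out = 20001)
      logw <- -n * (gg - ghat)^2 / (2 * d) - (gg - g_bar)^2 / (2 * t2)
      w <- exp(logw - max(logw))
      g_new <- sum(gg * w) / sum(w)
    } else {
      g_new <- g_bar
    }
    sum2 <- sum((z - g_new)^2)
    mode_d <- (0.5 * sum2 + b) / (n / 2 + a + 1)
    dd <- exp(seq(log(mode_d) - 6, log(mode_d) + 6, length.out = 20001))
    # integrate over log(d): density w.r.t. d times Jacobian d
    logwd <- -(n / 2 + a + 1) * log(dd) - (0.5 * sum2 + b) / dd + log(dd)
    wd <- exp(logwd - max(logwd))
    d_new <- sum(dd * wd) / sum(wd)
    if (max(abs(g_new - g), abs(d_new - d)) < tol) {
      g <- g_new
      d <- d_new
      break
    }
    g <- g_new
    d <- d_new
  }
  c(gamma = g, delta2 = d)
}

# Exhaustive pairwise Mann-Whitney AUC (ties count 1/2).
auc_enum_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) for (sn in neg) {
    total <- total + (sp > sn) + 0.5 * (sp == sn)
  }
  total / (length(pos) * length(neg))
}

# Pillai's trace by dense eigendecomposition of H (H + E)^{-1}.
pillai_eigen_oracle <- function(Y, group) {
  group <- factor(group)
  grand <- colMeans(Y)
  p <- ncol(Y)
  H <- matrix(0, p, p)
  E <- matrix(0, p, p)
  for (lev in levels(group)) {
    Yg <- Y[group == lev, , drop = FALSE]
    mg <- colMeans(Yg)
    H <- H + nrow(Yg) * tcrossprod(mg - grand)
    E <- E + crossprod(sweep(Yg, 2, mg, "-"))
  }
  sum(Re(eigen(H %*% solve(H + E))$values))
}

# Small 3-site dataset with controllable dimensions, used across tests.
make_toy <- function(n_per = 20, p = 4, M = 3, seed = 42, x = TRUE) {
  set.seed(seed)
  n <- n_per * M
  Y <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  site <- factor(rep(paste0("s", seq_len(M)), each = n_per))
  shift <- seq(-1, 1, length.out = M)
  scale <- seq(0.7, 1.4, length.out = M)
  for (i in seq_len(M)) {
    rows <- site == levels(site)[i]
    Y[rows, ] <- Y[rows, ] * scale[i] + shift[i]
  }
  X <- if (x) matrix(rbinom(n, 1, 0.4), ncol = 1, dimnames = list(NULL, "dx")) else NULL
  if (!is.null(X)) Y <- Y + X %*% matrix(0.5, 1, p)
  list(Y = Y, site = site, X = X)
}

dx_matrix <- function(x) matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, "diagnosis"))

pairwise_mean_dist <- function(covs) {
  M <- length(covs)
  pairs <- utils::combn(M, 2)
  mean(apply(pairs, 2, function(pr) frobenius_distance(covs[[pr[1]]], covs[[pr[2]]])))
}
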