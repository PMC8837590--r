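test_that("residual PCA matches a dense eigensolver and round-trips", {
  # 4 x 3 toy against brute-force eigendecomposition of the explicit covariance
  E <- matrix(c(1, -1, 2, -2,
                0.5, 0.2, -0.4, -0.3,
                1.1, -0.9, 0.3, -0.5), 4, 3)
  E <- sweep(E, 2, colMeans(E), "-")
  colnames(E) <- paste0("f", 1:3)
  dec <- residual_pca(E)
  oracle <- eigen(cov(E), symmetric = TRUE)
  expect_equal(dec$eigenvalues, oracle$values, tolerance = 1e-10)
  for (k in 1:3) {
    expect_equal(abs(sum(dec$components[, k] * oracle$vectors[, k])), 1, tolerance = 1e-8)
  }

  # orthonormality and reconstruction for a random full-rank 20 x 5 matrix
  set.seed(8)
  E2 <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("f", 1:5)))
  dec2 <- residual_pca(E2, center_tol = Inf)
  expect_equal(crossprod(dec2$components), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(reconstruct_residuals(dec2, dec2$scores), E2, tolerance = 1e-8,
               ignore_attr = TRUE)

  # rank-1 residuals: one positive eigenvalue, the rest numerically zero
  u <- rnorm(10); v <- rnorm(4)
  E3 <- outer(u - mean(u), v)
  colnames(E3) <- paste0("f", 1:4)
  dec3 <- residual_pca(E3, center_tol = Inf)
  expect_gt(dec3$eigenvalues[1], 0)
  expect_lt(max(abs(dec3$eigenvalues[-1])), 1e-10)

  # SVD path (n < p) agrees with the covariance eigendecomposition
  set.seed(12)
  E4 <- matrix(rnorm(6 * 9), 6, 9, dimnames = list(NULL, paste0("f", 1:9)))
  dec4 <- residual_pca(E4, center_tol = Inf)
  ev4 <- eigen(cov(E4), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(dec4$eigenvalues, ev4[seq_len(dec4$rank_q)], tolerance = 1e-8)

  expect_error(residual_pca(cbind(E2, k = rep(1, 20))), "constant")
})

test_that("select_k implements the cumulative-variance rule", {
  expect_identical(select_k(c(4, 3, 2, 1), pct_var = 0.70), 2L)
  expect_identical(select_k(c(4, 3, 2, 1), pct_var = 1.0), 4L)
  expect_identical(select_k(c(1, 1, 1, 1), pct_var = 0.95), 4L)
  expect_identical(select_k(c(4, 3, 2, 1), k_fixed = 99), 4L)
  expect_identical(select_k(c(4, 3, 2, 1), k_fixed = 0), 0L)
  expect_error(select_k(c(4, 3), pct_var = 1.2), "pct_var")
  expect_error(select_k(c(4, 3)), "exactly one")
})

test_that("direct score adjustment matches pooled moments exactly", {
  set.seed(14)
  n_per <- 30
  site <- factor(rep(c("a", "b", "c"), each = n_per))
  E <- matrix(rnorm(90 * 4), 90, 4, dimnames = list(NULL, paste0("f", 1:4)))
  dec <- residual_pca(E, center_tol = Inf)
  K <- 3L
  res <- adjust_scores(dec, site, K)

  for (k in seq_len(K)) {
    pm <- mean(dec$scores[, k])
    pv <- var(dec$scores[, k])
    for (s in levels(site)) {
      expect_equal(mean(res$scores[site == s, k]), pm, tolerance = 1e-8)
      expect_equal(var(res$scores[site == s, k]), pv, tolerance = 1e-8)
    }
  }
  # components beyond K untouched
  expect_identical(res$scores[, 4], dec$scores[, 4])
  # K = 0 leaves everything untouched, exactly
  res0 <- adjust_scores(dec, site, 0L)
  expect_identical(res0$scores, dec$scores)
})

test_that("score adjustment recovers hand-computed per-site moments", {
  # one informative component with site means (-1, 0, 1) and SDs (0.5, 1, 2)
  set.seed(15)
  n_per <- 200
  base <- rnorm(3 * n_per)
  site <- factor(rep(c("a", "b", "c"), each = n_per))
  xi <- base * rep(c(0.5, 1, 2), each = n_per) + rep(c(-1, 0, 1), each = n_per)
  E <- cbind(f1 = xi, f2 = rnorm(3 * n_per, sd = 1e-3))
  dec <- residual_pca(E, center_tol = Inf)
  res <- adjust_scores(dec, site, 1L)
  adj <- res$adjustment

  # estimated centers/ratios match direct sample moments of the score column
  for (i in 1:3) {
    s <- levels(site)[i]
    expect_equal(unname(adj$mu_hat[i, 1]), mean(dec$scores[site == s, 1]), tolerance = 1e-10)
    expect_equal(unname(adj$rho_hat[i, 1]),
                 sd(dec$scores[site == s, 1]) / sd(dec$scores[, 1]), tolerance = 1e-10)
  }
  for (s in levels(site)) {
    expect_equal(mean(res$scores[site == s, 1]), mean(dec$scores[, 1]), tolerance = 1e-8)
    expect_equal(var(res$scores[site == s, 1]), var(dec$scores[, 1]), tolerance = 1e-8)
  }
  expect_error(adjust_scores(dec, site, 1L, mode = "eb"), "at least 2")
})

test_that("reconstruction implements the two-sum projection identity", {
  set.seed(16)
  E <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, paste0("f", 1:3)))
  dec <- residual_pca(E, center_tol = Inf)
  sc <- dec$scores
  sc[, 1] <- sc[, 1] * 2 + 0.3  # pretend-adjusted leading component

  # naive double loop over the K adjusted and q - K untouched terms
  oracle <- matrix(0, 4, 3)
  for (j in 1:4) {
    for (k in 1:3) oracle[j, ] <- oracle[j, ] + sc[j, k] * dec$components[, k]
  }
  oracle <- sweep(oracle, 2, dec$center, "+")
  expect_equal(reconstruct_residuals(dec, sc), oracle, tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_equal(reconstruct_residuals(dec, dec$scores), E, tolerance = 1e-8,
               ignore_attr = TRUE)
  zero <- reconstruct_residuals(dec, matrix(0, 4, 3))
  expect_equal(sweep(zero, 2, dec$center, "-"), matrix(0, 4, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(reconstruct_residuals(dec, dec$scores[, 1:2]), "q = 3")
})

test_that("CovBat degenerates to ComBat at K = 0 and to identity on one site", {
  d <- make_toy(n_per = 20, p = 5)
  res0 <- covbat_harmonize(d$Y, d$site, d$X, n_pc = 0)
  cm <- combat_fit(d$Y, d$site, d$X)
  expect_identical(res0$harmonized, combat_transform(cm, d$Y, d$site, d$X))

  set.seed(17)
  Y1 <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
  res1 <- covbat_harmonize(Y1, rep("one", 40), pct_var = 0.95, eb = FALSE)
  expect_equal(res1$harmonized, Y1, tolerance = 1e-8)
})

test_that("score harmonization preserves pooled residual column means", {
  cfg <- sim_config("simple", n_i = 50, p = 10, seed = 23)
  ds <- simulate_dataset(cfg)
  X <- dx_matrix(ds$x)
  cm <- combat_fit(ds$Y, ds$site, X)
  E <- combat_residuals(cm, ds$Y, ds$site, X)
  dec <- residual_pca(E, center_tol = Inf)
  res <- adjust_scores(dec, ds$site, select_k(dec$eigenvalues, pct_var = 0.95))
  Ecov <- reconstruct_residuals(dec, res$scores)
  expect_lt(max(abs(colMeans(Ecov) - colMeans(E))), 1e-8)
})

test_that("fitted CovBat models apply to held-out subjects without re-estimation", {
  cfg <- sim_config("simple", n_i = 80, p = 12, seed = 29)
  ds <- simulate_dataset(cfg)
  X <- dx_matrix(ds$x)
  res <- covbat_harmonize(ds$Y, ds$site, X)

  # training data reproduces the harmonized output
  expect_equal(covbat_apply(res$model, ds$Y, ds$site, X), res$harmonized,
               tolerance = 1e-10)

  # a single held-out subject yields a 1 x p matrix
  one <- covbat_apply(res$model, ds$Y[1, , drop = FALSE],
                      ds$site[1], X[1, , drop = FALSE])
  expect_identical(dim(one), c(1L, ncol(ds$Y)))

  # unseen site refused with advice to refit
  expect_error(covbat_apply(res$model, ds$Y[1:5, ], rep("elsewhere", 5), X[1:5, , drop = FALSE]),
               "refit")
})

test_that("held-out score means approach pooled means as n grows", {
  bias_one <- function(n_i, seed) {
    cfg <- sim_config("simple", n_i = n_i, p = 10, seed = seed)
    ds <- simulate_dataset(cfg)
    X <- dx_matrix(ds$x)
    n <- nrow(ds$Y)
    set.seed(101)
    idx <- sample.int(n, n / 2)
    fit <- covbat_harmonize(ds$Y[idx, ], ds$site[idx], X[idx, , drop = FALSE])
    held <- covbat_apply(fit$model, ds$Y[-idx, ], ds$site[-idx], X[-idx, , drop = FALSE])
    # project held-out harmonized residuals onto the frozen basis and compare
    # per-site means of the first adjusted score to the frozen pooled mean
    E <- combat_residuals(fit$model$combat, held, ds$site[-idx], X[-idx, , drop = FALSE])
    sc <- sweep(E, 2, fit$model$decomposition$center, "-") %*%
      fit$model$decomposition$components
    k1 <- fit$model$adjustment$active[1]
    pooled <- unname(fit$model$adjustment$pooled_mean[1])
    mean(abs(vapply(levels(ds$site), function(s) {
      mean(sc[ds$site[-idx] == s, k1]) - pooled
    }, numeric(1))))
  }
  bias_at <- function(n_i) {
    mean(vapply(1:8, function(r) bias_one(n_i, child_seed(37, r)), numeric(1)))
  }
  expect_lt(bias_at(500), bias_at(50))
})

test_that("CovBat improves covariance recovery over ComBat in the eigen-shift design", {
  # scaled-down version of the recovery experiment: 3 sites, rank-1 shifts
  wins <- 0L
  n_reps <- 20L
  for (r in seq_len(n_reps)) {
    cfg <- sim_config("simple", n_i = 100, p = 20, seed = child_seed(57, r))
    ds <- simulate_dataset(cfg)
    X <- dx_matrix(ds$x)
    cb <- combat_transform(combat_fit(ds$Y, ds$site, X), ds$Y, ds$site, X)
    cv <- covbat_harmonize(ds$Y, ds$site, X)$harmonized
    d_cb <- mean(vapply(within_site_covariances(cb, ds$site, X),
                        frobenius_distance, numeric(1), B = ds$truth$S))
    d_cv <- mean(vapply(within_site_covariances(cv, ds$site, X),
                        frobenius_distance, numeric(1), B = ds$truth$S))
    if (d_cv < d_cb) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.95 * n_reps))
})

test_that("covbat model JSON serialization round-trips the transform", {
  d <- make_toy(n_per = 25, p = 6)
  res <- covbat_harmonize(d$Y, d$site, d$X, pct_var = 0.9)
  path <- tempfile(fileext = ".json")
  write_model(res$model, path)
  m2 <- read_model(path)
  expect_equal(covbat_apply(m2, d$Y, d$site, d$X), res$harmonized, tolerance = 1e-12)

  # eb score mode serializes too
  res_eb <- covbat_harmonize(d$Y, d$site, d$X, pct_var = 0.9, score_eb = TRUE)
  path2 <- tempfile(fileext = ".json")
  write_model(res_eb$model, path2)
  m3 <- read_model(path2)
  expect_equal(covbat_apply(m3, d$Y, d$site, d$X), res_eb$harmonized, tolerance = 1e-12)
})
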