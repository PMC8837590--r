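test_that("least-squares stage matches explicit normal equations on a 2-site toy", {
  # site A values {1, 3}, site B values {5, 7}, one feature, no covariates
  Y <- matrix(c(1, 3, 5, 7), ncol = 1, dimnames = list(NULL, "f"))
  site <- factor(c("A", "A", "B", "B"))
  fit <- fit_naive(Y, site, min_site_size = 2L)

  # oracle: explicit normal-equations solve on the site-indicator design
  D <- cbind(A = c(1, 1, 0, 0), B = c(0, 0, 1, 1))
  site_means <- ls_oracle(D, Y)
  alpha <- sum(c(0.5, 0.5) * site_means)      # n_i/n-weighted grand mean
  expect_equal(unname(fit$alpha_hat), alpha)  # = 4
  expect_equal(unname(fit$alpha_hat), 4)

  resid <- Y - D %*% site_means
  sigma <- sqrt(mean(resid^2))                 # pooled within-site SD, denominator n
  expect_equal(unname(fit$sigma_hat), sigma)

  z <- (Y - alpha) / sigma
  g_oracle <- c(mean(z[site == "A"]), mean(z[site == "B"]))
  expect_equal(unname(fit$gamma_hat[, 1]), g_oracle)
  # weighted-zero identification constraint
  expect_equal(sum(fit$n_i / 4 * fit$gamma_hat[, 1]), 0, tolerance = 1e-8)
})

test_that("covariate coefficients are recovered by least squares", {
  set.seed(11)
  n <- 200
  x <- rnorm(n)
  Y <- matrix(2 + 0.5 * x + rnorm(n, sd = 0.01), ncol = 1, dimnames = list(NULL, "f"))
  fit <- fit_naive(Y, rep("one", n), X = cbind(age = x))
  se <- 0.01 / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(fit$beta_hat["age", "f"] - 0.5), 3 * se)

  # single site: gamma_hat is exactly zero and delta2_hat exactly one by
  # construction of the standardization
  expect_equal(unname(fit$gamma_hat[1, ]), 0, tolerance = 1e-12)
  expect_equal(unname(fit$delta2_hat[1, ]), 1, tolerance = 1e-12)
})

test_that("fit errors name the offending site, feature, or column", {
  d <- make_toy()
  expect_error(fit_naive(d$Y[1:22, ], d$site[1:22]), "fewer than")
  Ybad <- d$Y
  Ybad[, 2] <- 7
  expect_error(fit_naive(Ybad, d$site), "f2")
  Xbad <- cbind(a = d$X[, 1], b = 2 * d$X[, 1])
  expect_error(fit_naive(d$Y, d$site, Xbad), "rank deficient")
})

test_that("empirical Bayes degenerates correctly and shrinks toward the prior", {
  d <- make_toy(n_per = 30, p = 6)
  naive <- fit_naive(d$Y, d$site, d$X)

  # constant gamma_hat across features forces full shrinkage to that value
  nv <- naive
  nv$gamma_hat[1, ] <- 0.3
  nv$delta2_hat[1, ] <- 1.21
  res <- NULL
  expect_warning(res <- estimate_eb(nv), "zero")
  expect_equal(unname(res$gamma_star[1, ]), rep(0.3, 6))
  expect_equal(unname(res$delta_star[1, ]), rep(1.1, 6))

  # shrinkage direction: posterior means lie between data and prior mean
  post <- estimate_eb(naive)
  for (i in seq_len(nrow(naive$gamma_hat))) {
    gbar <- post$hyper$gamma_prior_mean[i]
    expect_true(all(abs(post$gamma_star[i, ] - gbar) <=
                      abs(naive$gamma_hat[i, ] - gbar) + 1e-12))
  }
})

test_that("EB posterior means match the grid-integration oracle", {
  d <- make_toy(n_per = 25, p = 5, M = 2, seed = 9)
  naive <- fit_naive(d$Y, d$site, d$X)
  post <- estimate_eb(naive, tol = 1e-7)
  Z <- naive$standardized
  for (i in 1:2) {
    g_hat <- naive$gamma_hat[i, ]
    d2_hat <- naive$delta2_hat[i, ]
    g_bar <- mean(g_hat)
    t2 <- var(g_hat)
    m <- mean(d2_hat)
    s2 <- var(d2_hat)
    a <- m^2 / s2 + 2
    b <- m * (a - 1)
    rows <- d$site == levels(d$site)[i]
    for (v in seq_len(5)) {
      oracle <- eb_grid_oracle(Z[rows, v], g_bar, t2, a, b)
      expect_equal(unname(post$gamma_star[i, v]), unname(oracle["gamma"]), tolerance = 1e-3)
      expect_equal(unname(post$delta_star[i, v]), sqrt(unname(oracle["delta2"])), tolerance = 1e-3)
    }
  }
})

test_that("transform is the identity for single-site data and for null adjustments", {
  set.seed(3)
  Y <- matrix(rnorm(150), 30, 5, dimnames = list(NULL, paste0("f", 1:5)))
  site <- rep("only", 30)
  fit <- combat_fit(Y, site, eb = FALSE)
  expect_equal(combat_transform(fit, Y, site), Y, tolerance = 1e-10)

  d <- make_toy()
  fit2 <- combat_fit(d$Y, d$site, d$X, eb = FALSE)
  fit2$gamma_star[] <- 0
  fit2$delta_star[] <- 1
  expect_equal(combat_transform(fit2, d$Y, d$site, d$X), d$Y,
               tolerance = 1e-14)  # identity adjustment leaves values untouched
})

test_that("non-EB transform matches a hand-computed location-scale oracle", {
  # 2 sites x 2 features: standardize per feature, remove per-site mean/scale
  set.seed(21)
  Y <- matrix(rnorm(40, sd = 2), 20, 2, dimnames = list(NULL, c("a", "b")))
  site <- factor(rep(c("s1", "s2"), each = 10))
  Y[site == "s2", ] <- Y[site == "s2", ] * 1.5 + 1
  fit <- combat_fit(Y, site, eb = FALSE)
  out <- combat_transform(fit, Y, site)

  for (v in 1:2) {
    y <- Y[, v]
    m1 <- mean(y[site == "s1"]); m2 <- mean(y[site == "s2"])
    alpha <- (m1 + m2) / 2
    resid <- y - ifelse(site == "s1", m1, m2)
    sigma <- sqrt(mean(resid^2))
    z <- (y - alpha) / sigma
    g <- ifelse(site == "s1", mean(z[site == "s1"]), mean(z[site == "s2"]))
    dl <- ifelse(site == "s1",
                 sqrt(mean((z[site == "s1"] - mean(z[site == "s1"]))^2)),
                 sqrt(mean((z[site == "s2"] - mean(z[site == "s2"]))^2)))
    expect_equal(out[, v], sigma * (z - g) / dl + alpha, tolerance = 1e-10)
  }
})

test_that("non-EB harmonization matches per-site moments exactly and is idempotent", {
  d <- make_toy(n_per = 15, p = 3)
  fit <- combat_fit(d$Y, d$site, d$X, eb = FALSE)
  out <- combat_transform(fit, d$Y, d$site, d$X)

  # moment matching: per-site means of covariate-adjusted values equal across
  # sites; per-site variances equal the pooled sigma^2
  adj <- out - cbind(1, d$X) %*% rbind(fit$naive$alpha_hat, fit$naive$beta_hat)
  for (v in seq_len(ncol(out))) {
    ms <- tapply(adj[, v], d$site, mean)
    vs <- tapply(adj[, v], d$site, function(z) mean((z - mean(z))^2))
    expect_equal(max(ms) - min(ms), 0, tolerance = 1e-8)
    expect_equal(as.numeric(vs), rep(unname(fit$naive$sigma_hat[v])^2, 3), tolerance = 1e-8)
  }

  # idempotence: a second fit+transform on already-harmonized data (no
  # covariates, so the refit sees exactly matched site moments) is a no-op
  set.seed(31)
  Yb <- matrix(rnorm(180), 60, 3, dimnames = list(NULL, paste0("f", 1:3)))
  siteb <- factor(rep(c("a", "b", "c"), each = 20))
  Yb <- Yb * rep(c(0.5, 1, 2), each = 20) + rep(c(-1, 0, 1), each = 20)
  o1 <- combat_transform(combat_fit(Yb, siteb, eb = FALSE), Yb, siteb)
  o2 <- combat_transform(combat_fit(o1, siteb, eb = FALSE), o1, siteb)
  expect_equal(o2, o1, tolerance = 1e-8)

  # covariate preservation: with pure location site effects (delta forced to
  # one) the harmonized residuals stay orthogonal to the covariates, so a
  # refit recovers beta_hat exactly; per-site variance rescaling would
  # perturb it only at sampling order
  fit_loc <- combat_fit(d$Y, d$site, d$X, eb = FALSE)
  fit_loc$delta_star[] <- 1
  out_loc <- combat_transform(fit_loc, d$Y, d$site, d$X)
  refit <- fit_naive(out_loc, d$site, d$X)
  expect_equal(refit$beta_hat, fit_loc$naive$beta_hat, tolerance = 1e-6)
})

test_that("residuals satisfy the algebraic identities of the transform", {
  d <- make_toy()
  fit <- combat_fit(d$Y, d$site, d$X, eb = FALSE)
  tr <- combat_transform(fit, d$Y, d$site, d$X)
  re <- combat_residuals(fit, d$Y, d$site, d$X)
  stand_mean <- cbind(1, d$X) %*% rbind(fit$naive$alpha_hat, fit$naive$beta_hat)
  expect_equal(unname(tr - re), unname(stand_mean), tolerance = 1e-12)

  # X empty, single site: residuals are the column-centered data
  set.seed(5)
  Y <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
  f1 <- combat_fit(Y, rep("a", 20), eb = FALSE)
  r1 <- combat_residuals(f1, Y, rep("a", 20))
  expect_equal(unname(r1), unname(sweep(Y, 2, colMeans(Y), "-")), tolerance = 1e-10)

  # per-site means of residuals vanish in non-EB mode on simulated data
  cfg <- sim_config("combat", n_i = 40, p = 8, seed = 6)
  ds <- simulate_dataset(cfg)
  fm <- combat_fit(ds$Y, ds$site, dx_matrix(ds$x), eb = FALSE)
  rr <- combat_residuals(fm, ds$Y, ds$site, dx_matrix(ds$x))
  for (s in levels(ds$site)) {
    expect_lt(max(abs(colMeans(rr[ds$site == s, ]))), 1e-10)
  }
})

test_that("transform rejects unknown sites and mismatched features", {
  d <- make_toy()
  fit <- combat_fit(d$Y, d$site, d$X)
  expect_error(combat_transform(fit, d$Y, rep("new_site", nrow(d$Y)), d$X), "unknown site")
  Y2 <- d$Y
  colnames(Y2) <- paste0("g", seq_len(ncol(Y2)))
  expect_error(combat_transform(fit, Y2, d$site, d$X), "feature names")
})
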