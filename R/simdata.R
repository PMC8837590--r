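#' Surrogate bilateral correlation structure
#'
#' Builds a p x p correlation matrix emulating the block structure of
#' bilateral regional cortical-thickness data: within each hemisphere an
#' exponential-decay (AR-like) correlation \code{decay^|u - v|}, and a
#' cross-hemisphere block equal to \code{homotopic} times the
#' within-hemisphere block, so each region's mirror (homotopic) partner is
#' its most correlated contralateral region. The construction is positive
#' definite by design (eigenvalues are \code{(1 +/- homotopic)} times those
#' of the within-hemisphere block) with unit diagonal. Baseline means are
#' drawn uniformly in a plausible cortical-thickness range.
#'
#' A user-supplied correlation matrix and mean vector override the generated
#' surrogate after validation.
#'
#' @param p even number of features (>= 4).
#' @param seed integer seed controlling the baseline mean draw.
#' @param decay within-hemisphere correlation decay per index step, in [0, 1).
#' @param homotopic mirror-pair correlation boost, in [0, 1).
#' @param alpha_range range for baseline means.
#' @param S optional user correlation matrix (symmetric, unit diagonal, PD).
#' @param alpha optional user mean vector.
#' @return object of class \code{base_structure}: \code{alpha}, \code{S},
#'   \code{hemisphere} (factor left/right), \code{p}.
#' @export
surrogate_structure <- function(p, seed = 1L, decay = 0.5, homotopic = 0.4,
                                alpha_range = c(2.2, 3.6), S = NULL, alpha = NULL) {
  if (p %% 2 != 0 || p < 4) stop("`p` must be even and at least 4", call. = FALSE)
  h <- p / 2
  feat <- c(sprintf("roi_l_%02d", seq_len(h)), sprintf("roi_r_%02d", seq_len(h)))
  if (is.null(S)) {
    if (decay < 0 || decay >= 1 || homotopic < 0 || homotopic >= 1) {
      stop("`decay` and `homotopic` must lie in [0, 1)", call. = FALSE)
    }
    W <- decay^abs(outer(seq_len(h), seq_len(h), "-"))
    S <- rbind(cbind(W, homotopic * W), cbind(homotopic * W, W))
  } else {
    if (!is.matrix(S) || nrow(S) != p || ncol(S) != p) {
      stop(sprintf("supplied S must be a %d x %d matrix", p, p), call. = FALSE)
    }
    if (max(abs(S - t(S))) > 1e-10) stop("supplied S is not symmetric", call. = FALSE)
    if (max(abs(diag(S) - 1)) > 1e-10) stop("supplied S must have unit diagonal", call. = FALSE)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("S is not positive definite", call. = FALSE)
  if (is.null(alpha)) {
    set.seed(seed)
    alpha <- stats::runif(p, alpha_range[1L], alpha_range[2L])
  } else if (length(alpha) != p) {
    stop(sprintf("supplied alpha must have length %d", p), call. = FALSE)
  }
  dimnames(S) <- list(feat, feat)
  structure(list(
    alpha = stats::setNames(as.numeric(alpha), feat),
    S = S,
    hemisphere = factor(rep(c("left", "right"), each = h)),
    p = as.integer(p)
  ), class = "base_structure")
}

#' Draw per-dataset mean and variance site effects
#'
#' Mean site effects \eqn{\gamma_{iv}} are i.i.d. normal with mean zero and
#' standard deviation \code{gamma_sd}; variance site effects
#' \eqn{\delta_{iv}} are i.i.d. from site-specific inverse-gamma
#' distributions (shape/scale parameterization, mean scale/(shape - 1)).
#' Defaults for three sites are IG(46, 50), IG(51, 50), IG(56, 50), giving
#' mean scale factors near 1.11, 1.00, and 0.91.
#'
#' @param M number of sites.
#' @param p number of features.
#' @param variance_params list of M (shape, scale) pairs; defaults provided
#'   only for M = 3.
#' @param gamma_sd standard deviation of the mean site effects (default 0.1).
#' @param seed integer seed.
#' @return object of class \code{site_effect_draw}: \code{gamma} (M x p),
#'   \code{delta} (M x p, positive), \code{variance_params}.
#' @export
draw_site_effects <- function(M, p, variance_params = NULL, gamma_sd = 0.1, seed = 1L) {
  if (is.null(variance_params)) {
    if (M != 3) stop("default variance parameters exist only for M = 3; supply `variance_params`",
                     call. = FALSE)
    variance_params <- list(c(46, 50), c(51, 50), c(56, 50))
  }
  if (length(variance_params) != M) stop("`variance_params` must have one (shape, scale) pair per site",
                                         call. = FALSE)
  for (vp in variance_params) {
    if (length(vp) != 2 || any(vp <= 0)) {
      stop("inverse-gamma shape and scale must be positive", call. = FALSE)
    }
  }
  set.seed(seed)
  gamma <- matrix(if (gamma_sd == 0) 0 else stats::rnorm(M * p, 0, gamma_sd), M, p)
  delta <- matrix(0, M, p)
  for (i in seq_len(M)) {
    a <- variance_params[[i]][1L]
    b <- variance_params[[i]][2L]
    delta[i, ] <- 1 / stats::rgamma(p, shape = a, rate = b)
  }
  structure(list(gamma = gamma, delta = delta, variance_params = variance_params),
            class = "site_effect_draw")
}

#' Rescale a covariance matrix to unit diagonal
#'
#' Returns \eqn{D \Sigma D} with \eqn{D = diag(1/\sqrt{\Sigma_{kk}})}, so
#' covariance shifts do not modify marginal variances. The output diagonal is
#' exactly 1.
#'
#' @param Sigma symmetric matrix with positive diagonal.
#' @return rescaled symmetric matrix.
#' @export
scale_to_unit_diag <- function(Sigma) {
  d <- diag(Sigma)
  if (any(d <= 0)) stop("diagonal entries must be positive", call. = FALSE)
  s <- 1 / sqrt(d)
  out <- Sigma * tcrossprod(s)
  diag(out) <- 1
  out
}

#' Clip negative eigenvalues to a positive floor
#'
#' Eigendecomposes a symmetric matrix, replaces eigenvalues below
#' \code{floor} with \code{floor}, and reconstructs, yielding a valid
#' (positive semidefinite up to the floor) covariance matrix. Inputs already
#' satisfying the floor are returned unchanged.
#'
#' @param Sigma symmetric matrix (asymmetry beyond 1e-10 is an error).
#' @param floor eigenvalue floor (default 1e-12).
#' @return symmetric matrix with minimum eigenvalue >= \code{floor} (within
#'   numerical tolerance).
#' @export
psd_repair <- function(Sigma, floor = 1e-12) {
  if (!is.matrix(Sigma) || nrow(Sigma) != ncol(Sigma)) {
    stop("`Sigma` must be square", call. = FALSE)
  }
  if (max(abs(Sigma - t(Sigma))) > 1e-10) stop("`Sigma` is not symmetric", call. = FALSE)
  e <- eigen(Sigma, symmetric = TRUE)
  if (min(e$values) >= floor) return(Sigma)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

#' Construct distinct site covariance-shift matrices
#'
#' Builds M symmetric unit-diagonal matrices standing in for complex,
#' high-rank, image-like site effects on covariance. Each is a spatially
#' smoothed random symmetric field (squared-exponential kernel applied on
#' both sides of i.i.d. Gaussian noise, then symmetrized), rescaled to unit
#' entry spread, shifted on the diagonal to make the rescaling valid, and
#' row/column-rescaled to unit diagonal. The fields are deliberately
#' indefinite with off-diagonal amplitude comparable to the diagonal, so
#' the shifted covariances genuinely exercise the eigenvalue-floor repair
#' and carry high effective rank, unlike low-rank eigen-shift effects. A
#' deterministic retry loop guarantees that leading eigenvectors are
#' mutually distinct (pairwise absolute cosine < 0.9) and, when
#' \code{avoid} is supplied, distinct from the leading eigenvector of that
#' matrix too.
#'
#' @param M number of matrices.
#' @param p dimension.
#' @param seed integer seed; construction is deterministic given it.
#' @param bandwidth smoothing kernel bandwidth in feature-index units
#'   (default 2.5: enough spatial structure to be image-like while keeping
#'   effective rank a sizable fraction of p).
#' @param diag_floor smallest diagonal entry of the shifted field before
#'   unit-diagonal rescaling; bounds how much the rescaling can amplify
#'   off-diagonal entries.
#' @param avoid optional symmetric matrix (e.g. the base correlation) whose
#'   leading eigenvector the shifts must also avoid.
#' @return list of M symmetric p x p matrices with unit diagonal.
#' @export
make_site_shift_matrices <- function(M, p, seed = 1L, bandwidth = 2.5,
                                     diag_floor = 0.4, avoid = NULL) {
  if (M < 1) stop("`M` must be at least 1", call. = FALSE)
  idx <- seq_len(p)
  Kern <- exp(-outer(idx, idx, "-")^2 / (2 * bandwidth^2))
  lead <- function(A) {
    e <- eigen(A, symmetric = TRUE)
    e$vectors[, 1L]
  }
  avoid_vecs <- if (is.null(avoid)) list() else list(lead(avoid))
  build <- function(s) {
    set.seed(s)
    F <- Kern %*% matrix(stats::rnorm(p * p), p, p) %*% Kern
    A <- (F + t(F)) / 2
    A <- A / stats::sd(A)
    A <- A + diag(diag_floor - min(diag(A)), p)
    scale_to_unit_diag(A)
  }
  out <- vector("list", M)
  vecs <- avoid_vecs
  offset <- 0L
  for (i in seq_len(M)) {
    repeat {
      cand <- build(child_seed(seed, i, offset))
      v <- lead(cand)
      ok <- all(vapply(vecs, function(u) abs(sum(u * v)) < 0.9, logical(1)))
      if (ok) {
        out[[i]] <- cand
        vecs <- c(vecs, list(v))
        break
      }
      offset <- offset + 1L
      if (offset > 1000L) stop("could not construct distinct shift matrices", call. = FALSE)
    }
  }
  out
}

#' Simulation configuration
#'
#' Assembles the complete parameterization of one synthetic multi-site
#' design. Designs:
#' \describe{
#'   \item{simple}{rank-\code{rank_K} eigenvalue shifts of the base
#'     correlation, severities \code{c} per site (defaults -1/2, 0, 1/2 so
#'     the pooled covariance equals the base).}
#'   \item{combat}{mean/variance site effects only; no covariance effects.}
#'   \item{dx_mean}{adds distinct high-rank site covariance shifts; the
#'     diagnosis affects only the mean.}
#'   \item{dx_cov}{additionally couples the diagnosis to covariance via
#'     \code{Psi = -3/4} times site 3's shift matrix.}
#'   \item{cov_only}{site and diagnosis affect covariance only: mean and
#'     variance site effects and the mean diagnosis effect are all zeroed.}
#' }
#'
#' @param design one of "simple", "combat", "dx_mean", "dx_cov", "cov_only".
#' @param M number of sites (default 3).
#' @param n_i subjects per site (scalar or length-M).
#' @param p number of features (even).
#' @param bernoulli_p diagnosis prevalence (default 0.25).
#' @param beta_magnitude diagnosis effect on affected features (default -0.5).
#' @param gamma_sd SD of mean site effects (default 0.1).
#' @param variance_params per-site inverse-gamma (shape, scale) pairs;
#'   default IG(46,50), IG(51,50), IG(56,50) for M = 3.
#' @param severity per-site covariance-shift severity vector for the simple
#'   design (default (-1/2, 0, 1/2), so severities cancel in the pooled
#'   covariance).
#' @param rank_K rank of the simple covariance shift (default 1).
#' @param p_base dimension at which the base structure and shift matrices are
#'   built before taking hemispheric sub-blocks (default max(62, p)).
#' @param psd_floor eigenvalue floor for repair in the complex designs.
#' @param structure_seed seed fixing the base structure and shift matrices
#'   across replicates.
#' @param seed replicate seed for all data draws.
#' @param ... extra options passed to [surrogate_structure()] (decay,
#'   homotopic, alpha_range, S, alpha).
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(design = c("simple", "combat", "dx_mean", "dx_cov", "cov_only"),
                       M = 3L, n_i = 250L, p = 62L, bernoulli_p = 0.25,
                       beta_magnitude = -0.5, gamma_sd = 0.1,
                       variance_params = NULL, severity = c(-1/2, 0, 1/2), rank_K = 1L,
                       p_base = NULL, psd_floor = 1e-12,
                       structure_seed = 319L, seed = 1L, ...) {
  design <- match.arg(design)
  if (length(n_i) == 1L) n_i <- rep(as.integer(n_i), M)
  if (length(n_i) != M) stop("`n_i` must be scalar or length M", call. = FALSE)
  if (design == "simple" && length(severity) != M) stop("`severity` must have length M", call. = FALSE)
  structure(list(
    design = design, M = as.integer(M), n_i = n_i, p = as.integer(p),
    bernoulli_p = bernoulli_p, beta_magnitude = beta_magnitude,
    gamma_sd = gamma_sd, variance_params = variance_params,
    severity = severity, rank_K = as.integer(rank_K),
    p_base = if (is.null(p_base)) max(62L, as.integer(p)) else as.integer(p_base),
    psd_floor = psd_floor,
    structure_seed = as.integer(structure_seed), seed = as.integer(seed),
    structure_opts = list(...)
  ), class = "sim_config")
}

#' @noRd
#' Diagnosis effect vector: beta_magnitude on the first floor(p/4) features
#' of each hemisphere (about half of all features affected).
.beta_vector <- function(p, beta_magnitude) {
  h <- p / 2
  k <- floor(p / 4)
  beta <- numeric(p)
  if (k > 0) beta[c(seq_len(k), h + seq_len(k))] <- beta_magnitude
  beta
}

#' @noRd
#' Draw n rows from N(0, Sigma) using the (deterministic) Cholesky factor.
.rmvn <- function(n, Sigma) {
  R <- chol(Sigma)
  matrix(stats::rnorm(n * nrow(Sigma)), n, nrow(Sigma)) %*% R
}

#' @noRd
#' Indices of the first p/2 features of each hemisphere within a p_base
#' structure (used to take sub-blocks when p < p_base).
.subblock_index <- function(p, p_base) {
  h <- p / 2
  c(seq_len(h), p_base / 2 + seq_len(h))
}

#' @noRd
#' Draw gamma/delta from the CURRENT RNG stream (replicate seed already set),
#' in a fixed documented order: gamma first, then delta site by site.
.draw_effects_stream <- function(cfg) {
  gamma <- matrix(if (cfg$gamma_sd == 0) 0 else stats::rnorm(cfg$M * cfg$p, 0, cfg$gamma_sd),
                  cfg$M, cfg$p)
  vp <- cfg$variance_params
  if (is.null(vp)) vp <- list(c(46, 50), c(51, 50), c(56, 50))
  if (length(vp) != cfg$M) stop("`variance_params` must have one pair per site", call. = FALSE)
  delta <- matrix(0, cfg$M, cfg$p)
  for (i in seq_len(cfg$M)) {
    delta[i, ] <- 1 / stats::rgamma(cfg$p, shape = vp[[i]][1L], rate = vp[[i]][2L])
  }
  list(gamma = gamma, delta = delta)
}

#' @noRd
#' Assemble y = alpha + x beta + gamma_i + delta_i * e and package a dataset.
.assemble_dataset <- function(cfg, alpha, beta, x, site, eff, E, truth) {
  n <- length(x)
  p <- cfg$p
  Y <- matrix(alpha, n, p, byrow = TRUE) + outer(x, beta) +
    eff$gamma[as.integer(site), , drop = FALSE] +
    eff$delta[as.integer(site), , drop = FALSE] * E
  feat <- names(alpha)
  dimnames(Y) <- list(sprintf("s%04d", seq_len(n)), feat)
  truth$beta <- stats::setNames(beta, feat)
  truth$gamma <- eff$gamma
  truth$delta <- eff$delta
  truth$config <- cfg
  structure(list(Y = Y, site = site, x = x, truth = truth), class = "sim_dataset")
}

#' Simulate the rank-K eigenvalue-shift (simple covariance effects) design
#'
#' Error vectors for site i are drawn from
#' \eqn{N(0, S + c_i \sum_{k \le K} \hat\lambda_k \hat\phi_k \hat\phi_k^T)}
#' where the eigenpairs come from the base correlation S, so site covariance
#' effects live exactly in the leading principal-component directions. With
#' the default severities (-1/2, 0, 1/2) and equal site sizes the average of
#' the true site covariances equals S. Observations are assembled as
#' \eqn{y = \alpha + x\beta + \gamma_i + \delta_i \odot e} with mean and
#' variance site effects from [draw_site_effects()].
#'
#' @param cfg a \code{sim_config} with \code{design = "simple"}.
#' @return object of class \code{sim_dataset}: \code{Y}, \code{site} (factor),
#'   \code{x} (0/1 diagnosis), and \code{truth} (base structure, per-site
#'   true covariances, effect draws, config).
#' @export
simulate_simple <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$design == "simple")
  if (cfg$rank_K > cfg$p) stop("`rank_K` must not exceed p", call. = FALSE)
  base <- do.call(surrogate_structure,
                  c(list(p = cfg$p, seed = cfg$structure_seed), cfg$structure_opts))
  eig <- eigen(base$S, symmetric = TRUE)
  Sigma_site <- vector("list", cfg$M)
  for (i in seq_len(cfg$M)) {
    shift <- matrix(0, cfg$p, cfg$p)
    for (k in seq_len(cfg$rank_K)) {
      shift <- shift + eig$values[k] * tcrossprod(eig$vectors[, k])
    }
    Sig <- base$S + cfg$severity[i] * shift
    ev_min <- min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min <= 0) {
      stop(sprintf("shifted covariance for site %d is not positive definite; consider psd_repair", i),
           call. = FALSE)
    }
    Sigma_site[[i]] <- Sig
  }
  beta <- .beta_vector(cfg$p, cfg$beta_magnitude)
  n <- sum(cfg$n_i)
  site <- factor(rep(paste0("site", seq_len(cfg$M)), times = cfg$n_i))

  set.seed(cfg$seed)
  x <- stats::rbinom(n, 1, cfg$bernoulli_p)
  eff <- .draw_effects_stream(cfg)
  E <- matrix(0, n, cfg$p)
  for (i in seq_len(cfg$M)) {
    rows <- which(as.integer(site) == i)
    E[rows, ] <- .rmvn(length(rows), Sigma_site[[i]])
  }
  truth <- list(S = base$S, alpha = base$alpha, Sigma_site = Sigma_site,
                hemisphere = base$hemisphere)
  .assemble_dataset(cfg, base$alpha, beta, x, site, eff, E, truth)
}

#' Simulate the complex covariance-effects designs
#'
#' Per-subject error covariance is
#' \eqn{\Sigma_{ij} = S + x_{ij}\Psi + \Omega_i}, repaired to the eigenvalue
#' floor and rescaled to unit diagonal (\eqn{D_{ij}\Sigma_{ij}D_{ij}}), so
#' covariance effects never alter marginal variances. \eqn{\Omega_i} are
#' distinct high-rank site shifts from [make_site_shift_matrices()];
#' \eqn{\Psi = -3/4\,\Omega_3} when the diagnosis affects covariance. Design
#' toggles: \code{combat} zeroes \eqn{\Omega} and \eqn{\Psi}; \code{dx_mean}
#' zeroes \eqn{\Psi}; \code{cov_only} zeroes \eqn{\gamma}, sets
#' \eqn{\delta = 1}, and \eqn{\beta = 0}. When \code{p < p_base}, structures
#' are built at \code{p_base} and the sub-blocks for the first p/2 features
#' of each hemisphere are used.
#'
#' @param cfg a \code{sim_config} with design in
#'   \code{c("combat", "dx_mean", "dx_cov", "cov_only")}.
#' @return a \code{sim_dataset}; \code{truth$Sigma_group} holds the true
#'   (unit-diagonal) covariance for every site x diagnosis cell, and
#'   \code{truth$Omega}, \code{truth$Psi} the shift matrices.
#' @export
simulate_complex <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"),
            cfg$design %in% c("combat", "dx_mean", "dx_cov", "cov_only"))
  p_base <- cfg$p_base
  base <- do.call(surrogate_structure,
                  c(list(p = p_base, seed = cfg$structure_seed), cfg$structure_opts))
  need_omega <- cfg$design != "combat"
  Omega <- if (need_omega) {
    make_site_shift_matrices(cfg$M, p_base, seed = cfg$structure_seed, avoid = base$S)
  } else {
    replicate(cfg$M, matrix(0, p_base, p_base), simplify = FALSE)
  }
  Psi <- if (cfg$design %in% c("dx_cov", "cov_only")) {
    -0.75 * Omega[[min(3L, cfg$M)]]
  } else {
    matrix(0, p_base, p_base)
  }

  sub <- .subblock_index(cfg$p, p_base)
  S <- base$S[sub, sub]
  alpha <- base$alpha[sub]
  Omega <- lapply(Omega, function(Om) Om[sub, sub, drop = FALSE])
  Psi <- Psi[sub, sub, drop = FALSE]

  Sigma_group <- vector("list", cfg$M)
  for (i in seq_len(cfg$M)) {
    Sigma_group[[i]] <- lapply(c(0, 1), function(xv) {
      Sig <- S + xv * Psi + Omega[[i]]
      scale_to_unit_diag(psd_repair(Sig, cfg$psd_floor))
    })
  }

  cov_only <- cfg$design == "cov_only"
  beta <- if (cov_only) numeric(cfg$p) else .beta_vector(cfg$p, cfg$beta_magnitude)
  n <- sum(cfg$n_i)
  site <- factor(rep(paste0("site", seq_len(cfg$M)), times = cfg$n_i))

  set.seed(cfg$seed)
  x <- stats::rbinom(n, 1, cfg$bernoulli_p)
  eff <- if (cov_only) {
    list(gamma = matrix(0, cfg$M, cfg$p), delta = matrix(1, cfg$M, cfg$p))
  } else {
    .draw_effects_stream(cfg)
  }
  E <- matrix(0, n, cfg$p)
  for (i in seq_len(cfg$M)) {
    for (xv in c(0L, 1L)) {
      rows <- which(as.integer(site) == i & x == xv)
      if (length(rows)) E[rows, ] <- .rmvn(length(rows), Sigma_group[[i]][[xv + 1L]])
    }
  }
  truth <- list(S = S, alpha = alpha, Sigma_group = Sigma_group,
                Omega = Omega, Psi = Psi,
                hemisphere = factor(rep(c("left", "right"), each = cfg$p / 2)))
  .assemble_dataset(cfg, alpha, beta, x, site, eff, E, truth)
}

#' Simulate one dataset from any configured design
#'
#' Dispatches to [simulate_simple()] or [simulate_complex()].
#'
#' @param cfg a \code{sim_config}.
#' @return a \code{sim_dataset}.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$design == "simple") simulate_simple(cfg) else simulate_complex(cfg)
}
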