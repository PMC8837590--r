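#' @noRd
#' Coerce and validate a subjects x features matrix.
#' Feature names must be unique; missing values are rejected outright.
.as_feature_matrix <- function(Y, arg = "Y") {
  if (is.data.frame(Y)) Y <- as.matrix(Y)
  if (!is.matrix(Y) || !is.numeric(Y)) {
    stop(sprintf("`%s` must be a numeric matrix or data frame", arg), call. = FALSE)
  }
  if (ncol(Y) < 1L) stop(sprintf("`%s` must have at least one feature column", arg), call. = FALSE)
  if (anyNA(Y) || any(!is.finite(Y))) {
    bad <- which(!is.finite(Y), arr.ind = TRUE)[1L, ]
    stop(sprintf("`%s` contains missing or non-finite values (first at row %d, column %d)",
                 arg, bad[1L], bad[2L]), call. = FALSE)
  }
  if (is.null(colnames(Y))) colnames(Y) <- paste0("feature_", seq_len(ncol(Y)))
  if (anyDuplicated(colnames(Y))) {
    stop(sprintf("`%s` has duplicated feature names: %s", arg,
                 paste(unique(colnames(Y)[duplicated(colnames(Y))]), collapse = ", ")),
         call. = FALSE)
  }
  Y
}

#' @noRd
#' Validate site labels against a feature matrix and the minimum-size rule.
.as_site <- function(site, n, min_site_size = 3L) {
  if (length(site) != n) {
    stop(sprintf("site labels have length %d but data has %d rows", length(site), n),
         call. = FALSE)
  }
  if (anyNA(site)) stop("site labels contain missing values", call. = FALSE)
  site <- factor(site)
  site <- droplevels(site)
  counts <- table(site)
  small <- names(counts)[counts < min_site_size]
  if (length(small)) {
    stop(sprintf("site(s) %s have fewer than %d subjects",
                 paste(small, collapse = ", "), min_site_size), call. = FALSE)
  }
  site
}

#' @noRd
#' Validate an optional covariate design (no intercept column; full rank with one).
.as_design <- function(X, n, check_rank = TRUE) {
  if (is.null(X)) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  if (is.vector(X)) X <- matrix(X, ncol = 1, dimnames = list(NULL, "x"))
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("covariates must be a numeric matrix, data frame, or vector", call. = FALSE)
  }
  if (nrow(X) != n) stop(sprintf("covariates have %d rows but data has %d", nrow(X), n), call. = FALSE)
  if (anyNA(X) || any(!is.finite(X))) stop("covariates contain missing or non-finite values", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) > 0 && check_rank) {
    aug <- cbind(`(Intercept)` = 1, X)
    qa <- qr(aug)
    if (qa$rank < ncol(aug)) {
      dropped <- colnames(aug)[qa$pivot[seq.int(qa$rank + 1L, ncol(aug))]]
      stop(sprintf("covariate design is rank deficient; collinear column(s): %s",
                   paste(dropped, collapse = ", ")), call. = FALSE)
    }
  }
  X
}

#' Derive a child seed for a replicate stream
#'
#' Deterministic counter scheme used throughout the simulation harness: each
#' replicate (and each independent use of randomness within a replicate) gets
#' its own 31-bit seed derived from the master seed, so replicates are
#' individually reproducible.
#'
#' @param master master integer seed.
#' @param counter replicate index (1-based).
#' @param stream optional sub-stream index for independent draws within a
#'   replicate (0 = data generation, 1 = analysis randomness, ...).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, counter, stream = 0L) {
  as.integer(((as.numeric(master) %% 2147483646) +
                7919 * as.numeric(counter) +
                104729 * as.numeric(stream)) %% 2147483646) + 1L
}
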