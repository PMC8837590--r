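#' Replicate-level simulation study of harmonization performance
#'
#' Runs the full evaluation protocol over independently simulated datasets:
#' per replicate, a dataset is generated from \code{cfg}, harmonized per arm
#' (ComBat and CovBat always include the simulated diagnosis as a protected
#' covariate; CovBat uses \code{pct_var}), and the requested metrics are
#' computed:
#' \describe{
#'   \item{distance}{pairwise within-site covariance Frobenius distances of
#'     diagnosis-residualized data, plus mean distance to the true base
#'     correlation when the design provides one.}
#'   \item{ml}{one random 50/50 split per replicate; random-forest detection
#'     AUC for membership of site 1 (diagnosis residualized out first) and
#'     for the simulated diagnosis.}
#'   \item{manova}{Pillai-trace p-values for site and diagnosis.}
#' }
#' Replicates whose training or validation half lacks a label class are
#' replaced by a freshly generated dataset. All randomness derives from
#' \code{seed} through the documented [child_seed()] counter scheme.
#'
#' The report deliberately exposes per-replicate values: in particular the
#' number of replicates where CovBat's site AUC exceeds ComBat's is recorded
#' (\code{aggregates$site_auc_covbat_above_combat}), because small samples
#' with many features are a known regime where covariance harmonization can
#' inflate site detection.
#'
#' @param cfg a [sim_config()].
#' @param arms subset of \code{c("raw", "combat", "covbat")}.
#' @param n_reps number of replicate datasets.
#' @param seed master seed.
#' @param metrics subset of \code{c("distance", "ml", "manova")}.
#' @param ml_targets subset of \code{c("site", "diagnosis")}.
#' @param pct_var CovBat variance threshold (default 0.95).
#' @param classifier fit/score pair, see [rf_classifier()].
#' @param pc_sweep optional vector of \code{pct_var} values; for each, an
#'   extra CovBat arm (site-detection AUC only) is evaluated.
#' @param eb empirical Bayes in the ComBat stage (default TRUE).
#' @return object of class \code{study_report} with \code{per_rep} (long
#'   data frame: rep, arm, metric, value) and \code{aggregates}.
#' @export
simulation_study <- function(cfg, arms = c("raw", "combat", "covbat"),
                             n_reps = 100L, seed = 1L,
                             metrics = c("distance", "ml", "manova"),
                             ml_targets = c("site", "diagnosis"),
                             pct_var = 0.95, classifier = rf_classifier(),
                             pc_sweep = NULL, eb = TRUE) {
  stopifnot(inherits(cfg, "sim_config"), n_reps >= 1)
  arms <- match.arg(arms, c("raw", "combat", "covbat"), several.ok = TRUE)
  metrics <- match.arg(metrics, c("distance", "ml", "manova"), several.ok = TRUE)
  ml_targets <- match.arg(ml_targets, c("site", "diagnosis"), several.ok = TRUE)

  rows <- list()
  add_row <- function(rep, arm, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(rep = rep, arm = arm, metric = metric,
                                             value = value, stringsAsFactors = FALSE)
  }

  for (r in seq_len(n_reps)) {
    # regenerate degenerate datasets rather than redrawing the split
    ds <- NULL
    idx <- NULL
    for (attempt in 0:50) {
      cfg_r <- cfg
      cfg_r$seed <- child_seed(seed, r, stream = 3L + attempt)
      ds <- tryCatch(simulate_dataset(cfg_r), error = function(e) NULL)
      if (is.null(ds)) next
      n <- nrow(ds$Y)
      set.seed(child_seed(seed, r, stream = 1L))
      idx <- sample.int(n, floor(n / 2))
      if (!("ml" %in% metrics)) break
      site1 <- ds$site == levels(ds$site)[1L]
      ok <- length(unique(ds$x[idx])) == 2 && length(unique(ds$x[-idx])) == 2 &&
        length(unique(site1[idx])) == 2 && length(unique(site1[-idx])) == 2
      if (ok) break
      ds <- NULL
    }
    if (is.null(ds)) stop(sprintf("replicate %d: could not generate a usable dataset", r), call. = FALSE)

    x_mat <- matrix(as.numeric(ds$x), ncol = 1, dimnames = list(NULL, "diagnosis"))
    arm_data <- list()
    err_wrap <- function(expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("replicate %d: %s", r, conditionMessage(e)), call. = FALSE)
      })
    }
    if ("raw" %in% arms) arm_data$raw <- ds$Y
    if ("combat" %in% arms) {
      cm <- err_wrap(combat_fit(ds$Y, ds$site, x_mat, eb = eb))
      arm_data$combat <- combat_transform(cm, ds$Y, ds$site, x_mat)
    }
    if ("covbat" %in% arms) {
      arm_data$covbat <- err_wrap(
        covbat_harmonize(ds$Y, ds$site, x_mat, pct_var = pct_var, eb = eb)$harmonized)
    }
    if (!is.null(pc_sweep)) {
      for (pv in pc_sweep) {
        arm_data[[sprintf("covbat@%.2f", pv)]] <- err_wrap(
          covbat_harmonize(ds$Y, ds$site, x_mat, pct_var = pv, eb = eb)$harmonized)
      }
    }

    site1 <- ds$site == levels(ds$site)[1L]
    for (arm in names(arm_data)) {
      Ya <- arm_data[[arm]]
      sweep_arm <- grepl("^covbat@", arm)
      if ("distance" %in% metrics && !sweep_arm) {
        wsc <- within_site_covariances(Ya, ds$site, X = x_mat)
        M <- length(wsc)
        pairs <- utils::combn(M, 2)
        dists <- apply(pairs, 2, function(pr) frobenius_distance(wsc[[pr[1]]], wsc[[pr[2]]]))
        for (j in seq_len(ncol(pairs))) {
          add_row(r, arm, sprintf("dist_pair_%d_%d", pairs[1, j], pairs[2, j]), dists[j])
        }
        add_row(r, arm, "dist_pairwise_mean", mean(dists))
        if (!is.null(ds$truth$S)) {
          d_truth <- mean(vapply(wsc, frobenius_distance, numeric(1), B = ds$truth$S))
          add_row(r, arm, "dist_to_truth", d_truth)
        }
      }
      if ("ml" %in% metrics) {
        arm_id <- match(arm, names(arm_data))
        if ("site" %in% ml_targets) {
          Yres <- residualize(Ya, x_mat)
          fit <- classifier$fit(Yres[idx, , drop = FALSE], site1[idx],
                                seed = child_seed(seed, r, stream = 100L + arm_id))
          add_row(r, arm, "auc_site", auc(classifier$score(fit, Yres[-idx, , drop = FALSE]),
                                          site1[-idx]))
        }
        if ("diagnosis" %in% ml_targets && !sweep_arm) {
          fit <- classifier$fit(Ya[idx, , drop = FALSE], ds$x[idx] == 1L,
                                seed = child_seed(seed, r, stream = 200L + arm_id))
          add_row(r, arm, "auc_diagnosis", auc(classifier$score(fit, Ya[-idx, , drop = FALSE]),
                                               ds$x[-idx]))
        }
      }
      if ("manova" %in% metrics && !sweep_arm) {
        add_row(r, arm, "manova_p_site", manova_pillai(Ya, ds$site)$p_value)
        add_row(r, arm, "manova_p_diagnosis", manova_pillai(Ya, factor(ds$x))$p_value)
      }
    }
  }

  per_rep <- do.call(rbind, rows)
  report <- structure(list(
    config = cfg,
    arms = arms,
    n_reps = as.integer(n_reps),
    seed = as.integer(seed),
    pct_var = pct_var,
    metrics = metrics,
    classifier = classifier$description,
    per_rep = per_rep,
    aggregates = .aggregate_study(per_rep, arms, n_reps)
  ), class = "study_report")
  report
}

#' @noRd
.aggregate_study <- function(per_rep, arms, n_reps) {
  agg <- list()
  get <- function(arm, metric) per_rep$value[per_rep$arm == arm & per_rep$metric == metric]
  metrics <- unique(per_rep$metric)

  for (metric in metrics) {
    for (arm in unique(per_rep$arm)) {
      v <- get(arm, metric)
      if (!length(v)) next
      key <- sprintf("%s.%s", metric, arm)
      if (startsWith(metric, "auc")) {
        agg[[key]] <- list(median = stats::median(v),
                           iqr = unname(stats::quantile(v, c(0.25, 0.75))))
      } else if (startsWith(metric, "manova_p")) {
        agg[[key]] <- list(rejection_rate = mean(v < 0.05))
      } else {
        agg[[key]] <- list(mean = mean(v), sd = stats::sd(v))
      }
    }
  }
  if (all(c("raw", "combat", "covbat") %in% arms) &&
      "dist_pairwise_mean" %in% metrics) {
    d_raw <- get("raw", "dist_pairwise_mean")
    d_cb <- get("combat", "dist_pairwise_mean")
    d_cv <- get("covbat", "dist_pairwise_mean")
    agg$distance_ordering_frac <- mean(d_cv < d_cb & d_cb < d_raw)
  }
  if (all(c("combat", "covbat") %in% arms) && "auc_site" %in% metrics) {
    a_cb <- get("combat", "auc_site")
    a_cv <- get("covbat", "auc_site")
    if (length(a_cb) == length(a_cv) && length(a_cb) > 0) {
      agg$site_auc_covbat_above_combat <- sum(a_cv > a_cb)
    }
  }
  agg
}

#' Write a study report to JSON and CSV
#'
#' The JSON document carries the configuration, seeds, and aggregates; the
#' CSV is the flat per-replicate table (one row per replicate x arm x
#' metric) for downstream plotting.
#'
#' @param report a \code{study_report}.
#' @param json_path output path for the JSON summary (NULL to skip).
#' @param csv_path output path for the per-replicate CSV (NULL to skip).
#' @return invisibly, the report.
#' @export
write_study_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "study_report"))
  if (!is.null(json_path)) {
    cfg <- report$config
    cfg$structure_opts <- NULL
    doc <- list(
      version = 1L,
      design = cfg$design,
      config = cfg[c("design", "M", "n_i", "p", "bernoulli_p", "beta_magnitude",
                     "gamma_sd", "severity", "rank_K", "psd_floor", "structure_seed", "seed")],
      arms = report$arms,
      n_reps = report$n_reps,
      seed = report$seed,
      pct_var = report$pct_var,
      classifier = report$classifier,
      aggregates = report$aggregates
    )
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_rep, csv_path, row.names = FALSE)
  }
  invisible(report)
}
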