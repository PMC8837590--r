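#' Read a subjects-by-features dataset from delimited text
#'
#' Comma-separated by default; tab-separated files are auto-detected from a
#' \code{.tsv}/\code{.tab} extension. The header is mandatory; the site
#' column is required; covariate columns are taken by name; feature columns
#' are all remaining numeric columns unless listed explicitly. Missing
#' values and non-numeric cells are hard errors naming their coordinates.
#'
#' @param path file path.
#' @param site_column name of the site/batch column.
#' @param covariate_columns character vector of covariate column names.
#' @param feature_columns explicit feature list (NULL = auto).
#' @param id_column optional subject-id column (checked for duplicates, used
#'   as row names).
#' @param min_site_size minimum subjects per site.
#' @return list with \code{Y} (matrix), \code{site} (factor), \code{X}
#'   (covariate matrix or NULL), \code{ids}.
#' @export
read_dataset <- function(path, site_column, covariate_columns = character(),
                         feature_columns = NULL, id_column = NULL,
                         min_site_size = 3L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  if (!site_column %in% names(df)) {
    stop(sprintf("site column '%s' not found", site_column), call. = FALSE)
  }
  missing_cov <- setdiff(covariate_columns, names(df))
  if (length(missing_cov)) {
    stop(sprintf("covariate column(s) not found: %s", paste(missing_cov, collapse = ", ")),
         call. = FALSE)
  }
  ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) stop(sprintf("id column '%s' not found", id_column), call. = FALSE)
    ids <- as.character(df[[id_column]])
    if (anyDuplicated(ids)) {
      stop(sprintf("duplicate subject id(s): %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
    }
  }
  reserved <- c(site_column, covariate_columns, id_column)
  if (is.null(feature_columns)) {
    feature_columns <- setdiff(names(df), reserved)
    numericish <- vapply(df[feature_columns], function(col) {
      is.numeric(col) || all(!is.na(suppressWarnings(as.numeric(col[!is.na(col)]))))
    }, logical(1))
    feature_columns <- feature_columns[numericish]
  } else {
    missing_feat <- setdiff(feature_columns, names(df))
    if (length(missing_feat)) {
      stop(sprintf("feature column(s) not found: %s", paste(missing_feat, collapse = ", ")),
           call. = FALSE)
    }
  }
  if (!length(feature_columns)) stop("no feature columns found", call. = FALSE)

  coerce_block <- function(cols, what) {
    mat <- matrix(NA_real_, nrow(df), length(cols), dimnames = list(ids, cols))
    for (cn in cols) {
      raw <- df[[cn]]
      if (anyNA(raw)) {
        stop(sprintf("missing value in %s column '%s' at row(s) %s", what, cn,
                     paste(utils::head(which(is.na(raw)), 5), collapse = ", ")), call. = FALSE)
      }
      val <- suppressWarnings(as.numeric(raw))
      if (anyNA(val)) {
        bad <- which(is.na(val))
        stop(sprintf("non-numeric cell(s) in %s column '%s' at row(s) %s: %s", what, cn,
                     paste(utils::head(bad, 5), collapse = ", "),
                     paste(utils::head(raw[bad], 5), collapse = ", ")), call. = FALSE)
      }
      mat[, cn] <- val
    }
    mat
  }
  Y <- coerce_block(feature_columns, "feature")
  X <- if (length(covariate_columns)) coerce_block(covariate_columns, "covariate") else NULL
  if (anyNA(df[[site_column]])) {
    stop(sprintf("missing value in site column at row(s) %s",
                 paste(utils::head(which(is.na(df[[site_column]])), 5), collapse = ", ")),
         call. = FALSE)
  }
  site <- .as_site(df[[site_column]], nrow(Y), min_site_size)
  list(Y = Y, site = site, X = X, ids = ids)
}

#' Write a dataset to delimited text
#'
#' Inverse of [read_dataset()]: one row per subject, site (and optional
#' covariate / extra label) columns followed by the feature columns, in the
#' input row and column order. Tab-separated when the path ends in
#' \code{.tsv}/\code{.tab}.
#'
#' @param Y feature matrix.
#' @param site site labels.
#' @param path output path.
#' @param X optional covariate matrix.
#' @param extra optional named list of additional columns (e.g. diagnosis).
#' @return invisibly, the path.
#' @export
write_dataset <- function(Y, site, path, X = NULL, extra = NULL) {
  Y <- .as_feature_matrix(Y)
  df <- data.frame(site = as.character(site), stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!is.null(extra)) for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  if (!is.null(X)) for (nm in colnames(X)) df[[nm]] <- X[, nm]
  for (nm in colnames(Y)) df[[nm]] <- Y[, nm]
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @noRd
.serialize_combat <- function(model) {
  nv <- model$naive
  list(
    alpha_hat = nv$alpha_hat,
    beta_hat = nv$beta_hat,
    sigma_hat = nv$sigma_hat,
    gamma_hat = nv$gamma_hat,
    delta2_hat = nv$delta2_hat,
    site_levels = nv$site_levels,
    n_i = unname(nv$n_i),
    covariate_names = nv$covariate_names,
    min_site_size = nv$min_site_size,
    feature_names = names(nv$alpha_hat),
    hyper = model$hyper,
    gamma_star = model$gamma_star,
    delta_star = model$delta_star,
    eb_enabled = model$eb_enabled
  )
}

#' @noRd
.deserialize_combat <- function(doc) {
  feat <- unlist(doc$feature_names)
  site_levels <- unlist(doc$site_levels)
  cov_names <- if (length(doc$covariate_names)) unlist(doc$covariate_names) else character(0)
  # row-major nested arrays are already simplified to matrices by
  # jsonlite::read_json(simplifyVector = TRUE); fall back to manual refill
  as_mat <- function(x, nr, nc, dn) {
    m <- if (is.matrix(x)) x else matrix(unlist(x), nr, nc, byrow = TRUE)
    dimnames(m) <- dn
    m
  }
  M <- length(site_levels)
  p <- length(feat)
  naive <- structure(list(
    alpha_hat = stats::setNames(unlist(doc$alpha_hat), feat),
    beta_hat = if (length(cov_names)) as_mat(doc$beta_hat, length(cov_names), p, list(cov_names, feat))
               else matrix(numeric(0), 0, p, dimnames = list(NULL, feat)),
    sigma_hat = stats::setNames(unlist(doc$sigma_hat), feat),
    gamma_hat = as_mat(doc$gamma_hat, M, p, list(site_levels, feat)),
    delta2_hat = as_mat(doc$delta2_hat, M, p, list(site_levels, feat)),
    standardized = NULL,
    site_levels = site_levels,
    n_i = stats::setNames(unlist(doc$n_i), site_levels),
    covariate_names = cov_names,
    min_site_size = doc$min_site_size
  ), class = "combat_naive")
  structure(list(
    naive = naive,
    hyper = doc$hyper,
    gamma_star = as_mat(doc$gamma_star, M, p, list(site_levels, feat)),
    delta_star = as_mat(doc$delta_star, M, p, list(site_levels, feat)),
    eb_enabled = isTRUE(doc$eb_enabled),
    covariate_names = cov_names
  ), class = "combat_model")
}

#' Serialize a fitted harmonization model to JSON
#'
#' Single versioned JSON document (all matrices row-major). Works for both
#' \code{combat_model} and \code{covbat_model} objects; the standardized
#' training residuals are not stored (they are not needed to apply the
#' model).
#'
#' @param model a \code{combat_model} or \code{covbat_model}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "combat_model")) {
    doc <- list(version = 1L, type = "combat", combat = .serialize_combat(model))
  } else if (inherits(model, "covbat_model")) {
    adj <- model$adjustment
    adj_doc <- list(mode = adj$mode, K = adj$K, skipped = adj$skipped,
                    active = adj$active, site_levels = adj$site_levels)
    if (identical(adj$mode, "eb") && !is.null(adj$score_model)) {
      adj_doc$score_model <- .serialize_combat(adj$score_model)
    } else if (length(adj$active)) {
      adj_doc$mu_hat <- adj$mu_hat
      adj_doc$rho_hat <- adj$rho_hat
      adj_doc$pooled_mean <- adj$pooled_mean
      adj_doc$pooled_var <- adj$pooled_var
    }
    doc <- list(
      version = 1L, type = "covbat",
      combat = .serialize_combat(model$combat),
      decomposition = list(
        components = model$decomposition$components,
        eigenvalues = model$decomposition$eigenvalues,
        center = model$decomposition$center,
        rank_q = model$decomposition$rank_q
      ),
      adjustment = adj_doc,
      pct_var = model$pct_var,
      K = model$K
    )
  } else {
    stop("`model` must be a combat_model or covbat_model", call. = FALSE)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a harmonization model from JSON
#'
#' @param path path to a document written by [write_model()]. Documents with
#'   a newer major version are refused.
#' @return a \code{combat_model} or \code{covbat_model}.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$version) || doc$version > 1) {
    stop("unsupported model document version; this package reads version 1", call. = FALSE)
  }
  cm <- .deserialize_combat(doc$combat)
  if (identical(doc$type, "combat")) return(cm)
  feat <- names(cm$naive$alpha_hat)
  q <- doc$decomposition$rank_q
  comp <- doc$decomposition$components
  if (!is.matrix(comp)) comp <- matrix(unlist(comp), length(feat), q, byrow = TRUE)
  dimnames(comp) <- list(feat, paste0("PC", seq_len(q)))
  adj_doc <- doc$adjustment
  adj <- structure(list(
    mode = adj_doc$mode,
    K = as.integer(adj_doc$K),
    skipped = as.integer(unlist(adj_doc$skipped)),
    active = as.integer(unlist(adj_doc$active)),
    site_levels = unlist(adj_doc$site_levels)
  ), class = "score_adjustment")
  if (length(adj$active)) {
    if (identical(adj$mode, "eb")) {
      adj$score_model <- .deserialize_combat(adj_doc$score_model)
    } else {
      nm <- paste0("PC", adj$active)
      M <- length(adj$site_levels)
      as_mat <- function(x) {
        m <- if (is.matrix(x)) x else matrix(unlist(x), M, length(adj$active), byrow = TRUE)
        dimnames(m) <- list(adj$site_levels, nm)
        m
      }
      adj$mu_hat <- as_mat(adj_doc$mu_hat)
      adj$rho_hat <- as_mat(adj_doc$rho_hat)
      adj$pooled_mean <- stats::setNames(unlist(adj_doc$pooled_mean), nm)
      adj$pooled_var <- stats::setNames(unlist(adj_doc$pooled_var), nm)
    }
  }
  structure(list(
    combat = cm,
    decomposition = list(
      components = comp,
      eigenvalues = unlist(doc$decomposition$eigenvalues),
      center = stats::setNames(unlist(doc$decomposition$center), feat),
      rank_q = as.integer(q)
    ),
    adjustment = adj,
    pct_var = doc$pct_var,
    K = as.integer(doc$K)
  ), class = "covbat_model")
}

#' @noRd
#' Minimal --flag / --key value argument parser.
.parse_args <- function(argv, flags = character()) {
  out <- list(.positional = character(0))
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (key %in% flags) {
        out[[key]] <- TRUE
        i <- i + 1L
      } else {
        if (i == length(argv)) stop(sprintf("flag --%s needs a value", key), call. = FALSE)
        out[[key]] <- argv[i + 1L]
        i <- i + 2L
      }
    } else {
      out$.positional <- c(out$.positional, a)
      i <- i + 1L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: \code{harmonize} (read a dataset, fit and apply
#' ComBat/CovBat, write harmonized data and a model JSON), \code{simulate}
#' (write a synthetic dataset and its ground truth), \code{evaluate}
#' (covariance-distance / detection / MANOVA diagnostics on a labeled
#' dataset), and \code{study} (a replicate-level simulation study). Results
#' go to files; logging goes to stderr. Exit codes: 0 success, 2 usage
#' error, 3 data validation error, 4 numerical failure.
#'
#' A thin executable wrapper lives at \code{system.file("cli", "covbat",
#' package = "covbat")}.
#'
#' @param argv character vector of arguments (subcommand first).
#' @return integer exit status (invisibly suitable for \code{quit()}).
#' @export
run_command <- function(argv) {
  usage <- function() {
    message(paste(
      "usage: covbat <subcommand> [options]",
      "  harmonize --input F --site-col S [--covariates a,b] [--method combat|covbat]",
      "            [--pct-var 0.95 | --n-pc K] [--score-eb] [--no-eb] [--min-site-size 3]",
      "            --output F [--model-out F]",
      "  simulate  --design D [--ni 250] [--p 62] [--seed 1] --out-prefix P",
      "  evaluate  --input F --site-col S --label-col L [--covariates a,b]",
      "            [--reps 100] [--seed 1] --out F",
      "  study     --design D [--reps 100] [--ni 250] [--p 62] [--seed 1]",
      "            [--pct-var 0.95] [--metrics distance,ml,manova] --out-prefix P",
      sep = "\n"))
  }
  if (length(argv) < 1) {
    usage()
    return(invisible(2L))
  }
  sub <- argv[1L]
  if (!sub %in% c("harmonize", "simulate", "evaluate", "study")) {
    message(sprintf("unknown subcommand '%s'", sub))
    usage()
    return(invisible(2L))
  }
  args <- tryCatch(.parse_args(argv[-1L], flags = c("score-eb", "no-eb", "quiet")),
                   error = function(e) e)
  if (inherits(args, "error")) {
    message(conditionMessage(args))
    return(invisible(2L))
  }
  log_msg <- function(...) if (!isTRUE(args$quiet)) message(sprintf(...))
  need <- function(keys) {
    miss <- setdiff(keys, names(args))
    if (length(miss)) stop(sprintf("missing required option(s): %s",
                                   paste0("--", miss, collapse = ", ")), call. = FALSE)
  }
  num <- function(key, default) if (is.null(args[[key]])) default else as.numeric(args[[key]])

  status <- tryCatch({
    seed <- as.integer(num("seed", 1))
    log_msg("covbat %s | seed %d | package version %s", sub, seed,
            as.character(utils::packageVersion("covbat")))
    if (sub == "harmonize") {
      need(c("input", "site-col", "output"))
      covs <- if (is.null(args$covariates)) character(0) else strsplit(args$covariates, ",")[[1L]]
      d <- read_dataset(args$input, args[["site-col"]], covs,
                        min_site_size = as.integer(num("min-site-size", 3)))
      method <- if (is.null(args$method)) "covbat" else args$method
      eb <- !isTRUE(args[["no-eb"]])
      if (method == "combat") {
        model <- combat_fit(d$Y, d$site, d$X, eb = eb)
        out <- combat_transform(model, d$Y, d$site, d$X)
      } else if (method == "covbat") {
        n_pc <- if (is.null(args[["n-pc"]])) NULL else as.integer(args[["n-pc"]])
        if (!is.null(n_pc) && !is.null(args[["pct-var"]])) {
          stop("--pct-var and --n-pc are mutually exclusive", call. = FALSE)
        }
        res <- covbat_harmonize(d$Y, d$site, d$X, pct_var = num("pct-var", 0.95),
                                n_pc = n_pc, eb = eb,
                                score_eb = isTRUE(args[["score-eb"]]))
        model <- res$model
        out <- res$harmonized
        log_msg("covbat K = %d principal components harmonized", model$K)
      } else {
        stop(sprintf("unknown method '%s'", method), call. = FALSE)
      }
      write_dataset(out, d$site, args$output, X = d$X)
      if (!is.null(args[["model-out"]])) write_model(model, args[["model-out"]])
      log_msg("wrote %s", args$output)
      0L
    } else if (sub == "simulate") {
      need(c("design", "out-prefix"))
      cfg <- sim_config(design = args$design, n_i = as.integer(num("ni", 250)),
                        p = as.integer(num("p", 62)), seed = seed)
      ds <- simulate_dataset(cfg)
      data_path <- paste0(args[["out-prefix"]], "_data.csv")
      write_dataset(ds$Y, ds$site, data_path, extra = list(diagnosis = ds$x))
      truth <- list(version = 1L, design = cfg$design, seed = seed,
                    beta = ds$truth$beta, gamma = ds$truth$gamma, delta = ds$truth$delta,
                    S = ds$truth$S)
      jsonlite::write_json(truth, paste0(args[["out-prefix"]], "_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      log_msg("wrote %s", data_path)
      0L
    } else if (sub == "evaluate") {
      need(c("input", "site-col", "label-col", "out"))
      covs <- if (is.null(args$covariates)) character(0) else strsplit(args$covariates, ",")[[1L]]
      d <- read_dataset(args$input, args[["site-col"]], c(covs, args[["label-col"]]))
      lab <- d$X[, args[["label-col"]]]
      Xcov <- if (length(covs)) d$X[, covs, drop = FALSE] else NULL
      wsc <- within_site_covariances(d$Y, d$site, X = d$X)
      pairs <- utils::combn(length(wsc), 2)
      dists <- apply(pairs, 2, function(pr) frobenius_distance(wsc[[pr[1]]], wsc[[pr[2]]]))
      det_site <- detection_experiment(d$Y, d$site == levels(d$site)[1L],
                                       confounds = d$X, n_reps = as.integer(num("reps", 100)),
                                       seed = seed)
      det_lab <- detection_experiment(d$Y, lab, confounds = Xcov,
                                      n_reps = as.integer(num("reps", 100)), seed = seed)
      man_site <- manova_pillai(d$Y, d$site, X = Xcov)
      man_lab <- manova_pillai(d$Y, factor(lab), X = Xcov)
      doc <- list(version = 1L, seed = seed,
                  pairwise_covariance_distance = as.numeric(dists),
                  site_detection = det_site[c("median", "iqr", "n_reps", "classifier")],
                  label_detection = det_lab[c("median", "iqr", "n_reps", "classifier")],
                  manova_site = man_site[c("pillai", "approx_f", "df", "p_value")],
                  manova_label = man_lab[c("pillai", "approx_f", "df", "p_value")])
      jsonlite::write_json(doc, args$out, auto_unbox = TRUE, digits = NA)
      log_msg("wrote %s", args$out)
      0L
    } else {
      need(c("design", "out-prefix"))
      metrics <- if (is.null(args$metrics)) c("distance", "ml", "manova")
                 else strsplit(args$metrics, ",")[[1L]]
      cfg <- sim_config(design = args$design, n_i = as.integer(num("ni", 250)),
                        p = as.integer(num("p", 62)), seed = seed)
      rep_ct <- as.integer(num("reps", 100))
      report <- simulation_study(cfg, n_reps = rep_ct, seed = seed,
                                 metrics = metrics, pct_var = num("pct-var", 0.95))
      write_study_report(report,
                         json_path = paste0(args[["out-prefix"]], "_report.json"),
                         csv_path = paste0(args[["out-prefix"]], "_replicates.csv"))
      log_msg("wrote %s_report.json", args[["out-prefix"]])
      0L
    }
  }, error = function(e) {
    msg <- conditionMessage(e)
    message(sprintf("error: %s", msg))
    if (grepl("missing required|mutually exclusive|unknown method|needs a value", msg)) 2L
    else if (grepl("not found|missing value|non-numeric|duplicate|fewer than|rank deficient|must", msg)) 3L
    else 4L
  })
  invisible(as.integer(status))
}
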