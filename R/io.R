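# Delimited-text readers/writers. Canonical layout: sites as rows, a
# `site_id` first column, feature names as the remaining header fields.

#' Read and write feature matrices as CSV
#'
#' The on-disk layout is sites-by-features with a `site_id` first column and
#' a header row of feature names; in memory the matrix is features-by-sites
#' (see [feature_matrix()]).
#'
#' @param features a [feature_matrix()].
#' @param path file path.
#' @return `read_feature_matrix()` returns a [feature_matrix()];
#'   `write_feature_matrix()` returns `path` invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  stopifnot(is_feature_matrix(features))
  df <- data.frame(site_id = features$site_ids,
                   t(features$values), check.names = FALSE)
  names(df)[-1] <- features$feature_names
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "site_id") {
    stop("expected a 'site_id' first column", call. = FALSE)
  }
  feature_matrix(t(as.matrix(df[-1])),
                 feature_names = names(df)[-1],
                 site_ids = as.character(df$site_id))
}

#' Read and write site distributions as CSV
#'
#' Two columns: `site_id`, `mass`. Reading validates against an optional
#' expected site ordering.
#'
#' @param p probability vector.
#' @param site_ids character vector of site identifiers.
#' @param path file path.
#' @param expect_sites optional site-id vector to validate order against.
#' @export
write_distribution <- function(p, site_ids, path) {
  stopifnot(length(p) == length(site_ids))
  utils::write.csv(data.frame(site_id = site_ids, mass = p), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path, expect_sites = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("site_id", "mass") %in% names(df))) {
    stop("expected columns site_id, mass", call. = FALSE)
  }
  if (!is.null(expect_sites) &&
      !identical(as.character(df$site_id), as.character(expect_sites))) {
    stop("site ids do not match the feature matrix", call. = FALSE)
  }
  stats::setNames(df$mass, df$site_id)
}

#' Read a group assignment table
#'
#' Two columns: `feature`, `group`. Validated against the feature names of a
#' feature matrix when given.
#'
#' @param path file path.
#' @param features optional [feature_matrix()] whose feature ordering the
#'   table must cover exactly.
#' @return a [group_structure()].
#' @export
read_groups <- function(path, features = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("feature", "group") %in% names(df))) {
    stop("expected columns feature, group", call. = FALSE)
  }
  if (!is.null(features)) {
    idx <- match(features$feature_names, df$feature)
    if (anyNA(idx)) {
      stop(sprintf("no group label for feature(s): %s",
                   paste(features$feature_names[is.na(idx)], collapse = ", ")),
           call. = FALSE)
    }
    df <- df[idx, ]
  }
  group_structure(df$group)
}

#' Write path-fitting outputs
#'
#' Writes the per-hyperparameter summary table (`path.csv`: t, t/t0, raw and
#' cumulative nonzero counts, residual, iterations, converged, dual
#' objective) and the full coefficient matrix (`coefficients.csv`, features
#' by path points).
#'
#' @param result a [fit_path()] result.
#' @param dir output directory (created if needed).
#' @param zero_tol threshold for the nonzero counts.
#' @return invisibly, the paths written.
#' @export
write_path_result <- function(result, dir, zero_tol = 1e-8) {
  stopifnot(inherits(result, "maxent_path"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prof <- nonzero_profile(result, zero_tol = zero_tol)
  tab <- data.frame(
    t = prof$t, t_ratio = prof$t_ratio,
    nonzero = prof$nonzero, cumulative_nonzero = prof$cumulative_nonzero,
    residual = result$residuals, iterations = result$iterations,
    converged = result$converged, dual_objective = result$dual_objectives
  )
  path_file <- file.path(dir, "path.csv")
  utils::write.csv(tab, path_file, row.names = FALSE, quote = FALSE)
  coef_df <- data.frame(feature = rownames(result$coefficients),
                        result$coefficients, check.names = FALSE)
  names(coef_df)[-1] <- sprintf("t%03d", seq_along(result$schedule) - 1L)
  coef_file <- file.path(dir, "coefficients.csv")
  utils::write.csv(coef_df, coef_file, row.names = FALSE, quote = FALSE)
  invisible(c(path_file, coef_file))
}

#' Write or read a synthetic dataset directory
#'
#' Serializes a [generate_synthetic()] result to plain CSV files
#' (`features.csv`, `prior.csv`, `empirical.csv`, `true_p.csv`,
#' `true_w.csv`, `samples.csv`) plus a `manifest.dcf` recording the
#' generating parameters and seed.
#'
#' @param sim a `maxent_sim`.
#' @param dir output directory.
#' @return `write_simulation()` the directory, invisibly;
#'   `read_simulation()` a list mirroring the generator output (with the
#'   `problem` rebuilt).
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "maxent_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sites <- sim$features$site_ids
  write_feature_matrix(sim$features, file.path(dir, "features.csv"))
  write_distribution(sim$prior, sites, file.path(dir, "prior.csv"))
  write_distribution(sim$empirical, sites, file.path(dir, "empirical.csv"))
  write_distribution(sim$true_p, sites, file.path(dir, "true_p.csv"))
  utils::write.csv(data.frame(feature = sim$features$feature_names,
                              w = sim$true_w),
                   file.path(dir, "true_w.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(sample = seq_along(sim$samples),
                              site = sim$samples),
                   file.path(dir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- data.frame(m = sim$m, n = sim$n, sparsity = sim$sparsity,
                         l = sim$l, signal_scale = sim$signal_scale,
                         seed = sim$seed)
  write.dcf(manifest, file.path(dir, "manifest.dcf"))
  invisible(dir)
}

#' @rdname write_simulation
#' @export
read_simulation <- function(dir) {
  manifest <- as.list(as.data.frame(read.dcf(file.path(dir, "manifest.dcf")),
                                    stringsAsFactors = FALSE))
  manifest <- lapply(manifest, function(x) as.numeric(x))
  features <- read_feature_matrix(file.path(dir, "features.csv"))
  sites <- features$site_ids
  prior <- unname(read_distribution(file.path(dir, "prior.csv"), sites))
  empirical <- unname(read_distribution(file.path(dir, "empirical.csv"),
                                        sites))
  true_p <- unname(read_distribution(file.path(dir, "true_p.csv"), sites))
  tw <- utils::read.csv(file.path(dir, "true_w.csv"))
  samples <- utils::read.csv(file.path(dir, "samples.csv"))$site
  structure(
    list(features = features, true_w = tw$w, prior = prior,
         true_p = true_p, samples = as.integer(samples),
         empirical = empirical,
         problem = maxent_problem(features, empirical, prior),
         m = features$m, n = features$n,
         sparsity = as.integer(manifest$sparsity),
         l = as.integer(manifest$l),
         signal_scale = manifest$signal_scale,
         seed = as.integer(manifest$seed)),
    class = "maxent_sim"
  )
}
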