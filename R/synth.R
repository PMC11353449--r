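# Presence-only data preparation operators and the synthetic-data generator.

#' Ecoregion-weighted empirical distribution
#'
#' Builds the empirical distribution from presence-only occurrence flags by
#' weighting relative frequencies across regions: with \eqn{n_{r,total}}
#' sites in region r, \eqn{n_{r,fire}} of them with at least one occurrence,
#' and \eqn{Z = \sum_r n_{r,fire}/n_{r,total}}, each occurrence site j in
#' region r gets \eqn{\hat D(j) = (1/n_{r,total})/Z} and every other site 0.
#' Regions where occurrences are more widespread therefore receive more
#' total mass.
#'
#' @param region length-n vector of region labels.
#' @param fire length-n logical (or 0/1) occurrence flag per site.
#' @return probability vector of length n, with attributes `n_total`,
#'   `n_fire` (per region) and `Z`.
#' @examples
#' ecoregion_empirical_distribution(c(1, 1, 1, 1, 2, 2),
#'                                  c(1, 1, 0, 0, 1, 0))
#' @export
ecoregion_empirical_distribution <- function(region, fire) {
  n <- length(region)
  stopifnot(length(fire) == n)
  fire <- as.logical(fire)
  if (anyNA(fire) || anyNA(region)) stop("missing values", call. = FALSE)
  if (!any(fire)) {
    stop("no occurrences at all: empirical distribution is empty",
         call. = FALSE)
  }
  labels <- unique(region)
  idx <- match(region, labels)
  n_total <- tabulate(idx, nbins = length(labels))
  n_fire <- vapply(seq_along(labels),
                   function(r) sum(fire[idx == r]), integer(1))
  Z <- sum(n_fire / n_total)
  d <- numeric(n)
  d[fire] <- 1 / n_total[idx[fire]] / Z
  structure(d, n_total = stats::setNames(n_total, labels),
            n_fire = stats::setNames(n_fire, labels), Z = Z)
}

#' Impute and normalize a presence-only prior
#'
#' Sites without any recorded occurrence are given a tenth of the smallest
#' score observed among occurrence sites (\eqn{p_{nfire} =
#' \min(p_{fire})/10}), then all scores are normalized to sum to one. The
#' result is strictly positive and usable directly as a MaxEnt prior.
#'
#' @param p_fire length-n nonnegative scores (e.g. predicted occurrence
#'   probabilities).
#' @param fire length-n occurrence flag; scores at `fire == FALSE` sites are
#'   replaced by the imputed value.
#' @return strictly positive probability vector of length n.
#' @export
impute_and_normalize_prior <- function(p_fire, fire) {
  n <- length(p_fire)
  stopifnot(length(fire) == n)
  fire <- as.logical(fire)
  if (any(!is.finite(p_fire)) || any(p_fire < 0)) {
    stop("scores must be finite and nonnegative", call. = FALSE)
  }
  if (!any(fire) || all(p_fire[fire] == 0)) {
    stop("need at least one occurrence site with a positive score",
         call. = FALSE)
  }
  out <- p_fire
  out[!fire] <- min(p_fire[fire]) / 10
  if (any(out <= 0)) {
    stop("occurrence sites with zero score would leave the prior degenerate",
         call. = FALSE)
  }
  out / sum(out)
}

#' Min-max scale each feature to [0, 1]
#'
#' Applies the per-feature affine map \eqn{(x - \min)/(\max - \min)} so all
#' features share the range \[0, 1\]. Constant features map to all zeros with
#' a warning. The per-feature minima and ranges are stored as attributes
#' `scale_min` / `scale_range` so held-out sites can be scaled identically
#' via [apply_feature_scaling()].
#'
#' @param raw m x n numeric matrix (features by sites), finite entries.
#' @return a [feature_matrix()] with scaling attributes.
#' @export
minmax_scale_features <- function(raw) {
  raw <- as.matrix(raw)
  if (!all(is.finite(raw))) stop("non-finite feature values", call. = FALSE)
  mins <- apply(raw, 1, min)
  rng <- apply(raw, 1, max) - mins
  flat <- rng == 0
  if (any(flat)) {
    warning(sprintf("%d constant feature(s) mapped to all zeros", sum(flat)))
  }
  denom <- ifelse(flat, 1, rng)
  scaled <- (raw - mins) / denom
  scaled[flat, ] <- 0
  fm <- feature_matrix(scaled, feature_names = rownames(raw),
                       site_ids = colnames(raw))
  attr(fm, "scale_min") <- mins
  attr(fm, "scale_range") <- rng
  fm
}

#' Scale held-out sites with stored statistics
#'
#' @param raw m x k matrix of unscaled feature values for new sites.
#' @param scaled a [minmax_scale_features()] output carrying the scaling
#'   attributes.
#' @return m x k matrix on the training scale (values may fall outside
#'   \[0, 1\] for out-of-range sites; they are not clipped).
#' @export
apply_feature_scaling <- function(raw, scaled) {
  mins <- attr(scaled, "scale_min")
  rng <- attr(scaled, "scale_range")
  if (is.null(mins) || is.null(rng)) {
    stop("no scaling statistics attached; pass a minmax_scale_features() result",
         call. = FALSE)
  }
  raw <- as.matrix(raw)
  stopifnot(nrow(raw) == length(mins))
  denom <- ifelse(rng == 0, 1, rng)
  out <- (raw - mins) / denom
  out[rng == 0, ] <- 0
  out
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic presence-only MaxEnt dataset
#'
#' Emulates the statistical structure of the estimation setting: raw
#' features drawn i.i.d. uniform and min-max scaled to \[0, 1\]; a planted
#' sparse dual vector `true_w` with `sparsity` nonzero entries of magnitude
#' `signal_scale` and random signs; site probabilities from the Gibbs form
#' over a strictly positive prior (uniform by default); and `l` i.i.d. site
#' draws from that distribution, with the empirical distribution given by
#' relative frequencies. Sampling uses inverse-CDF lookup against the
#' cumulative site probabilities in site order, so a seed reproduces the
#' dataset bitwise.
#'
#' @param m,n feature and site counts.
#' @param sparsity number of planted nonzero coefficients (<= m).
#' @param l number of occurrence samples.
#' @param signal_scale magnitude of the planted coefficients.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @param prior optional strictly positive prior (default uniform).
#' @return object of class `maxent_sim`: list with `features`, `true_w`,
#'   `prior`, `true_p`, `samples` (site indices), `empirical`, `problem` (a
#'   ready [maxent_problem()]), and the generating parameters.
#' @export
generate_synthetic <- function(m = 20, n = 500, sparsity = 3, l = 50000,
                               signal_scale = 2, seed = 1L, prior = NULL) {
  stopifnot(m >= 1, n >= 2, sparsity >= 0, sparsity <= m, l >= 1)
  if (is.null(prior)) prior <- rep(1 / n, n)
  prior <- validate_distribution(prior, n = n, what = "prior")
  if (any(prior <= 0)) stop("prior must be strictly positive", call. = FALSE)
  with_seed(seed, {
    raw <- matrix(stats::runif(m * n), m, n)
    features <- minmax_scale_features(raw)
    true_w <- numeric(m)
    if (sparsity > 0) {
      support <- sample.int(m, sparsity)
      true_w[support] <- signal_scale *
        sample(c(-1, 1), sparsity, replace = TRUE)
    }
    true_p <- gibbs_core(true_w, features$values, log(prior))
    u <- stats::runif(l)
    # guard roundoff at the top of the CDF
    samples <- as.integer(pmin(findInterval(u, cumsum(true_p)) + 1L, n))
    counts <- tabulate(samples, nbins = n)
    empirical <- counts / l
    structure(
      list(features = features, true_w = true_w, prior = prior,
           true_p = true_p, samples = samples, empirical = empirical,
           problem = maxent_problem(features, empirical, prior),
           m = as.integer(m), n = as.integer(n),
           sparsity = as.integer(sparsity), l = as.integer(l),
           signal_scale = signal_scale, seed = as.integer(seed)),
      class = "maxent_sim"
    )
  })
}

#' @export
print.maxent_sim <- function(x, ...) {
  cat(sprintf(
    "<maxent_sim> m = %d, n = %d, sparsity = %d, l = %d, seed = %d\n",
    x$m, x$n, x$sparsity, x$l, x$seed
  ))
  invisible(x)
}
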