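#' MaxEnt estimation problem data
#'
#' Bundles the feature matrix, a strictly positive prior over sites, and the
#' empirical distribution induced by the occurrence samples. The regularized
#' MaxEnt estimate is the minimizer over the simplex of
#' \deqn{D_{KL}(p\|p_{prior}) + t\, H^*\!\big((E_{\hat D}[\Phi] - E_p[\Phi])/t\big),}
#' where the potential \eqn{H^*} is set by the regularizer (see
#' [elastic_net()], [group_lasso()], [linf_reg()]) and \eqn{t > 0} is the
#' regularization hyperparameter. The empirical feature average is cached at
#' construction.
#'
#' @param features a [feature_matrix()].
#' @param empirical probability vector of length n (the empirical
#'   distribution \eqn{\hat D}).
#' @param prior strictly positive probability vector of length n; default
#'   uniform.
#' @return An object of class `maxent_problem` with elements `features`,
#'   `prior`, `empirical`, `empirical_avg`, `prior_avg`, `log_prior`.
#' @examples
#' fm <- feature_matrix(matrix(runif(3 * 10), 3, 10))
#' emp <- prop.table(runif(10))
#' pb <- maxent_problem(fm, emp)
#' all.equal(pb$empirical_avg, model_average(emp, fm))
#' @export
maxent_problem <- function(features, empirical, prior = NULL) {
  stopifnot(is_feature_matrix(features))
  n <- features$n
  if (is.null(prior)) prior <- rep(1 / n, n)
  prior <- validate_distribution(prior, n = n, what = "prior")
  if (any(prior <= 0)) {
    stop("prior must be strictly positive (see floor_prior())", call. = FALSE)
  }
  empirical <- validate_distribution(empirical, n = n, what = "empirical")
  structure(
    list(
      features = features,
      prior = prior,
      empirical = empirical,
      empirical_avg = drop(features$values %*% empirical),
      prior_avg = drop(features$values %*% prior),
      log_prior = log(prior)
    ),
    class = "maxent_problem"
  )
}

is_maxent_problem <- function(x) inherits(x, "maxent_problem")

#' @export
print.maxent_problem <- function(x, ...) {
  cat(sprintf(
    "<maxent_problem> %d features x %d sites; ||A||_op = %.4g; %d sites with empirical mass\n",
    x$features$m, x$features$n, x$features$op_norm, sum(x$empirical > 0)
  ))
  invisible(x)
}
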