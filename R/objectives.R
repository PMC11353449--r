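#' Primal MaxEnt objective
#'
#' \eqn{D_{KL}(p\|p_{prior}) + t H^*((E_{\hat D}[\Phi] - E_p[\Phi])/t)} with
#' the potential of the chosen regularizer. For the elastic net the second
#' term is the quadratic hinge
#' \eqn{\frac{1}{2t(1-\alpha)}\sum_i \max(0, |r_i| - t\alpha)^2}; for the
#' group-lasso and sup-norm models the potential is an indicator, so the
#' value is the KL term when the feature-average residual is feasible and
#' `Inf` otherwise. `feas_tol` gives a relative slack on the indicator
#' constraints (useful when evaluating iterates accepted by the stopping
#' rule, which permits a 1e-5 relative violation); the default 0 is the
#' strict sentinel.
#'
#' @param p probability vector of length n.
#' @param problem a [maxent_problem()].
#' @param reg a regularizer.
#' @param t positive hyperparameter.
#' @param feas_tol relative slack on indicator constraints (default 0).
#' @return scalar objective value (possibly `Inf`).
#' @export
primal_objective <- function(p, problem, reg, t, feas_tol = 0) {
  stopifnot(is_maxent_problem(problem), is_regularizer(reg))
  if (!(is.numeric(t) && length(t) == 1L && t > 0)) {
    stop("t must be a positive scalar", call. = FALSE)
  }
  check_reg_dim(reg, problem$features$m)
  p <- validate_distribution(p, n = problem$features$n)
  kl <- kl_divergence(p, problem$prior)
  r <- problem$empirical_avg - model_average(p, problem$features)
  pen <- switch(reg$kind,
    elastic_net =
      sum(pmax(0, abs(r) - t * reg$alpha)^2) / (2 * t * (1 - reg$alpha)),
    group_lasso = {
      ok <- all(group_norms(r, reg$groups) <=
                  t * reg$group_weights * (1 + feas_tol))
      if (ok) 0 else Inf
    },
    linf = if (sum(abs(r)) <= t * (1 + feas_tol)) 0 else Inf,
    stop("unknown regularizer kind", call. = FALSE)
  )
  kl + pen
}

#' Dual MaxEnt objective
#'
#' \eqn{\langle w, E_{\hat D}[\Phi]\rangle - t H(w) -
#' \log \sum_j p_{prior}(j) e^{\langle w, \Phi(j)\rangle}}, the regularized
#' log-likelihood over the Gibbs family, maximized by the dual solution. The
#' log-partition term is log-sum-exp stabilized. At `w = 0` the value is 0.
#'
#' @param w dual vector of length m.
#' @param problem a [maxent_problem()].
#' @param reg a regularizer.
#' @param t nonnegative hyperparameter.
#' @return scalar dual objective value.
#' @export
dual_objective <- function(w, problem, reg, t) {
  stopifnot(is_maxent_problem(problem), is_regularizer(reg))
  if (!(is.numeric(t) && length(t) == 1L && t >= 0)) {
    stop("t must be a nonnegative scalar", call. = FALSE)
  }
  w <- as.numeric(w)
  if (length(w) != problem$features$m || any(!is.finite(w))) {
    stop("w must be a finite vector of length m", call. = FALSE)
  }
  sum(w * problem$empirical_avg) - t * regularizer_value(w, reg) -
    log_partition(w, problem$features$values, problem$log_prior)
}
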