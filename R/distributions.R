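#' @keywords internal
validate_distribution <- function(p, n = NULL, tol = 1e-12, what = "p") {
  p <- as.numeric(p)
  if (!is.null(n) && length(p) != n) {
    stop(sprintf("%s has length %d, expected %d", what, length(p), n),
         call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    stop(sprintf("%s must be finite and nonnegative", what), call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("%s must sum to 1 (off by %.3g)", what, abs(sum(p) - 1)),
         call. = FALSE)
  }
  p
}

#' Floor and renormalize a prior distribution
#'
#' Priors used in a MaxEnt solve must lie in the interior of the simplex.
#' This optional utility clamps entries below `floor` and renormalizes,
#' emitting a message when any entry was actually floored. It is never
#' applied automatically.
#'
#' @param p nonnegative numeric vector summing to 1.
#' @param floor smallest admissible mass (default 1e-300).
#' @return a strictly positive probability vector.
#' @export
floor_prior <- function(p, floor = 1e-300) {
  p <- validate_distribution(p, what = "prior")
  k <- sum(p < floor)
  if (k > 0) {
    message(sprintf("floor_prior: floored %d entries below %g", k, floor))
    p <- pmax(p, floor)
    p <- p / sum(p)
  }
  p
}

# Stabilized Gibbs core: works from the log-prior, subtracting the max logit
# before exponentiating so ||z|| up to ~1e3 cannot overflow.
gibbs_core <- function(z, values, log_prior) {
  s <- log_prior + drop(crossprod(values, z))
  s <- s - max(s)
  e <- exp(s)
  e / sum(e)
}

# log sum_j prior_j exp(<z, Phi_j>), stabilized
log_partition <- function(z, values, log_prior) {
  s <- log_prior + drop(crossprod(values, z))
  mx <- max(s)
  mx + log(sum(exp(s - mx)))
}

#' Gibbs distribution induced by a dual vector
#'
#' Evaluates \eqn{p(j) \propto p_{prior}(j) \exp\langle z, \Phi(j)\rangle},
#' normalized over sites — the parametric family in which every dual iterate
#' lives. Computation subtracts the max logit before exponentiating, so large
#' dual vectors do not overflow.
#'
#' @param z numeric dual vector of length m (finite).
#' @param problem a [maxent_problem()].
#' @return probability vector of length n. With `z = 0` this is exactly the
#'   prior.
#' @export
gibbs_distribution <- function(z, problem) {
  stopifnot(is_maxent_problem(problem))
  z <- as.numeric(z)
  if (length(z) != problem$features$m) {
    stop("z has wrong length", call. = FALSE)
  }
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  gibbs_core(z, problem$features$values, problem$log_prior)
}

#' Model average of the features
#'
#' The linear operator \eqn{A p = \sum_j p(j) \Phi(j) = E_p[\Phi]}.
#'
#' @param p probability vector of length n.
#' @param features a [feature_matrix()].
#' @return numeric vector of length m.
#' @export
model_average <- function(p, features) {
  stopifnot(is_feature_matrix(features))
  p <- as.numeric(p)
  if (length(p) != features$n) {
    stop("p has wrong length for this feature matrix", call. = FALSE)
  }
  drop(features$values %*% p)
}

#' Kullback-Leibler divergence between site distributions
#'
#' \eqn{D_{KL}(p\|q) = \sum_j p(j)\log(p(j)/q(j))} in nats, with the
#' convention \eqn{0 \log 0 = 0}. Returns `Inf` when some site has
#' \eqn{p(j) > 0} but \eqn{q(j) = 0}.
#'
#' @param p,q probability vectors of equal length.
#' @return nonnegative scalar, zero iff `p == q`.
#' @export
kl_divergence <- function(p, q) {
  p <- validate_distribution(p, what = "p")
  q <- validate_distribution(q, n = length(p), what = "q")
  pos <- p > 0
  if (any(q[pos] == 0)) return(Inf)
  sum(p[pos] * log(p[pos] / q[pos]))
}
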