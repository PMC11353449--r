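#' Group structure for the group-lasso penalty
#'
#' A non-overlapping partition of the m features into G groups. Labels may be
#' arbitrary (character or numeric); groups are indexed in order of first
#' appearance.
#'
#' @param assignment length-m vector of group labels, one per feature.
#' @return An object of class `group_structure` with `assignment` (integer
#'   group index per feature), `labels`, `sizes` (per-group feature counts)
#'   and `G`.
#' @export
group_structure <- function(assignment) {
  if (anyNA(assignment) || length(assignment) < 1L) {
    stop("every feature needs a group label", call. = FALSE)
  }
  labels <- unique(assignment)
  idx <- match(assignment, labels)
  structure(
    list(
      assignment = idx,
      labels = as.character(labels),
      sizes = tabulate(idx, nbins = length(labels)),
      G = length(labels)
    ),
    class = "group_structure"
  )
}

#' Regularizer specifications
#'
#' Each regularizer is a pair (potential \eqn{H^*}, dual penalty \eqn{H}):
#'
#' * `elastic_net(alpha)`: \eqn{H(w) = \alpha\|w\|_1 +
#'   \tfrac{1-\alpha}{2}\|w\|_2^2}; the potential is the quadratic hinge
#'   \eqn{H^*(u) = \tfrac{1}{2(1-\alpha)}\sum_i \max(0, |u_i|-\alpha)^2}.
#'   Smooth potential, so the linear-rate solver applies; its modulus field
#'   `gamma` is \eqn{1-\alpha}.
#' * `group_lasso(groups)`: \eqn{H(w) = \sum_g k_g \|w_g\|_2} with
#'   \eqn{k_g = \sqrt{m_g}} by default (`weighting = "size"` uses the literal
#'   group size \eqn{m_g}); the potential is the indicator of
#'   \eqn{\|u_g\|_2 \le k_g} for all g.
#' * `linf_reg()`: \eqn{H(w) = \|w\|_\infty}; the potential is the indicator
#'   of the unit \eqn{\ell_1} ball.
#'
#' @param alpha elastic-net mixing parameter, strictly between 0 and 1.
#' @param groups a [group_structure()] (or a plain label vector).
#' @param weighting group multiplier convention, `"sqrt"` (default) or
#'   `"size"`.
#' @return an object of class `c("<kind>", "regularizer")`.
#' @name regularizers
NULL

#' @rdname regularizers
#' @export
elastic_net <- function(alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L)
  if (!(alpha > 0 && alpha < 1)) {
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(
    list(kind = "elastic_net", alpha = alpha, gamma = 1 - alpha),
    class = c("elastic_net", "regularizer")
  )
}

#' @rdname regularizers
#' @export
group_lasso <- function(groups, weighting = c("sqrt", "size")) {
  weighting <- match.arg(weighting)
  if (!inherits(groups, "group_structure")) groups <- group_structure(groups)
  k_g <- if (weighting == "sqrt") sqrt(groups$sizes) else groups$sizes
  structure(
    list(kind = "group_lasso", groups = groups, weighting = weighting,
         group_weights = k_g, gamma = 0),
    class = c("group_lasso", "regularizer")
  )
}

#' @rdname regularizers
#' @export
linf_reg <- function() {
  structure(list(kind = "linf", gamma = 0),
            class = c("linf", "regularizer"))
}

is_regularizer <- function(x) inherits(x, "regularizer")

#' @export
print.regularizer <- function(x, ...) {
  extra <- switch(x$kind,
    elastic_net = sprintf(" (alpha = %g)", x$alpha),
    group_lasso = sprintf(" (%d groups, %s weighting)",
                          x$groups$G, x$weighting),
    ""
  )
  cat(sprintf("<regularizer: %s%s>\n", x$kind, extra))
  invisible(x)
}

check_reg_dim <- function(reg, m) {
  if (reg$kind == "group_lasso" && length(reg$groups$assignment) != m) {
    stop(sprintf("group structure covers %d features, problem has %d",
                 length(reg$groups$assignment), m), call. = FALSE)
  }
  invisible(TRUE)
}

# ---- proximal operators ----------------------------------------------------

#' Soft thresholding
#'
#' Componentwise \eqn{\mathrm{sign}(v_i)\max(0, |v_i| - \lambda)}, the
#' proximal operator of \eqn{\lambda\|\cdot\|_1}.
#'
#' @param v numeric vector.
#' @param lam threshold, nonnegative scalar.
#' @export
soft_threshold <- function(v, lam) {
  stopifnot(is.numeric(lam), length(lam) == 1L, lam >= 0)
  sign(v) * pmax(abs(v) - lam, 0)
}

#' Elastic-net proximal operator
#'
#' Minimizer of \eqn{\lambda(\alpha\|w\|_1 + \tfrac{1-\alpha}{2}\|w\|_2^2)
#' + \tfrac12\|w - v\|_2^2}: soft-threshold at \eqn{\lambda\alpha}, then
#' divide by \eqn{1 + \lambda(1-\alpha)}.
#'
#' @inheritParams soft_threshold
#' @param alpha mixing parameter in \[0, 1\].
#' @export
prox_elastic_net <- function(v, lam, alpha) {
  stopifnot(lam >= 0)
  if (!(is.numeric(alpha) && alpha >= 0 && alpha <= 1)) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  soft_threshold(v, lam * alpha) / (1 + lam * (1 - alpha))
}

#' Group-lasso proximal operator (block soft thresholding)
#'
#' Per group g, scales the block by \eqn{\max(0, 1 - \lambda k_g /
#' \|v_g\|_2)}; a block with \eqn{\|v_g\|_2 \le \lambda k_g} (including the
#' zero block) maps to zero.
#'
#' @inheritParams soft_threshold
#' @param groups a [group_structure()].
#' @param group_weights per-group multipliers \eqn{k_g}; default
#'   \eqn{\sqrt{m_g}}.
#' @export
prox_group_lasso <- function(v, lam, groups,
                             group_weights = sqrt(groups$sizes)) {
  stopifnot(inherits(groups, "group_structure"), lam >= 0)
  if (length(v) != length(groups$assignment)) {
    stop("group structure inconsistent with length(v)", call. = FALSE)
  }
  out <- v
  for (g in seq_len(groups$G)) {
    ix <- groups$assignment == g
    nrm <- sqrt(sum(v[ix]^2))
    fac <- if (nrm > 0) max(0, 1 - lam * group_weights[g] / nrm) else 0
    out[ix] <- fac * v[ix]
  }
  out
}

#' Euclidean projection onto the l1 ball
#'
#' Sort-based threshold method: if \eqn{\|v\|_1 \le r} the point is returned
#' unchanged; otherwise the simplex threshold \eqn{\theta} is found from the
#' sorted magnitudes and the result is \eqn{\mathrm{sign}(v)\max(|v|-\theta,
#' 0)}. O(m log m).
#'
#' @param v numeric vector (finite).
#' @param radius positive ball radius.
#' @export
project_l1_ball <- function(v, radius) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0)
  if (any(!is.finite(v))) stop("v must be finite", call. = FALSE)
  a <- abs(v)
  if (sum(a) <= radius) return(v)
  u <- sort(a, decreasing = TRUE)
  css <- cumsum(u)
  k <- seq_along(u)
  rho <- max(k[u > (css - radius) / k])
  theta <- (css[rho] - radius) / rho
  sign(v) * pmax(a - theta, 0)
}

#' Sup-norm proximal operator via Moreau decomposition
#'
#' \eqn{\mathrm{prox}_{\lambda\|\cdot\|_\infty}(v) = v -
#' \Pi_{\|\cdot\|_1 \le \lambda}(v)}; in particular the result is 0 whenever
#' \eqn{\|v\|_1 \le \lambda}.
#'
#' @inheritParams project_l1_ball
#' @param lam positive scalar.
#' @export
prox_linf <- function(v, lam) {
  stopifnot(is.numeric(lam), length(lam) == 1L, lam > 0)
  v - project_l1_ball(v, lam)
}

#' Proximal operator of a regularizer's dual penalty
#'
#' Dispatches to the closed form for \eqn{\mathrm{argmin}_w\, \lambda H(w) +
#' \tfrac12\|w - v\|_2^2} for the given regularizer.
#'
#' @param reg a regularizer (see [regularizers]).
#' @param v numeric vector.
#' @param lam nonnegative prox parameter \eqn{\lambda}.
#' @export
prox_regularizer <- function(reg, v, lam) {
  stopifnot(is_regularizer(reg))
  switch(reg$kind,
    elastic_net = prox_elastic_net(v, lam, reg$alpha),
    group_lasso = prox_group_lasso(v, lam, reg$groups, reg$group_weights),
    linf = if (lam == 0) v else prox_linf(v, lam),
    stop("unknown regularizer kind", call. = FALSE)
  )
}

#' Dual penalty value H(w)
#'
#' @param w numeric dual vector.
#' @param reg a regularizer.
#' @return nonnegative scalar, zero at `w = 0`.
#' @export
regularizer_value <- function(w, reg) {
  stopifnot(is_regularizer(reg))
  check_reg_dim(reg, length(w))
  switch(reg$kind,
    elastic_net = reg$alpha * sum(abs(w)) + (1 - reg$alpha) / 2 * sum(w^2),
    group_lasso = {
      gs <- reg$groups
      s <- 0
      for (g in seq_len(gs$G)) {
        s <- s + reg$group_weights[g] * sqrt(sum(w[gs$assignment == g]^2))
      }
      s
    },
    linf = if (length(w)) max(abs(w)) else 0,
    stop("unknown regularizer kind", call. = FALSE)
  )
}

# ---- path start and stopping rule ------------------------------------------

group_norms <- function(r, gs) {
  vapply(seq_len(gs$G),
         function(g) sqrt(sum(r[gs$assignment == g]^2)), numeric(1))
}

#' Smallest hyperparameter with the trivial solution
#'
#' The path start \eqn{t(0)}: the smallest t at which \eqn{(p_{prior}, 0)}
#' satisfies the model's optimality condition, computed from the residual
#' \eqn{r = E_{\hat D}[\Phi] - E_{p_{prior}}[\Phi]} as
#' \eqn{\|r\|_\infty/\alpha} (elastic net), \eqn{\max_g \|r_g\|_2/k_g}
#' (group lasso), or \eqn{\|r\|_1} (sup-norm model). Returns 0 when the
#' averages coincide.
#'
#' @param problem a [maxent_problem()].
#' @param reg a regularizer.
#' @export
t_max <- function(problem, reg) {
  stopifnot(is_maxent_problem(problem), is_regularizer(reg))
  check_reg_dim(reg, problem$features$m)
  r <- problem$empirical_avg - problem$prior_avg
  switch(reg$kind,
    elastic_net = max(abs(r)) / reg$alpha,
    group_lasso = max(group_norms(r, reg$groups) / reg$group_weights),
    linf = sum(abs(r)),
    stop("unknown regularizer kind", call. = FALSE)
  )
}

# residual value from a precomputed feature-average residual vector;
# shared between optimality_residual() and the solver inner loops
residual_value <- function(r, w, reg, t) {
  switch(reg$kind,
    elastic_net = list(
      residual = max(abs(r - t * (1 - reg$alpha) * w)),
      threshold = t * reg$alpha
    ),
    group_lasso = list(
      residual = max(group_norms(r, reg$groups) / reg$group_weights),
      threshold = t
    ),
    linf = list(residual = sum(abs(r)), threshold = t),
    stop("unknown regularizer kind", call. = FALSE)
  )
}

#' Optimality residual and stopping rule
#'
#' Evaluates the model-specific optimality-condition residual at a
#' primal/dual pair and tests it against the path-fitting stopping rule at
#' tolerance `tol`:
#' \itemize{
#'   \item elastic net: \eqn{\|E_{\hat D}[\Phi]-E_p[\Phi]-t(1-\alpha)w\|_\infty
#'     \le t\alpha(1+tol)};
#'   \item group lasso: \eqn{\max_g \|(E_{\hat D}[\Phi]-E_p[\Phi])_g\|_2/k_g
#'     \le t(1+tol)};
#'   \item sup-norm model: \eqn{\|E_{\hat D}[\Phi]-E_p[\Phi]\|_1 \le t(1+tol)}.
#' }
#'
#' @param p probability vector of length n.
#' @param w dual vector of length m.
#' @param problem a [maxent_problem()].
#' @param reg a regularizer.
#' @param t positive hyperparameter.
#' @param tol stopping slack (default 1e-5).
#' @return list with `residual`, `threshold` (the right-hand side without the
#'   slack), and logical `satisfied`.
#' @export
optimality_residual <- function(p, w, problem, reg, t, tol = 1e-5) {
  stopifnot(is_maxent_problem(problem), is_regularizer(reg), t > 0)
  check_reg_dim(reg, problem$features$m)
  p <- validate_distribution(p, n = problem$features$n)
  r <- problem$empirical_avg - model_average(p, problem$features)
  rv <- residual_value(r, w, reg, t)
  list(
    residual = rv$residual,
    threshold = rv$threshold,
    satisfied = rv$residual <= rv$threshold * (1 + tol)
  )
}
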