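#' Regularization-path hyperparameter schedule
#'
#' The 141-point piecewise-linear schedule used for path fitting:
#' \deqn{t(l) = (1 - l/100)\, t_0 \; (l = 0..50), \qquad
#'       t(l) = (0.5 - (l-50)/200)\, t_0 \; (l = 51..140),}
#' so the grid steps by \eqn{t_0/100} down to \eqn{0.5 t_0} and then by
#' \eqn{t_0/200} down to \eqn{0.05 t_0}.
#'
#' @param t0 positive path start (typically [t_max()]).
#' @return object of class `path_schedule`: a strictly decreasing numeric
#'   vector of length 141 with attribute `t0`.
#' @export
make_schedule <- function(t0) {
  if (!(is.numeric(t0) && length(t0) == 1L && is.finite(t0) && t0 > 0)) {
    stop(paste0("degenerate path: t0 must be a positive number ",
                "(the empirical and prior feature averages coincide?)"),
         call. = FALSE)
  }
  l <- 0:140
  values <- ifelse(l <= 50, (1 - l / 100) * t0, (0.5 - (l - 50) / 200) * t0)
  structure(values, t0 = t0, class = "path_schedule")
}

#' @export
print.path_schedule <- function(x, ...) {
  cat(sprintf("<path_schedule> %d values from %.6g down to %.6g\n",
              length(x), x[1], x[length(x)]))
  invisible(x)
}

#' Fit a warm-started regularization path
#'
#' Solves the MaxEnt problem along the decreasing hyperparameter schedule.
#' The first entry is the exact trivial solution \eqn{(p_{prior}, 0)} at
#' \eqn{t(0) = t_{max}}; each subsequent solve is warm-started by setting
#' both initial vectors \eqn{z_0 = w_0 = w^{(l-1)}}. The linear-rate scheme
#' is used when the regularizer's potential is smooth (`gamma > 0`, i.e. the
#' elastic net), the sublinear scheme otherwise; `solver = "fbs"` forces the
#' forward-backward baseline. Non-converged solves are recorded and flagged,
#' never fatal.
#'
#' @param problem a [maxent_problem()].
#' @param reg a regularizer.
#' @param config a [solver_config()].
#' @param schedule optional [make_schedule()] output; default builds the
#'   141-point schedule at `t_max(problem, reg)`.
#' @param solver `"npdhg"` (default, scheme chosen from the regularizer) or
#'   `"fbs"`.
#' @return object of class `maxent_path`: list with `schedule`, `t0`,
#'   `coefficients` (m x 141 matrix of dual vectors), `p` (n x 141 matrix),
#'   `converged`, `iterations`, `residuals`, `dual_objectives`, `reg`.
#' @export
fit_path <- function(problem, reg, config = solver_config(),
                     schedule = NULL, solver = c("npdhg", "fbs")) {
  stopifnot(is_maxent_problem(problem), is_regularizer(reg))
  solver <- match.arg(solver)
  check_reg_dim(reg, problem$features$m)
  if (is.null(schedule)) schedule <- make_schedule(t_max(problem, reg))
  L <- length(schedule)
  m <- problem$features$m
  n <- problem$features$n

  W <- matrix(0, m, L)
  P <- matrix(0, n, L)
  converged <- logical(L)
  iterations <- integer(L)
  residuals <- numeric(L)
  dobj <- numeric(L)

  # l = 0 entry: the trivial pair, exact by definition of t(0)
  P[, 1] <- problem$prior
  r0 <- optimality_residual(problem$prior, numeric(m), problem, reg,
                            schedule[1], tol = config$tolerance)
  converged[1] <- r0$satisfied
  residuals[1] <- r0$residual
  iterations[1] <- 0L
  dobj[1] <- 0

  w_prev <- numeric(m)
  for (l in 2:L) {
    fit <- if (solver == "fbs") {
      fbs_solve(problem, reg, schedule[l], init_w = w_prev, config = config)
    } else {
      npdhg_solve(problem, reg, schedule[l], init_w = w_prev,
                  init_z = w_prev, config = config)
    }
    if (!fit$converged) {
      warning(sprintf(
        "path point %d (t = %.4g) did not converge in %d iterations",
        l - 1L, schedule[l], fit$iterations))
    }
    W[, l] <- fit$w
    P[, l] <- fit$p
    converged[l] <- fit$converged
    iterations[l] <- fit$iterations
    residuals[l] <- if (length(fit$residual_history))
      fit$residual_history[length(fit$residual_history)] else NA_real_
    dobj[l] <- fit$dual_objective
    w_prev <- fit$w
  }
  rownames(W) <- problem$features$feature_names
  structure(
    list(schedule = schedule, t0 = attr(schedule, "t0"),
         coefficients = W, p = P, converged = converged,
         iterations = iterations, residuals = residuals,
         dual_objectives = dobj, reg = reg, solver = solver),
    class = "maxent_path"
  )
}

#' @export
print.maxent_path <- function(x, ...) {
  cat(sprintf(
    "<maxent_path: %s> %d points from t0 = %.4g; %d converged; final nonzeros %d/%d\n",
    x$reg$kind, length(x$schedule), x$t0, sum(x$converged),
    sum(abs(x$coefficients[, ncol(x$coefficients)]) > 1e-8),
    nrow(x$coefficients)
  ))
  invisible(x)
}

#' Sparsity profile along a fitted path
#'
#' Counts nonzero dual coefficients (|w_i| > `zero_tol`) at each path point,
#' both raw (at that t) and cumulative (ever activated at or before that t),
#' plus per-group first-activation points when the path used a group-lasso
#' regularizer (or when `groups` is supplied).
#'
#' @param result a [fit_path()] result.
#' @param zero_tol magnitude below which a coefficient counts as zero
#'   (default 1e-8).
#' @param groups optional [group_structure()] for group-level reporting.
#' @return list with `t`, `t_ratio` (t/t0), `nonzero` (raw counts),
#'   `cumulative_nonzero`, and (with groups) `group_first_selection`, a
#'   data.frame of per-group first-activation index and t/t0 ratio (NA when
#'   a group never activates).
#' @export
nonzero_profile <- function(result, zero_tol = 1e-8, groups = NULL) {
  stopifnot(inherits(result, "maxent_path"), zero_tol > 0)
  W <- result$coefficients
  active <- abs(W) > zero_tol
  nonzero <- colSums(active)
  ever <- t(apply(active, 1, cummax)) > 0
  out <- list(
    t = as.numeric(result$schedule),
    t_ratio = as.numeric(result$schedule) / result$t0,
    nonzero = as.integer(nonzero),
    cumulative_nonzero = as.integer(colSums(ever))
  )
  if (is.null(groups) && result$reg$kind == "group_lasso") {
    groups <- result$reg$groups
  }
  if (!is.null(groups)) {
    if (!inherits(groups, "group_structure")) groups <- group_structure(groups)
    first_idx <- vapply(seq_len(groups$G), function(g) {
      act <- colSums(active[groups$assignment == g, , drop = FALSE]) > 0
      if (any(act)) which(act)[1] else NA_integer_
    }, integer(1))
    out$group_first_selection <- data.frame(
      group = groups$labels,
      first_index = first_idx,
      t_ratio = out$t_ratio[first_idx]
    )
  }
  out
}
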