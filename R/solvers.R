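#' Solver configuration
#'
#' Collects the tunables shared by the NPDHG schemes and the
#' forward-backward splitting (FBS) baseline. Defaults follow the fitting
#' protocol: \eqn{\theta_0 = 0}, \eqn{\tau_0 = 2},
#' \eqn{\sigma_0 = 1/(2\|A\|_{op}^2)} (so \eqn{\tau_0\sigma_0\|A\|_{op}^2 = 1},
#' the feasibility bound, holds with equality), stopping tolerance 1e-5, and
#' at least 40 iterations before convergence is checked.
#'
#' @param theta0,tau0 initial extrapolation and primal stepsize for the
#'   sublinear scheme.
#' @param sigma0 initial dual stepsize; `NULL` means
#'   \eqn{1/(2\|A\|_{op}^2)}, resolved per problem.
#' @param tolerance relative slack in the stopping rule.
#' @param min_iterations iterations to run before the first convergence check.
#' @param max_iterations iteration cap; hitting it flags the result rather
#'   than erroring.
#' @param check_every how often (in iterations) to test the stopping rule
#'   once past `min_iterations`.
#' @param theta_update `"sqrt"` for the accelerated rule
#'   \eqn{\theta_{k+1} = 1/\sqrt{1+\tau_k}}, `"plain"` for
#'   \eqn{1/(1+\tau_k)}.
#' @param gamma_override optional smoothness modulus for the linear-rate
#'   scheme; default uses the regularizer's own (elastic net:
#'   \eqn{1-\alpha}).
#' @param fbs_step FBS gradient step; `NULL` means \eqn{1/\|A\|_2^2}.
#' @param fbs_momentum `"auto"` picks the strongly-convex momentum for the
#'   elastic net and FISTA otherwise; or force `"fista"` /
#'   `"strongly_convex_q"`.
#' @param seed integer seed for any randomized component (none of the
#'   bundled schemes are randomized; recorded for provenance).
#' @return list of class `solver_config`.
#' @export
solver_config <- function(theta0 = 0, tau0 = 2, sigma0 = NULL,
                          tolerance = 1e-5, min_iterations = 40L,
                          max_iterations = 100000L, check_every = 1L,
                          theta_update = c("sqrt", "plain"),
                          gamma_override = NULL,
                          fbs_step = NULL,
                          fbs_momentum = c("auto", "fista",
                                           "strongly_convex_q"),
                          seed = NULL) {
  theta_update <- match.arg(theta_update)
  fbs_momentum <- match.arg(fbs_momentum)
  stopifnot(tolerance > 0, min_iterations >= 1L, max_iterations >= 1L,
            check_every >= 1L, tau0 > 0)
  structure(
    list(theta0 = theta0, tau0 = tau0, sigma0 = sigma0,
         tolerance = tolerance,
         min_iterations = as.integer(min_iterations),
         max_iterations = as.integer(max_iterations),
         check_every = as.integer(check_every),
         theta_update = theta_update, gamma_override = gamma_override,
         fbs_step = fbs_step, fbs_momentum = fbs_momentum, seed = seed),
    class = "solver_config"
  )
}

#' Linear-rate NPDHG stepsizes
#'
#' For a regularizer whose potential is \eqn{\gamma}-smooth, the constant
#' stepsizes \deqn{\theta = 1 - \frac{t}{2\gamma\|A\|_{op}^2}
#' \left(\sqrt{1 + 4\gamma\|A\|_{op}^2/t} - 1\right),\quad
#' \tau = \frac{1-\theta}{\theta},\quad \sigma = \frac{\gamma\tau}{t}.}
#' Computed in the cancellation-free form \eqn{\theta = (d-1)/(d+1)} with
#' \eqn{d = \sqrt{1+4r}}, \eqn{r = \gamma\|A\|_{op}^2/t}, which is exact for
#' r from 1e-12 up. The triple satisfies \eqn{\tau\sigma\|A\|_{op}^2 =
#' 1/\theta} identically; this is asserted before returning, along with
#' \eqn{0 < \theta < 1}, \eqn{\tau > 0}, \eqn{\sigma > 0}.
#'
#' @param t positive hyperparameter.
#' @param gamma positive smoothness modulus.
#' @param op_norm \eqn{\|A\|_{op} > 0}.
#' @return list with `theta`, `tau`, `sigma`.
#' @export
stepsizes_linear <- function(t, gamma, op_norm) {
  stopifnot(t > 0, gamma > 0, op_norm > 0)
  r <- gamma * op_norm^2 / t
  d <- sqrt(1 + 4 * r)
  theta <- (d - 1) / (d + 1)
  tau <- (1 - theta) / theta
  sigma <- gamma * tau / t
  for (nm in c("theta", "tau", "sigma")) {
    val <- get(nm)
    if (!is.finite(val) || val <= 0) {
      stop(sprintf("stepsizes_linear: %s = %g is not a positive finite number",
                   nm, val), call. = FALSE)
    }
  }
  if (theta >= 1) stop("stepsizes_linear: theta must be < 1", call. = FALSE)
  if (abs(tau * sigma * op_norm^2 * theta - 1) > 1e-8) {
    stop("stepsizes_linear: feasibility identity tau*sigma*||A||op^2 = 1/theta failed",
         call. = FALSE)
  }
  list(theta = theta, tau = tau, sigma = sigma)
}

solve_result <- function(w, p, iterations, residual_history, converged,
                         problem, reg, t, method) {
  structure(
    list(w = w, p = p, iterations = iterations,
         residual_history = residual_history, converged = converged,
         dual_objective = dual_objective(w, problem, reg, t),
         t = t, method = method),
    class = "solve_result"
  )
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf(
    "<solve_result: %s> %s after %d iterations; dual objective %.8g; residual %.3g\n",
    x$method, if (x$converged) "converged" else "NOT converged",
    x$iterations, x$dual_objective,
    if (length(x$residual_history)) tail(x$residual_history, 1) else NA_real_
  ))
  invisible(x)
}

# Shared NPDHG engine. `smooth = FALSE` runs the sublinear scheme with
# accelerating (theta, tau, sigma); `smooth = TRUE` keeps them fixed at the
# linear-rate values. Update order per iteration:
#   z+ = (z + tau (w + theta (w - w_prev))) / (1 + tau)
#   p+ = Gibbs(z+);  w_hat = w + sigma (E_Dhat[Phi] - E_{p+}[Phi])
#   w+ = prox_{t sigma H}(w_hat)
#   then (sublinear only) theta+ = 1/sqrt(1+tau), tau+ = theta+ tau,
#   sigma+ = sigma / theta+.
npdhg_engine <- function(problem, reg, t, init_w, init_z, config, smooth) {
  stopifnot(is_maxent_problem(problem), is_regularizer(reg))
  if (!(is.numeric(t) && length(t) == 1L && t > 0)) {
    stop("t must be a positive scalar", call. = FALSE)
  }
  check_reg_dim(reg, problem$features$m)
  m <- problem$features$m
  values <- problem$features$values
  log_prior <- problem$log_prior
  chat <- problem$empirical_avg
  op <- problem$features$op_norm

  w <- if (is.null(init_w)) numeric(m) else as.numeric(init_w)
  z <- if (is.null(init_z)) w else as.numeric(init_z)
  stopifnot(length(w) == m, length(z) == m)
  if (any(!is.finite(w)) || any(!is.finite(z))) {
    stop("initial vectors must be finite", call. = FALSE)
  }
  w_prev <- w # w_{-1} = w_0

  if (smooth) {
    gamma <- if (is.null(config$gamma_override)) reg$gamma else
      config$gamma_override
    if (!(is.numeric(gamma) && gamma > 0)) {
      stop(paste0("the linear-rate scheme needs a smooth potential ",
                  "(gamma > 0); use npdhg_solve_nonsmooth() for this ",
                  "regularizer"), call. = FALSE)
    }
    st <- stepsizes_linear(t, gamma, op)
    theta <- st$theta; tau <- st$tau; sigma <- st$sigma
  } else {
    theta <- config$theta0
    tau <- config$tau0
    sigma <- if (is.null(config$sigma0)) 1 / (2 * op^2) else config$sigma0
    if (tau * sigma * op^2 > 1 + 1e-12) {
      stop(sprintf(
        "stepsize feasibility violated: tau0*sigma0*||A||op^2 = %g > 1",
        tau * sigma * op^2), call. = FALSE)
    }
  }

  res_hist <- numeric(config$max_iterations)
  converged <- FALSE
  k_done <- config$max_iterations
  p <- gibbs_core(z, values, log_prior)
  for (k in seq_len(config$max_iterations)) {
    z <- (z + tau * (w + theta * (w - w_prev))) / (1 + tau)
    p <- gibbs_core(z, values, log_prior)
    r <- chat - drop(values %*% p)
    w_hat <- w + sigma * r
    w_prev <- w
    w <- prox_regularizer(reg, w_hat, t * sigma)
    if (any(!is.finite(w)) || any(!is.finite(p))) {
      stop(sprintf("non-finite iterate at iteration %d", k), call. = FALSE)
    }
    if (!smooth) {
      theta <- if (config$theta_update == "sqrt") 1 / sqrt(1 + tau) else
        1 / (1 + tau)
      tau <- theta * tau
      sigma <- sigma / theta
    }
    rv <- residual_value(r, w, reg, t)
    res_hist[k] <- rv$residual
    if (k >= config$min_iterations && k %% config$check_every == 0L &&
        rv$residual <= rv$threshold * (1 + config$tolerance)) {
      converged <- TRUE
      k_done <- k
      break
    }
  }
  solve_result(w, p, k_done, res_hist[seq_len(k_done)], converged,
               problem, reg, t,
               method = if (smooth) "npdhg_smooth" else "npdhg_nonsmooth")
}

#' Sublinear-rate NPDHG solver
#'
#' The accelerated nonlinear primal-dual hybrid gradient scheme whose primal
#' proximal step is a KL divergence, so the primal update is a closed-form
#' Gibbs distribution and every iteration costs O(mn). Applies to any of the
#' bundled regularizers; converges at the optimal O(1/eps) rate without
#' smoothness assumptions on the potential.
#'
#' @param problem a [maxent_problem()].
#' @param reg a regularizer.
#' @param t positive hyperparameter.
#' @param init_w,init_z optional warm starts (default zero vectors; path
#'   fitting passes the previous solution for both).
#' @param config a [solver_config()].
#' @return a `solve_result` with elements `w`, `p`, `iterations`,
#'   `residual_history`, `converged`, `dual_objective`.
#' @export
npdhg_solve_nonsmooth <- function(problem, reg, t, init_w = NULL,
                                  init_z = NULL, config = solver_config()) {
  npdhg_engine(problem, reg, t, init_w, init_z, config, smooth = FALSE)
}

#' Linear-rate NPDHG solver for smooth potentials
#'
#' Same update order as [npdhg_solve_nonsmooth()] but with the constant
#' stepsizes of [stepsizes_linear()], valid when the potential is
#' \eqn{\gamma}-smooth (elastic net with \eqn{\alpha < 1}, \eqn{\gamma =
#' 1-\alpha}). Converges at the optimal O(log(1/eps)) rate.
#'
#' @inheritParams npdhg_solve_nonsmooth
#' @export
npdhg_solve_smooth <- function(problem, reg, t, init_w = NULL,
                               init_z = NULL, config = solver_config()) {
  npdhg_engine(problem, reg, t, init_w, init_z, config, smooth = TRUE)
}

#' NPDHG solver, scheme chosen from the regularizer
#'
#' Uses the linear-rate scheme when the regularizer's potential is smooth
#' (`gamma > 0`), the sublinear scheme otherwise.
#'
#' @inheritParams npdhg_solve_nonsmooth
#' @export
npdhg_solve <- function(problem, reg, t, init_w = NULL, init_z = NULL,
                        config = solver_config()) {
  smooth <- !is.null(reg$gamma) && reg$gamma > 0
  npdhg_engine(problem, reg, t, init_w, init_z, config, smooth = smooth)
}

#' Forward-backward splitting baseline on the dual
#'
#' Accelerated proximal gradient ascent on the dual objective: with
#' \eqn{p(w)} the Gibbs distribution of w, iterate
#' \eqn{w^+ = \mathrm{prox}_{\eta t H}(y + \eta(E_{\hat D}[\Phi] -
#' E_{p(y)}[\Phi]))} with FISTA extrapolation, step \eqn{\eta = 1/\|A\|_2^2}
#' by default. For the elastic net the dual is strongly concave and the
#' constant-momentum variant with \eqn{q = (1-\alpha)t/(\|A\|_2^2 +
#' (1-\alpha)t)} is used. Stopping rule identical to the NPDHG solvers. This
#' is the classical baseline whose stepsize needs the expensive
#' \eqn{\|A\|_2}; it exists for cross-validation and benchmarking.
#'
#' @inheritParams npdhg_solve_nonsmooth
#' @param init_w optional warm start (default zero).
#' @export
fbs_solve <- function(problem, reg, t, init_w = NULL,
                      config = solver_config()) {
  stopifnot(is_maxent_problem(problem), is_regularizer(reg))
  if (!(is.numeric(t) && length(t) == 1L && t > 0)) {
    stop("t must be a positive scalar", call. = FALSE)
  }
  check_reg_dim(reg, problem$features$m)
  m <- problem$features$m
  values <- problem$features$values
  log_prior <- problem$log_prior
  chat <- problem$empirical_avg

  eta <- if (is.null(config$fbs_step)) 1 / spectral_norm(problem$features)^2
         else config$fbs_step
  stopifnot(eta > 0)

  momentum <- config$fbs_momentum
  if (momentum == "auto") {
    momentum <- if (reg$kind == "elastic_net") "strongly_convex_q" else
      "fista"
  }
  beta_const <- NA_real_
  if (momentum == "strongly_convex_q") {
    if (reg$kind != "elastic_net") {
      stop("strongly_convex_q momentum requires the elastic net", call. = FALSE)
    }
    L <- 1 / eta
    q <- (1 - reg$alpha) * t / (L + (1 - reg$alpha) * t)
    beta_const <- (1 - sqrt(q)) / (1 + sqrt(q))
  }

  w <- if (is.null(init_w)) numeric(m) else as.numeric(init_w)
  stopifnot(length(w) == m, all(is.finite(w)))
  w_prev <- w
  a <- 1 # FISTA sequence
  d0 <- dual_objective(w, problem, reg, t)

  res_hist <- numeric(config$max_iterations)
  converged <- FALSE
  k_done <- config$max_iterations
  p <- gibbs_core(w, values, log_prior)
  for (k in seq_len(config$max_iterations)) {
    if (momentum == "strongly_convex_q") {
      beta <- beta_const
    } else {
      a_new <- (1 + sqrt(1 + 4 * a^2)) / 2
      beta <- (a - 1) / a_new
      a <- a_new
    }
    y <- w + beta * (w - w_prev)
    py <- gibbs_core(y, values, log_prior)
    grad <- chat - drop(values %*% py) # ascent direction of the smooth part
    w_prev <- w
    w <- prox_regularizer(reg, y + eta * grad, eta * t)
    if (any(!is.finite(w))) {
      stop(sprintf("non-finite FBS iterate at iteration %d", k),
           call. = FALSE)
    }
    p <- gibbs_core(w, values, log_prior)
    r <- chat - drop(values %*% p)
    rv <- residual_value(r, w, reg, t)
    res_hist[k] <- rv$residual
    if (k >= config$min_iterations && k %% config$check_every == 0L) {
      if (rv$residual <= rv$threshold * (1 + config$tolerance)) {
        converged <- TRUE
        k_done <- k
        break
      }
      if (dual_objective(w, problem, reg, t) < d0 - 1e3) {
        stop("FBS diverged (dual objective collapsed); use a smaller fbs_step",
             call. = FALSE)
      }
    }
  }
  solve_result(w, p, k_done, res_hist[seq_len(k_done)], converged,
               problem, reg, t, method = "fbs")
}
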