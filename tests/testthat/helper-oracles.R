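# Independent numeric oracles and small fixture builders. Every oracle here
# deliberately avoids the code path it checks: proxes are recomputed by
# generic 1-D/penalized minimization, the l1 projection by root-finding on
# its Lagrange multiplier, and optimal MaxEnt solutions by BFGS on a
# softmax-parameterized primal with penalty continuation.

random_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

make_sim <- function(m = 6, n = 50, sparsity = 2, l = 10000, seed = 1) {
  generate_synthetic(m = m, n = n, sparsity = sparsity, l = l, seed = seed)
}

# --- prox oracles -----------------------------------------------------------

oracle_soft_threshold <- function(v, lam) {
  vapply(v, function(vi) {
    o <- stats::optimize(function(w) lam * abs(w) + 0.5 * (w - vi)^2,
                         c(-abs(vi) - 1, abs(vi) + 1), tol = 1e-12)
    if (o$objective > lam * 0 + 0.5 * vi^2) 0 else o$minimum
  }, numeric(1))
}

oracle_prox_en <- function(v, lam, alpha) {
  vapply(v, function(vi) {
    f <- function(w) {
      lam * (alpha * abs(w) + (1 - alpha) / 2 * w^2) + 0.5 * (w - vi)^2
    }
    o <- stats::optimize(f, c(-abs(vi) - 1, abs(vi) + 1), tol = 1e-12)
    if (f(0) < o$objective) 0 else o$minimum
  }, numeric(1))
}

# blockwise: the objective is rotation invariant within a block, so the
# minimizer lies on the ray through v_g and the problem reduces to a 1-D
# numeric minimization over the block norm
oracle_prox_gl <- function(v, lam, gs, kg = sqrt(gs$sizes)) {
  out <- v
  for (g in seq_len(gs$G)) {
    ix <- gs$assignment == g
    nv <- sqrt(sum(v[ix]^2))
    if (nv == 0) {
      out[ix] <- 0
      next
    }
    h <- function(rho) lam * kg[g] * rho + 0.5 * (rho - nv)^2
    rho <- stats::optimize(h, c(0, nv + 1), tol = 1e-12)$minimum
    if (h(0) < h(rho)) rho <- 0
    out[ix] <- rho * v[ix] / nv
  }
  out
}

# projection onto {||w||_1 <= r} through its KKT multiplier: the shrinkage
# level theta solves sum_i max(|v_i| - theta, 0) = r, found by root bracketing
oracle_proj_l1 <- function(v, r) {
  if (sum(abs(v)) <= r) return(v)
  g <- function(th) sum(pmax(abs(v) - th, 0)) - r
  th <- stats::uniroot(g, c(0, max(abs(v))), tol = 1e-15)$root
  sign(v) * pmax(abs(v) - th, 0)
}

# epigraph reformulation min over (w, s) of lam*s + 0.5||w - v||^2 subject to
# |w_i| <= s, solved by quadratic-penalty continuation with BFGS
oracle_prox_linf <- function(v, lam) {
  m <- length(v)
  x <- c(numeric(m), max(abs(v)))
  for (K in 10^c(2, 4, 6, 8, 10, 12)) {
    f <- function(x) {
      w <- x[1:m]; s <- x[m + 1]
      lam * s + 0.5 * sum((w - v)^2) +
        K * sum(pmax(0, abs(w) - s)^2) + K * max(0, -s)^2
    }
    g <- function(x) {
      w <- x[1:m]; s <- x[m + 1]
      ex <- pmax(0, abs(w) - s)
      c((w - v) + 2 * K * ex * sign(w),
        lam - 2 * K * sum(ex) - 2 * K * max(0, -s))
    }
    x <- stats::optim(x, f, g, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-16))$par
  }
  x[1:m]
}

# --- generic dense primal minimizer -----------------------------------------

# minimizes the primal over the simplex via softmax parameterization with
# analytic gradients; indicator potentials are handled by quadratic-penalty
# continuation, so the returned point can violate the constraint by O(1/K).
# The l1 norm inside the sup-norm model's constraint is pseudo-Huber
# smoothed (bias <= m*mu, driven to 1e-8) because BFGS stalls on its kinks.
oracle_primal <- function(pb, reg, t) {
  A <- pb$features$values
  chat <- pb$empirical_avg
  q <- pb$prior
  pen <- function(r, K, mu) {
    if (reg$kind == "elastic_net") {
      return(list(
        v = sum(pmax(0, abs(r) - t * reg$alpha)^2) / (2 * t * (1 - reg$alpha)),
        g = sign(r) * pmax(0, abs(r) - t * reg$alpha) / (t * (1 - reg$alpha))
      ))
    }
    if (reg$kind == "linf") {
      sm <- sqrt(r^2 + mu^2)
      ex <- max(0, sum(sm - mu) - t)
      return(list(v = K * ex^2, g = 2 * K * ex * r / sm))
    }
    gs <- reg$groups
    v <- 0
    g <- numeric(length(r))
    for (gg in seq_len(gs$G)) {
      ix <- gs$assignment == gg
      nr <- sqrt(sum(r[ix]^2))
      ex <- max(0, nr - t * reg$group_weights[gg])
      v <- v + K * ex^2
      if (ex > 0 && nr > 0) g[ix] <- 2 * K * ex * r[ix] / nr
    }
    list(v = v, g = g)
  }
  s <- log(q)
  stages <- if (reg$kind == "elastic_net") list(c(1, 0)) else
    list(c(1e2, 1e-3), c(1e4, 1e-4), c(1e6, 1e-5), c(1e8, 1e-6),
         c(1e10, 1e-7), c(1e12, 1e-8))
  for (st in stages) {
    K <- st[1]
    mu <- st[2]
    f <- function(s) {
      p <- exp(s - max(s)); p <- p / sum(p)
      r <- chat - drop(A %*% p)
      sum(p * log(p / q)) + pen(r, K, mu)$v
    }
    g <- function(s) {
      p <- exp(s - max(s)); p <- p / sum(p)
      r <- chat - drop(A %*% p)
      pe <- pen(r, K, mu)
      gp <- log(p / q) + 1 - drop(crossprod(A, pe$g))
      p * (gp - sum(p * gp))
    }
    s <- stats::optim(s, f, g, method = "BFGS",
                      control = list(maxit = 20000, reltol = 1e-16))$par
  }
  p <- exp(s - max(s))
  p / sum(p)
}

# --- protocol solves --------------------------------------------------------

# the standard schedule truncated at a target t (values >= t)
trunc_schedule <- function(t0, t) {
  s <- make_schedule(t0)
  structure(s[s >= t * (1 - 1e-9)], t0 = t0, class = "path_schedule")
}

# warm-started path down to t (the regime the stopping rule is designed
# for), then a long polish solve at t itself for a high-accuracy solution
solve_protocol <- function(pb, reg, t, solver = c("npdhg", "fbs"),
                           polish_iters = 3000) {
  solver <- match.arg(solver)
  sch <- trunc_schedule(t_max(pb, reg), t)
  pa <- fit_path(pb, reg, schedule = sch, solver = solver)
  w <- pa$coefficients[, length(sch)]
  cfg <- solver_config(min_iterations = polish_iters,
                       max_iterations = max(50000, polish_iters))
  if (solver == "fbs") {
    fbs_solve(pb, reg, t, init_w = w, config = cfg)
  } else {
    npdhg_solve(pb, reg, t, init_w = w, init_z = w, config = cfg)
  }
}
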