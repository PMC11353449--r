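test_that("gibbs_distribution matches direct evaluation and is stable", {
  fm <- feature_matrix(matrix(c(0, 1), 1, 2))
  pb <- maxent_problem(fm, empirical = c(0.5, 0.5), prior = c(0.5, 0.5))

  # z = 0 reproduces the prior exactly
  expect_identical(gibbs_distribution(0, pb), pb$prior)

  # hand-derived: weights (1, 3) / 4
  expect_equal(gibbs_distribution(log(3), pb), c(0.25, 0.75), tolerance = 1e-14)

  # adding a constant feature shifts every logit equally: p unchanged
  set.seed(41)
  fm2 <- feature_matrix(matrix(runif(3 * 6), 3, 6))
  fm3 <- feature_matrix(rbind(fm2$values, 1))
  pr <- random_simplex(6)
  pb2 <- maxent_problem(fm2, empirical = random_simplex(6), prior = pr)
  pb3 <- maxent_problem(fm3, empirical = pb2$empirical, prior = pr)
  z <- rnorm(3)
  expect_equal(gibbs_distribution(z, pb2), gibbs_distribution(c(z, 7.3), pb3),
               tolerance = 1e-13)

  # log-sum-exp stabilization: huge dual vectors stay finite and normalized
  big <- gibbs_distribution(1000, pb)
  expect_true(all(is.finite(big)))
  expect_equal(sum(big), 1, tolerance = 1e-12)

  expect_error(gibbs_distribution(NaN, pb), "finite")
  expect_error(maxent_problem(fm, c(0.5, 0.5), prior = c(0, 1)),
               "strictly positive")
})

test_that("model_average matches a brute-force double loop", {
  fm <- feature_matrix(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(model_average(c(1, 0), fm), c(1, 0)) # point mass -> column
  expect_equal(model_average(c(0.5, 0.5), fm), c(0.5, 0.5))

  set.seed(7)
  for (rep in 1:20) {
    fm <- feature_matrix(matrix(rnorm(3 * 5), 3, 5))
    p <- random_simplex(5)
    brute <- numeric(3)
    for (i in 1:3) for (j in 1:5) brute[i] <- brute[i] + p[j] * fm$values[i, j]
    expect_equal(model_average(p, fm), brute, tolerance = 1e-12)
  }
  expect_error(model_average(c(0.5, 0.5, 0), fm), "length")
})

test_that("kl_divergence handles conventions and matches direct summation", {
  p <- random_simplex(4)
  expect_identical(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-14)
  expect_identical(kl_divergence(c(1, 0), c(0, 1)), Inf)

  set.seed(8)
  for (rep in 1:20) {
    p <- random_simplex(4)
    p[sample.int(4, 1)] <- 0 # exercise 0 log 0
    p <- p / sum(p)
    q <- random_simplex(4)
    direct <- sum(ifelse(p > 0, p * log(p / q), 0))
    expect_equal(kl_divergence(p, q), direct, tolerance = 1e-12)
  }
})

test_that("operator norm is the exact max column norm", {
  expect_equal(operator_norm(feature_matrix(diag(2))), 1)
  expect_equal(operator_norm(feature_matrix(matrix(c(3, 4, 1, 0), 2, 2))), 5)
})

test_that("spectral_norm matches a dense SVD and dominates the op norm", {
  fm <- feature_matrix(cbind(diag(c(2, 1)), c(0, 0)))
  expect_equal(spectral_norm(fm), 2, tolerance = 1e-9)

  set.seed(9)
  for (rep in 1:20) {
    fm <- feature_matrix(matrix(rnorm(4 * 6), 4, 6))
    expect_equal(spectral_norm(fm, tol = 1e-12), svd(fm$values)$d[1],
                 tolerance = 1e-8)
  }
  for (rep in 1:100) {
    m <- sample(2:6, 1); n <- sample(2:8, 1)
    fm <- feature_matrix(matrix(rnorm(m * n), m, n))
    expect_lte(operator_norm(fm), spectral_norm(fm) * (1 + 1e-9))
  }
})

test_that("Pinsker's inequality holds on random pairs", {
  set.seed(10)
  for (rep in 1:200) {
    n <- sample(2:50, 1)
    p <- random_simplex(n)
    q <- random_simplex(n)
    expect_gte(kl_divergence(p, q), 0.5 * sum(abs(p - q))^2 - 1e-12)
  }
})

test_that("primal and dual objectives match direct formula evaluation", {
  set.seed(11)
  fm <- feature_matrix(matrix(runif(3 * 4), 3, 4))
  pr <- random_simplex(4)
  # matched averages at the prior: both objective terms vanish
  pb0 <- maxent_problem(fm, empirical = pr, prior = pr)
  for (reg in list(elastic_net(0.5), group_lasso(c(1, 1, 2)), linf_reg())) {
    expect_equal(primal_objective(pr, pb0, reg, t = 1), 0)
    expect_equal(dual_objective(numeric(3), pb0, reg, t = 1), 0,
                 tolerance = 1e-14)
  }

  pb <- maxent_problem(fm, empirical = random_simplex(4), prior = pr)
  reg <- elastic_net(0.3)
  t <- 0.2
  # hinge inactive when every residual entry is below t*alpha
  t_big <- max(abs(pb$empirical_avg - pb$prior_avg)) / reg$alpha * 1.5
  expect_equal(primal_objective(pb$prior, pb, reg, t_big),
               kl_divergence(pb$prior, pb$prior))

  for (rep in 1:20) {
    p <- random_simplex(4)
    r <- pb$empirical_avg - drop(fm$values %*% p)
    direct <- sum(p * log(p / pr)) +
      sum(pmax(0, abs(r) - t * reg$alpha)^2) / (2 * t * (1 - reg$alpha))
    expect_equal(primal_objective(p, pb, reg, t), direct, tolerance = 1e-12)

    w <- rnorm(3)
    H <- reg$alpha * sum(abs(w)) + (1 - reg$alpha) / 2 * sum(w^2)
    direct_d <- sum(w * pb$empirical_avg) - t * H -
      log(sum(pr * exp(drop(crossprod(fm$values, w)))))
    expect_equal(dual_objective(w, pb, reg, t), direct_d, tolerance = 1e-12)
  }

  # indicator potentials return the +Inf sentinel when infeasible
  expect_identical(
    primal_objective(pb$prior, pb, linf_reg(),
                     t = sum(abs(pb$empirical_avg - pb$prior_avg)) / 2),
    Inf
  )
})

test_that("primal and dual values meet at a converged solution", {
  sim <- make_sim(m = 5, n = 30, seed = 12)
  pb <- sim$problem
  reg <- elastic_net(0.4)
  t <- 0.4 * t_max(pb, reg)
  fit <- solve_protocol(pb, reg, t)
  gap <- primal_objective(fit$p, pb, reg, t) - fit$dual_objective
  expect_lt(abs(gap), 1e-5)
})
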