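test_that("soft_threshold matches examples and 1-D minimization", {
  v <- c(2.0, -1.2, 0.3)
  expect_identical(soft_threshold(v, 0), v)
  expect_equal(soft_threshold(0.3, 0.5), 0)
  expect_equal(soft_threshold(c(2.0, -1.2), 0.5), c(1.5, -0.7))
  set.seed(20)
  for (rep in 1:25) {
    v <- rnorm(5) * 2
    lam <- runif(1, 0, 2)
    expect_equal(soft_threshold(v, lam), oracle_soft_threshold(v, lam),
                 tolerance = 1e-7)
  }
  expect_error(soft_threshold(1, -0.1))
})

test_that("prox_elastic_net shrinks then scales", {
  v <- c(2, -0.4, 1)
  expect_equal(prox_elastic_net(v, 0.7, 1), soft_threshold(v, 0.7))
  expect_equal(prox_elastic_net(2, 1, 0), 1) # pure ridge: 2 / (1 + 1)
  expect_equal(prox_elastic_net(2, 1, 0.5), 1) # shrink(2, .5) / 1.5
  set.seed(21)
  for (rep in 1:25) {
    v <- rnorm(5) * 2
    lam <- runif(1, 0, 2)
    alpha <- runif(1)
    expect_equal(prox_elastic_net(v, lam, alpha),
                 oracle_prox_en(v, lam, alpha), tolerance = 1e-7)
  }
  expect_error(prox_elastic_net(1, 1, 1.2), "alpha")
})

test_that("prox_group_lasso block-thresholds per group", {
  gs <- group_structure(c(1, 1, 1, 1, 2, 2))
  v <- c(3, 4, 0, 0, 0.5, 0.5)
  out <- prox_group_lasso(v, 1, gs)
  expect_equal(out[1:4], c(1.8, 2.4, 0, 0)) # factor 1 - 2/5 on ||.|| = 5
  expect_equal(out[5:6], c(0, 0)) # ||v_g|| < lam * sqrt(2): dead zone
  expect_identical(prox_group_lasso(v, 0, gs), v)
  # zero block maps to zero even at the boundary
  expect_equal(prox_group_lasso(c(0, 0, 0, 0, 1, 1), 1, gs)[1:4], rep(0, 4))
  set.seed(22)
  gs2 <- group_structure(rep(1:3, c(2, 3, 3)))
  for (rep in 1:25) {
    v <- rnorm(8) * 2
    lam <- runif(1, 0, 1.5)
    expect_equal(prox_group_lasso(v, lam, gs2),
                 oracle_prox_gl(v, lam, gs2), tolerance = 1e-7)
  }
  expect_error(prox_group_lasso(1:3, 1, gs), "inconsistent")
})

test_that("project_l1_ball is the Euclidean projection", {
  expect_identical(project_l1_ball(c(0.5, -0.5), 2), c(0.5, -0.5))
  expect_equal(project_l1_ball(c(3, 1), 2), c(2, 0))
  set.seed(23)
  for (rep in 1:30) {
    v <- rnorm(6) * 2
    r <- runif(1, 0.2, 3)
    w <- project_l1_ball(v, r)
    expect_equal(w, oracle_proj_l1(v, r), tolerance = 1e-8)
    expect_lte(sum(abs(w)), r + 1e-12)
  }
  # no random feasible point is closer to v than the projection
  v <- rnorm(6) * 3
  r <- 1.5
  w <- project_l1_ball(v, r)
  d0 <- sum((w - v)^2)
  for (rep in 1:1000) {
    cand <- rnorm(6)
    cand <- cand / sum(abs(cand)) * runif(1) * r
    expect_gte(sum((cand - v)^2), d0 - 1e-12)
  }
  expect_error(project_l1_ball(c(1, NA), 1), "finite")
})

test_that("prox_linf satisfies the Moreau decomposition", {
  expect_equal(prox_linf(c(0.5, -0.5), 2), c(0, 0)) # inside the l1 ball
  expect_equal(prox_linf(c(3, 1), 2), c(1, 1))
  set.seed(24)
  for (rep in 1:50) {
    v <- rnorm(5) * 2
    lam <- runif(1, 0.1, 3)
    expect_equal(prox_linf(v, lam) + project_l1_ball(v, lam), v,
                 tolerance = 1e-12)
  }
  expect_error(prox_linf(c(1, 2), 0))
})

test_that("all prox operators are firmly nonexpansive", {
  set.seed(25)
  gs <- group_structure(rep(1:2, c(3, 3)))
  proxes <- list(
    function(v) soft_threshold(v, 0.7),
    function(v) prox_elastic_net(v, 0.9, 0.4),
    function(v) prox_group_lasso(v, 0.6, gs),
    function(v) project_l1_ball(v, 1.3),
    function(v) prox_linf(v, 0.8)
  )
  for (rep in 1:100) {
    x <- rnorm(6) * 3
    y <- rnorm(6) * 3
    for (pr in proxes) {
      expect_lte(sqrt(sum((pr(x) - pr(y))^2)),
                 sqrt(sum((x - y)^2)) + 1e-12)
    }
  }
})

test_that("regularizer_value evaluates each penalty", {
  expect_equal(regularizer_value(c(0, 0), elastic_net(0.5)), 0)
  expect_equal(regularizer_value(c(1, -1), elastic_net(0.5)), 1.5)
  expect_equal(regularizer_value(c(1, -3), linf_reg()), 3)
  gs <- group_structure(c(1, 1, 2))
  expect_equal(regularizer_value(c(3, 4, -2), group_lasso(gs)),
               sqrt(2) * 5 + 2)
  expect_equal(
    regularizer_value(c(3, 4, -2), group_lasso(gs, weighting = "size")),
    2 * 5 + 2
  )
})

test_that("t_max implements each path-start formula", {
  # residual E_Dhat[Phi] - E_prior[Phi] = (0.2, -0.4) by construction
  fm <- feature_matrix(matrix(c(0.4, -0.8, 0, 0), 2, 2))
  pb <- maxent_problem(fm, empirical = c(1, 0))
  expect_equal(pb$empirical_avg - pb$prior_avg, c(0.2, -0.4))
  expect_equal(t_max(pb, elastic_net(0.5)), 0.8) # 0.4 / 0.5
  expect_equal(t_max(pb, linf_reg()), 0.6) # l1 norm
  expect_equal(t_max(pb, group_lasso(c(1, 2))), 0.4)
  expect_equal(t_max(pb, group_lasso(c(1, 1))),
               sqrt(0.2^2 + 0.4^2) / sqrt(2))
  # degenerate path: matched averages
  pb0 <- maxent_problem(fm, empirical = c(0.5, 0.5))
  expect_equal(t_max(pb0, elastic_net(0.5)), 0)
})

test_that("optimality_residual encodes the stopping rules", {
  sim <- make_sim(m = 5, n = 20, seed = 26)
  pb <- sim$problem
  for (reg in list(elastic_net(0.6), group_lasso(rep(1:2, c(2, 3)))
                   , linf_reg())) {
    t0 <- t_max(pb, reg)
    m <- pb$features$m
    at_t0 <- optimality_residual(pb$prior, numeric(m), pb, reg, t0)
    expect_true(at_t0$satisfied)
    expect_equal(at_t0$residual, at_t0$threshold, tolerance = 1e-12)
    above <- optimality_residual(pb$prior, numeric(m), pb, reg, 1.5 * t0)
    expect_true(above$satisfied)
    expect_lt(above$residual, above$threshold)
  }
  # converged elastic-net solve passes; a perturbed w does not (alpha small
  # enough that a unit shift in one coordinate moves the residual by
  # t(1-alpha) > 2 t alpha, guaranteeing a violation)
  reg <- elastic_net(0.15)
  t <- 0.5 * t_max(pb, reg)
  fit <- solve_protocol(pb, reg, t)
  expect_true(optimality_residual(fit$p, fit$w, pb, reg, t)$satisfied)
  w_bad <- fit$w
  w_bad[1] <- w_bad[1] + 1
  expect_false(optimality_residual(fit$p, w_bad, pb, reg, t)$satisfied)
})
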