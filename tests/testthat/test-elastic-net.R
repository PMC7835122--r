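test_that("config validation rejects bad hyperparameters", {
  expect_error(enet_config(mix = 1.2), "mix")
  expect_error(enet_config(penalty = -1), "penalty")
  expect_error(enet_config(tolerance = 0), "tolerance")
})

test_that("overwhelming penalty shrinks weights and intercept to zero", {
  set.seed(31)
  x <- matrix(rnorm(40), 10, 4)
  y <- rep(c(1, -1), 5)
  fit <- enet_fit(x, y, enet_config(penalty = 1e6))
  expect_true(all(abs(fit$weights) < 1e-8))
  expect_lt(abs(fit$intercept), 1e-6)   # balanced classes: log-odds 0
})

test_that("a perfectly separable two-point problem stays finite", {
  x <- matrix(c(-1, 1), 2, 1)
  y <- c(-1, 1)
  fit <- enet_fit(x, y, enet_config())   # penalty defaults to 1/n
  expect_true(all(is.finite(fit$weights)))
  expect_true(is.finite(fit$objective))
  expect_true(fit$converged)
})

test_that("ridge fits match a quasi-Newton oracle to 1e-6", {
  set.seed(32)
  x <- matrix(rnorm(30), 10, 3)
  y <- sample(rep(c(-1, 1), 5))
  lam <- 0.1
  cfg <- enet_config(mix = 0, penalty = lam, standardize = FALSE,
                     tolerance = 1e-12, max_iterations = 20000)
  fit <- enet_fit(x, y, cfg)
  # alpha = 0 makes the objective smooth; BFGS is an independent route
  oracle <- optim(rep(0, 4), function(th) {
    enet_objective(x, y, th[1:3], th[4], mix = 0, penalty = lam)
  }, method = "BFGS", control = list(maxit = 5000, reltol = 1e-14))
  ours <- enet_objective(x, y, fit$weights, fit$intercept, 0, lam)
  expect_lt(abs(ours - oracle$value), 1e-6)
})

test_that("fits agree with glmnet's coordinate-descent solution", {
  set.seed(36)
  n <- 30; p <- 5
  x <- matrix(rnorm(n * p), n, p)
  y <- sample(rep(c(-1, 1), n / 2))
  for (alpha in c(0, 0.5, 1)) {
    lam <- 0.05
    fit <- enet_fit(x, y, enet_config(mix = alpha, penalty = lam,
                                      standardize = FALSE,
                                      tolerance = 1e-12,
                                      max_iterations = 50000))
    g <- glmnet::glmnet(x, factor(y), family = "binomial", alpha = alpha,
                        lambda = lam, standardize = FALSE,
                        thresh = 1e-14, maxit = 1e6)
    obj_ours <- enet_objective(x, y, fit$weights, fit$intercept, alpha,
                               lam)
    obj_glmnet <- enet_objective(x, y, as.vector(g$beta), g$a0, alpha,
                                 lam)
    expect_lt(abs(obj_ours - obj_glmnet), 1e-5)
  }
})

test_that("the objective is non-increasing across iterations", {
  set.seed(33)
  for (i in 1:5) {
    x <- matrix(rnorm(16 * 6), 16, 6)
    y <- sample(rep(c(-1, 1), 8))
    fit <- enet_fit(x, y, enet_config(mix = runif(1)))
    expect_true(all(diff(fit$objective_path) <= 1e-12))
  }
})

test_that("lasso on a single standardized feature matches grid search", {
  set.seed(34)
  n <- 40
  x <- matrix(rnorm(n), n, 1)
  x <- (x - mean(x)) / sd(x)
  y <- ifelse(x + rnorm(n, sd = 0.5) > 0, 1, -1)
  lam <- 0.05
  fit <- enet_fit(x, y, enet_config(mix = 1, penalty = lam,
                                    standardize = FALSE,
                                    tolerance = 1e-12,
                                    max_iterations = 20000))
  # dense 2-d grid over (weight, intercept) as an independent oracle
  ws <- seq(-3, 3, by = 0.002)
  obj_w <- vapply(ws, function(wv) {
    bs <- seq(-1, 1, by = 0.02)
    min(vapply(bs, function(bv) {
      enet_objective(x, y, wv, bv, 1, lam)
    }, numeric(1)))
  }, numeric(1))
  w_grid <- ws[which.min(obj_w)]
  expect_lt(abs(fit$weights - w_grid), 1e-2)
  expect_lte(fit$objective, min(obj_w) + 1e-4)
})

test_that("fit errors on degenerate inputs", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(enet_fit(x, rep(1, 5), enet_config()), "single-class")
  expect_error(enet_fit(x, c(1, -1, 1, -1, 2), enet_config()), "-1/\\+1")
  x[2, 1] <- NA
  expect_error(enet_fit(x, rep(c(1, -1), c(3, 2)), enet_config()),
               "finite")
})

test_that("decisions follow the score > 0.5 rule with ties negative", {
  fit <- structure(list(weights = c(0, 0), intercept = 0,
                        center = c(0, 0), scale = c(1, 1)),
                   class = "enet_fit")
  dec <- enet_decide(fit, matrix(rnorm(10), 5, 2))
  expect_true(all(dec$score == 0.5))
  expect_true(all(!dec$positive))

  fit$weights <- c(2, 0)
  x0 <- matrix(c(0, 0.5, 1, 0, 0, 0), 3, 2)
  dec2 <- enet_decide(fit, x0)
  expect_true(all(diff(dec2$score) > 0))  # monotone in the weighted feature

  expect_error(enet_decide(fit, matrix(0, 2, 3)), "dimensionality")
})

test_that("standardization makes decisions invariant to feature scaling", {
  set.seed(35)
  x <- matrix(rnorm(20 * 4), 20, 4)
  y <- sample(rep(c(-1, 1), 10))
  scales <- c(100, 0.01, 5, 1)
  x_scaled <- sweep(x, 2, scales, "*")
  cfg <- enet_config(standardize = TRUE, tolerance = 1e-10)
  d1 <- enet_decide(enet_fit(x, y, cfg), x)
  d2 <- enet_decide(enet_fit(x_scaled, y, cfg), x_scaled)
  expect_equal(d1$score, d2$score, tolerance = 1e-6)
  expect_identical(d1$positive, d2$positive)
})

test_that("zero-variance features at tiny n get unit scale, not NaN", {
  # the n = 2 case: one positive, one negative, constant features present
  x <- matrix(c(1, 1, 0, 2), 2, 2)
  fit <- enet_fit(x, c(1, -1), enet_config())
  expect_true(all(is.finite(fit$weights)))
  expect_equal(fit$scale[1], 1)
})
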