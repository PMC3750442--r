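test_that("beta conditional matches adaptive quadrature on random instances", {
  set.seed(202)
  for (i in 1:60) {
    spec <- mu_prior_spec(runif(1, 0.5, 0.9999),
                          b = runif(1, 0.001, 0.1),
                          l = runif(1, 0.5, 3))
    mu_t <- rnorm(1, 0, 0.8)
    tau <- runif(1, 0.02, 0.6)
    mix <- trunc_mixture(mu_t, tau, spec)
    oracle <- quad_beta_posterior(mu_t, tau, spec)
    expect_equal(mixture_mean(mix), oracle$mean, tolerance = 1e-6)
    expect_equal(mixture_prob_slab(mix), oracle$p_slab, tolerance = 1e-6)
    expect_equal(sum(mix$weights), 1, tolerance = 1e-12)
  }
})

test_that("symmetric likelihood gives equal slab weights; flat likelihood recovers the prior masses", {
  spec <- mu_prior_spec(0.99, 0.01, 1)
  mix <- trunc_mixture(0, 0.3, spec)
  expect_equal(mix$weights[2], mix$weights[3], tolerance = 1e-14)
  # sigma2 -> Inf: weights converge to (p0, (1-p0)/2, (1-p0)/2)
  flat <- trunc_mixture(0, 1e6, spec)
  expect_equal(flat$weights,
               c(spec$p0, (1 - spec$p0) / 2, (1 - spec$p0) / 2),
               tolerance = 1e-6)
})

test_that("weights stay normalized far in the tails (no underflow to all-zero)", {
  spec <- mu_prior_spec(0.999, 0.01, 1)
  for (mu_t in c(50, 500, 1000, -1000)) {
    mix <- trunc_mixture(mu_t, 1, spec)   # |mu_tilde| up to 1000 tau
    expect_false(anyNA(mix$weights))
    expect_equal(sum(mix$weights), 1, tolerance = 1e-12)
    # mass concentrates on the slab nearest the likelihood
    expect_gt(mix$weights[if (mu_t > 0) 3 else 2], 0.99)
  }
})

test_that("mixture draws honor weights, support and analytic mean", {
  spec <- mu_prior_spec(0.8, 0.2, 2)
  mix <- trunc_mixture(0.4, 0.5, spec)
  set.seed(55)
  x <- sample_trunc_mixture(mix, 2e4)
  expect_true(all(abs(x) <= spec$l))
  # component frequencies within 3 sigma of weights
  in_spike <- mean(abs(x) < spec$b)
  expect_lt(abs(in_spike - mix$weights[1]),
            3 * sqrt(mix$weights[1] * (1 - mix$weights[1]) / 2e4))
  expect_lt(abs(mean(x) - mixture_mean(mix)), 3 * sd(x) / sqrt(2e4))
  # degenerate weights: all draws confined to the spike
  deg <- mix
  deg$weights <- c(1, 0, 0)
  xd <- sample_trunc_mixture(deg, 500)
  expect_true(all(abs(xd) < spec$b))
})

test_that("intercept conditional reduces to OLS in the flat-prior limit", {
  set.seed(8)
  n <- 25
  X <- matrix(rnorm(n * 3), n)
  y <- rnorm(n, 2)
  state <- list(alpha = 5, beta = rep(0, 3), sigma2 = 1.3, u = numeric(0))
  fc <- full_conditional_alpha(state, X, y, c = 1e12)
  expect_equal(fc$mean, mean(y), tolerance = 1e-9)
  expect_equal(fc$var, 1.3 / n, tolerance = 1e-9)
  # exact conjugate form at finite c
  fc2 <- full_conditional_alpha(state, X, y, c = 2)
  v <- 1 / (n / 1.3 + 1 / 2)
  expect_equal(fc2$var, v)
  expect_equal(fc2$mean, v * sum(y) / 1.3)
  expect_equal(full_conditional_alpha(list(alpha = 0, beta = rep(0, 3),
                                           sigma2 = 1, u = numeric(0)),
                                      X, rep(0, n))$mean, 0)
})

test_that("family-effect conditional shrinks correctly", {
  set.seed(9)
  n <- 12
  X <- matrix(rnorm(n * 2), n)
  y <- rnorm(n)
  fam <- family_map(rep(1:3, each = 4))
  state <- list(alpha = 0, beta = c(0.2, -0.1), sigma2 = 0.8,
                u = c(0.1, -0.2, 0.3), sigma2_u = 0.5)
  fc <- full_conditional_u(2, state, X, y, fam)
  members <- fam$family_of == 2
  e <- y - as.vector(X %*% state$beta) - state$u[fam$family_of]
  rsum <- sum(e[members]) + 4 * state$u[2]
  v <- 1 / (4 / 0.8 + 1 / 0.5)
  expect_equal(fc$var, v)
  expect_equal(fc$mean, v * rsum / 0.8)
  # sigma2_u -> 0: complete shrinkage
  state$sigma2_u <- 1e-12
  fc0 <- full_conditional_u(2, state, X, y, fam)
  expect_lt(abs(fc0$mean), 1e-6)
  expect_lt(fc0$var, 1e-11)
  expect_error(full_conditional_u(1, list(alpha = 0, beta = c(0, 0),
                                          sigma2 = 1, u = numeric(0)),
                                  X, y, NULL), "not enabled")
})

test_that("variance conditional has the conjugate inverse-gamma form", {
  set.seed(10)
  n <- 18
  X <- matrix(rnorm(n * 2), n)
  state <- list(alpha = 0.5, beta = c(0.3, 0), sigma2 = 1, u = numeric(0))
  y <- rnorm(n)
  fc <- full_conditional_sigma2(state, X, y, s = 0.01, r = 0.01)
  sse <- sum((y - 0.5 - X %*% c(0.3, 0))^2)
  expect_equal(fc$shape, 0.01 + n / 2)
  expect_equal(fc$rate, 0.01 + sse / 2)
  # posterior mean rate/(shape-1) against 1-D quadrature of the IG density
  ig_mean <- integrate(function(v) {
    v * exp(fc$shape * log(fc$rate) - lgamma(fc$shape) -
              (fc$shape + 1) * log(v) - fc$rate / v)
  }, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(fc$rate / (fc$shape - 1), ig_mean, tolerance = 1e-8)
  # prior-only mode r/(s+1) = 1/101 for s = r = 0.01
  expect_equal((0.01) / (0.01 + 1), 1 / 101)
})

test_that("full_conditional_beta agrees with the partial-residual definition", {
  set.seed(12)
  n <- 30
  X <- matrix(rnorm(n * 4), n)
  y <- rnorm(n)
  spec <- mu_prior_spec(0.9, 0.05, 1.5)
  state <- list(alpha = 0.2, beta = c(0.1, -0.3, 0, 0.05), sigma2 = 0.7,
                u = numeric(0))
  mix <- full_conditional_beta(2, state, X, y, spec)
  r <- y - state$alpha - X[, -2] %*% state$beta[-2]
  expect_equal(mix$mu_tilde, sum(X[, 2] * r) / sum(X[, 2]^2))
  expect_equal(mix$tau, sqrt(0.7 / sum(X[, 2]^2)))
  Xz <- X; Xz[, 3] <- 0
  expect_error(full_conditional_beta(3, state, Xz, y, spec), "degenerate")
})
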