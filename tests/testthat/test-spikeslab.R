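test_that("the smoothed prior precision interpolates X'X with its diagonal", {
  # orthonormal columns scaled so X'X is the identity
  set.seed(20)
  n <- 12
  q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  om <- smoothed_prior_precision(q, g = 1, w = 0.5)
  expect_equal(om, diag(4) / n, tolerance = 1e-12)

  x <- matrix(rnorm(n * 3), n, 3)
  expect_equal(smoothed_prior_precision(x, g = 1, w = 1),
               crossprod(x) / n, tolerance = 1e-12)

  # duplicated columns: smoothing restores positive definiteness
  xd <- cbind(x, x)
  om_d <- smoothed_prior_precision(xd, w = 0.5)
  expect_gt(min(eigen(om_d, symmetric = TRUE, only.values = TRUE)$values),
            0)
  expect_error(smoothed_prior_precision(cbind(x, 0)), "positive norm")
})

test_that("the null-model log marginal matches the direct formula", {
  set.seed(21)
  x <- matrix(rnorm(15 * 4), 15, 4)
  y <- rnorm(15)
  prior <- spike_slab_prior(x, y, k = 1)
  n <- 15
  a0 <- prior$nu / 2
  b0 <- prior$ss / 2
  direct <- -n / 2 * log(2 * pi) + a0 * log(b0) - lgamma(a0) +
    lgamma(a0 + n / 2) - (a0 + n / 2) * log(b0 + sum(y^2) / 2) +
    sum(log(1 - prior$pi))
  expect_equal(log_marginal(rep(0, 4), x, y, prior), direct,
               tolerance = 1e-12)
})

test_that("duplicated predictors are exchangeable in the log marginal", {
  set.seed(22)
  x1 <- matrix(rnorm(20 * 2), 20, 2)
  x <- cbind(x1, x1[, 1])
  y <- rnorm(20)
  prior <- spike_slab_prior(x, y, k = 1)
  expect_equal(log_marginal(c(1, 0, 0), x, y, prior),
               log_marginal(c(0, 0, 1), x, y, prior), tolerance = 1e-10)
})

test_that("log marginal agrees with brute-force quadrature at small p", {
  skip_if_not_installed("pracma")
  set.seed(7)
  n <- 10; p <- 3
  x <- matrix(rnorm(n * p), n, p)
  y <- drop(x %*% c(0.8, -0.5, 0)) + rnorm(n, 0, 0.5)
  prior <- spike_slab_prior(x, y, k = 1)
  for (g in list(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))) {
    cf <- log_marginal(g, x, y, prior)
    qd <- quad_log_marginal(g, x, y, prior)
    expect_lt(abs(cf - qd) / abs(cf), 1e-6)
  }
})

test_that("the Gibbs chain is seeded-deterministic", {
  pb <- toy_problem(15, 5, seed = 23)
  d1 <- gibbs_sample(pb$x, pb$y, n_iterations = 300, burn_in = 50,
                     seed = 3, init = "null")
  d2 <- gibbs_sample(pb$x, pb$y, n_iterations = 300, burn_in = 50,
                     seed = 3, init = "null")
  expect_identical(d1$gamma_draws, d2$gamma_draws)
  expect_identical(d1$beta_draws, d2$beta_draws)
  d3 <- gibbs_sample(pb$x, pb$y, n_iterations = 300, burn_in = 50,
                     seed = 4, init = "null")
  expect_false(identical(d1$gamma_draws, d3$gamma_draws))
})

test_that("draw dimensions and the support/coefficient coupling hold", {
  pb <- toy_problem(15, 5, seed = 24)
  dr <- gibbs_sample(pb$x, pb$y, n_iterations = 400, burn_in = 100,
                     seed = 1, init = "null")
  expect_equal(dim(dr$gamma_draws), c(300L, 5L))
  expect_equal(dim(dr$beta_draws), c(300L, 5L))
  expect_true(all(dr$beta_draws[dr$gamma_draws == 0] == 0))
  expect_true(all(dr$sigma2_draws > 0))
})

test_that("in the prior-dominant limit, inclusion reverts to the prior", {
  # a dominating slab precision (huge g) pins every coefficient at zero,
  # making all model marginals equal; the posterior inclusion then equals
  # the Bernoulli prior pi = k/p
  set.seed(25)
  n <- 25; p <- 6
  x <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  prior <- spike_slab_prior(scale(x, scale = FALSE), y - mean(y),
                            k = p * 0.9, g = 1e10)
  dr <- gibbs_sample(x, y, prior = prior, n_iterations = 6000,
                     burn_in = 1000, seed = 2, init = "null")
  ip <- inclusion_from_draws(dr)
  expect_lt(max(abs(ip - 0.9)), 0.07)
})

test_that("inclusion probabilities are draw-frequency tallies", {
  draws <- structure(list(
    gamma_draws = rbind(c(1L, 0L), c(1L, 0L), c(0L, 0L), c(1L, 1L)),
    beta_draws = rbind(c(0.5, 0), c(-1, 0), c(0, 0), c(2, 0.1)),
    taxon_ids = c("a", "b")), class = "posterior_draws")
  expect_equal(unname(inclusion_from_draws(draws)), c(3 / 4, 1 / 4))
  draws$beta_draws[, 2] <- 0
  expect_equal(unname(inclusion_from_draws(draws))[2], 0)
})

test_that("equally informative duplicated predictors share inclusion", {
  set.seed(26)
  n <- 30
  x1 <- rnorm(n)
  x <- cbind(x1, x1, matrix(rnorm(n * 3), n, 3))
  y <- 2 * x1 + rnorm(n, 0, 0.5)
  dr <- gibbs_sample(x, y, n_iterations = 20000, burn_in = 2000,
                     seed = 5, init = "null")
  ip <- inclusion_from_draws(dr)
  expect_lt(abs(ip[1] - ip[2]), 0.03)
})

test_that("conditional coefficient draws have the conjugate moments", {
  # near-certain inclusion (k close to p) pins gamma to the full model,
  # where beta | sigma2 ~ N(btilde, sigma2 * V) in closed form
  set.seed(27)
  n <- 40
  x <- qr.Q(qr(matrix(rnorm(n * 2), n, 2))) * sqrt(n)
  y <- drop(x %*% c(1, -0.5)) + rnorm(n, 0, 0.4)
  xc <- scale(x, scale = FALSE)
  yc <- y - mean(y)
  prior <- spike_slab_prior(xc, yc, k = 1.999)
  dr <- gibbs_sample(x, y, prior = prior, n_iterations = 30000,
                     burn_in = 2000, seed = 6, init = c(1, 2))
  keep <- rowSums(dr$gamma_draws) == 2
  expect_gt(mean(keep), 0.9)
  vinv <- crossprod(xc) + prior$Omega
  btilde <- drop(solve(vinv, crossprod(xc, yc)))
  bd <- dr$beta_draws[keep, ]
  expect_equal(unname(colMeans(bd)), btilde, tolerance = 0.02)
  # spread: Var(beta_j) ~ E[sigma2] * V_jj over the kept draws
  vhat <- mean(dr$sigma2_draws[keep]) * diag(solve(vinv))
  expect_equal(unname(apply(bd, 2, var)), vhat, tolerance = 0.1)
})

test_that("running means of the model size settle within default chains", {
  tab <- generate_counts(preset_profile("fungal-like", seed = 28))
  d <- build_design(filter_zero(tab))
  ds <- simulate_dataset(d, scenario(sparsity = 0.04, snr = 4.6,
                                     seed = 29), 1)
  dr <- gibbs_sample(ds$x, ds$y, n_iterations = 4000, burn_in = 400,
                     seed = 7, init = "null")
  expect_lt(running_mean_drift(dr), 0.05)
})

test_that("a single-point k grid reproduces the default ensemble", {
  pb <- toy_problem(20, 6, seed = 30)
  bm <- bmac_select_k(pb$x, pb$y, k_grid = 1, folds = 3,
                      n_iterations = 600, burn_in = 100,
                      cv_iterations = 200, cv_burn_in = 50, seed = 3,
                      init = "null")
  expect_equal(bm$k, 1)
  direct <- gibbs_sample(pb$x, pb$y,
                         prior = spike_slab_prior(
                           scale(pb$x, scale = FALSE),
                           pb$y - mean(pb$y), k = 1),
                         n_iterations = 600, burn_in = 100, seed = 3,
                         init = integer(0))
  expect_identical(bm$draws$gamma_draws, direct$gamma_draws)
})

test_that("the cross-validated size achieves the minimum CV error", {
  pb <- toy_problem(24, 8, nonzero = c(2, -2, 1.5), seed = 31)
  bm <- bmac_select_k(pb$x, pb$y, k_grid = c(1, 3, 6), folds = 3,
                      n_iterations = 600, burn_in = 100,
                      cv_iterations = 300, cv_burn_in = 50, seed = 4,
                      init = "null")
  expect_equal(unname(bm$cv_mse[as.character(bm$k)]), min(bm$cv_mse))
})
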