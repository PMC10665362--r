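test_that("weight conditional solves the normal equations", {
  set.seed(4)
  N <- 20; L <- 3; D <- 3
  Z <- cbind(runif(N), runif(N), 1)
  W_true <- matrix(rnorm(L * D), L, D)
  X <- Z %*% t(W_true) + 0.1 * matrix(rnorm(N * L), N, L)
  s2x <- rep(0.01, L); s2w <- rep(4, L)
  cp <- weight_conditional_params(X, Z, s2x, s2w)
  for (l in 1:L) {
    lhs <- (crossprod(Z) / s2x[l] + diag(1 / s2w[l], D)) %*% cp$mean[l, ]
    rhs <- crossprod(Z, X[, l]) / s2x[l]
    expect_equal(drop(lhs), drop(rhs), tolerance = 1e-10)
  }
})

test_that("weight conditional approaches ordinary least squares", {
  set.seed(5)
  N <- 50; D <- 3
  Z <- cbind(runif(N), runif(N), 1)
  w_true <- c(1, -2, 0.5)
  x <- drop(Z %*% w_true) + 0.05 * rnorm(N)
  cp <- weight_conditional_params(cbind(x), Z, sigma2_x = 0.0025,
                                  sigma2_w = 1e8)
  ols <- drop(solve(crossprod(Z), crossprod(Z, x)))
  expect_equal(drop(cp$mean), ols, tolerance = 1e-5)
})

test_that("variance conditional shapes and rates are the conjugate forms", {
  set.seed(6)
  N <- 12; L <- 2; D <- 3
  Z <- cbind(runif(N), runif(N), 1)
  W <- matrix(rnorm(L * D), L, D)
  X <- Z %*% t(W) + matrix(rnorm(N * L), N, L)
  cp <- variance_conditional_params(X, Z, W, a_x = 0.5, b_x = 1,
                                    a_w = 100, b_w = 1000)
  expect_equal(cp$shape_x, rep(0.5 + N / 2, L))
  rss <- colSums((X - Z %*% t(W))^2)
  expect_equal(cp$rate_x, 1 + rss / 2)
  expect_equal(cp$shape_w, rep(100 + D / 2, L))
  expect_equal(cp$rate_w, 1000 + rowSums(W^2) / 2)
  compat <- variance_conditional_params(X, Z, W, 0.5, 1, 100, 1000,
                                        compat_printed_shape = TRUE)
  expect_equal(compat$shape_x, rep(0.5 + 2 / N, L))
})

test_that("Gibbs draws follow their exact conditionals on a tiny instance", {
  # 3 samples, 1 feature: compare 2e4 draws against the closed-form
  # conditional with a Kolmogorov-Smirnov test
  set.seed(7)
  Z <- cbind(c(0.2, 0.5, 0.9), c(0.1, 0.3, 0.05), 1)
  w_true <- c(1.5, -0.8, 0.3)
  x <- drop(Z %*% w_true) + 0.2 * rnorm(3)
  s2x <- 0.04; s2w <- 9
  nrep <- 2e4
  draws <- t(replicate(nrep,
                       drop(gibbs_update_weights(cbind(x), Z, s2x, s2w))))
  cp <- weight_conditional_params(cbind(x), Z, s2x, s2w)
  Sigma <- solve(cp$precision[[1]])
  for (d in 1:3) {
    ks <- suppressWarnings(
      ks.test(draws[, d], "pnorm", cp$mean[1, d], sqrt(Sigma[d, d])))
    expect_lt(unname(ks$statistic), 0.05)
  }
  # variance draws against the Gamma conditional
  W <- matrix(w_true, 1, 3)
  vd <- replicate(nrep,
                  gibbs_update_variances(cbind(x), Z, W, 0.5, 1, 100,
                                         1000)$sigma2_x)
  cpv <- variance_conditional_params(cbind(x), Z, W, 0.5, 1, 100, 1000)
  ks <- suppressWarnings(
    ks.test(1 / vd, "pgamma", cpv$shape_x, rate = cpv$rate_x))
  expect_lt(unname(ks$statistic), 0.05)
  # conditional precision mean equals shape/rate analytically
  expect_equal(mean(1 / vd), unname(cpv$shape_x / cpv$rate_x),
               tolerance = 0.05)
})

test_that("prior-only hierarchy sampling recovers the prior summary", {
  summ <- structure(list(
    mu_mean = matrix(c(0.05, 0.5, 4, 1, 0.45, 4.5), 3, 2,
                     dimnames = abfew:::dn_phik()),
    mu_sd = matrix(0.05, 3, 2, dimnames = abfew:::dn_phik()),
    lam_shape = matrix(50, 3, 2, dimnames = abfew:::dn_phik()),
    lam_rate = matrix(1, 3, 2, dimnames = abfew:::dn_phik())),
    class = "hyper_summary")
  d <- mcmc_update_theta_hyper(NULL, summ, obs = NULL,
                               mcmc = mcmc_config(2, 500, 2000, seed = 3))
  mu_hat <- colMeans(d$mu)
  expect_true(all(abs(mu_hat - as.vector(summ$mu_mean)) <
                    pmax(3 * apply(d$mu, 2, sd) / sqrt(200), 0.02)))
  lam_hat <- colMeans(1 / d$sigma2)
  expect_equal(unname(lam_hat), rep(50, 6), tolerance = 0.15)
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(8)
  chain <- rep(1:2, each = 500)
  good <- rnorm(1000)
  expect_lt(split_rhat(good, chain), 1.05)
  bad <- c(rnorm(500), rnorm(500, 3))
  expect_gt(split_rhat(bad, chain), 1.5)
})

test_that("effective sample size reflects autocorrelation", {
  set.seed(9)
  chain <- rep(1, 2000)
  iid <- rnorm(2000)
  expect_gt(ess_basic(iid, chain), 1000)
  ar <- as.numeric(arima.sim(list(ar = 0.95), 2000))
  expect_lt(ess_basic(ar, chain), ess_basic(iid, chain) / 5)
})
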