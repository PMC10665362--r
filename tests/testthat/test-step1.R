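test_that("least squares recovers noiseless parameters up to the zero anchor", {
  # the initializer includes a zero pseudo-observation at t = 0 per
  # sample; z(0) = alpha * plogis(-gamma) > 0, so recovery is exact only
  # up to that small documented bias
  true <- logistic_params(alpha = 0.9, beta = 0.5, gamma = 4.8)
  ages <- rep(seq(2, 18, by = 2), each = 3)
  y <- logistic_accumulation(true, ages)
  ds <- ab_dataset(id = sprintf("s%02d", seq_along(ages)),
                   type = rep("AD", length(ages)), age = ages, y = y,
                   X = NULL)
  # WT side is absent -> must use the fallback copied from the AD fit
  ds_wt <- ab_dataset(id = c(ds$id, "w1", "w2", "w3"),
                      type = c(ds$type, rep("WT", 3)),
                      age = c(ds$age, 8, 12, 16),
                      y = c(ds$y, 0, 0, 0))
  init <- least_squares_init(ds_wt)
  expect_equal(unname(init$m["alpha", "AD"]), 0.9, tolerance = 0.02)
  expect_equal(unname(init$m["beta", "AD"]), 0.5, tolerance = 0.04)
  expect_equal(unname(init$m["gamma", "AD"]), 4.8, tolerance = 0.03)
  expect_true(init$fallback_used["WT"])
  expect_false(init$fallback_used["AD"])
  expect_equal(unname(init$m["beta", "WT"]),
               unname(init$m["beta", "AD"]))
  expect_equal(unname(init$m["alpha", "WT"]), 0.05)
})

test_that("noisy near-zero data are declared degenerate, not fitted", {
  set.seed(10)
  ages <- rep(c(4, 8, 12, 16), each = 5)
  ds <- ab_dataset(id = sprintf("s%02d", 1:40),
                   type = rep(c("AD", "WT"), each = 20),
                   age = rep(ages, 2),
                   y = c(logistic_accumulation(logistic_params(1, 0.45, 4.5),
                                               ages) + 0.05 * rnorm(20),
                         0.05 * rnorm(20)))
  init <- least_squares_init(ds)
  expect_true(init$fallback_used["WT"])
})

test_that("hyper-posterior summarization moment-matches exactly", {
  set.seed(11)
  mu_draws <- matrix(rnorm(600, mean = rep(1:6, each = 100),
                           sd = rep(0.1 * (1:6), each = 100)),
                     100, 6, byrow = FALSE)
  s2_draws <- matrix(rgamma(600, 4, 8), 100, 6)
  summ <- summarize_hyperposterior(list(mu = mu_draws,
                                        sigma2 = s2_draws))
  expect_equal(as.vector(summ$mu_mean), colMeans(mu_draws))
  expect_equal(as.vector(summ$mu_sd), apply(mu_draws, 2, sd))
  lam <- 1 / s2_draws
  m <- colMeans(lam); v <- apply(lam, 2, var)
  expect_equal(as.vector(summ$lam_shape), m^2 / v)
  expect_equal(as.vector(summ$lam_rate), m / v)
  # the Gamma summary preserves mean and variance of the precision
  expect_equal(as.vector(summ$lam_shape / summ$lam_rate), m)
  expect_equal(as.vector(summ$lam_shape / summ$lam_rate^2), v)
})

test_that("step-1 pre-training runs and returns a usable summary", {
  st <- small_study()
  pre <- suppressWarnings(step1_pretrain(st$dataset,
                                         mcmc = mcmc_config(2, 300, 300,
                                                            seed = 2)))
  expect_s3_class(pre, "ab_pretrain")
  expect_s3_class(pre$summary, "hyper_summary")
  expect_equal(nrow(pre$diagnostics), 12L)
  expect_true(all(is.finite(pre$summary$mu_mean)))
  expect_true(all(pre$summary$lam_shape > 0))
  # AD maximum should land in a plausible band around the truth (1.0)
  expect_gt(pre$summary$mu_mean["alpha", "AD"], 0.5)
  expect_lt(pre$summary$mu_mean["alpha", "AD"], 1.5)
  expect_output(print(pre), "pre-training")
})

test_that("step 1 requires Abeta data for both types", {
  ds <- ab_dataset(id = c("a1", "a2", "a3"), type = rep("AD", 3),
                   age = c(4, 8, 12), y = c(0.1, 0.4, 0.8))
  expect_error(step1_pretrain(ds), "both types")
})
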