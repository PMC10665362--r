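test_that("step-2 training returns a complete fit object", {
  fit <- small_fit()
  st <- small_study()
  expect_s3_class(fit, "abm_fit")
  expect_equal(fit$L, 4L)
  expect_equal(fit$D, 3L)
  expect_equal(length(fit$ids), st$dataset$N_X)
  expect_equal(ncol(fit$draws$W), fit$L * fit$D)
  expect_equal(ncol(fit$draws$theta), 3L * length(fit$ids))
  expect_output(print(fit), "accumulation-emission")
  co <- coef(fit)
  expect_equal(dim(co$W), c(4L, 3L))
})

test_that("the default speed scaling follows the summary means", {
  fit <- small_fit()
  s <- small_summary()
  expect_equal(fit$C, 4 / (s$mu_mean["beta", "AD"] *
                             s$mu_mean["alpha", "AD"]))
})

test_that("dropping the derivative yields the two-column model", {
  st <- small_study()
  fit2 <- suppressWarnings(
    step2_train(st$dataset, small_summary(),
                mcmc = mcmc_config(1, 100, 100, seed = 5),
                include_derivative = FALSE))
  expect_equal(fit2$D, 2L)
  expect_equal(ncol(fit2$draws$W), 2L * fit2$L)
  expect_equal(dim(posterior_mean_W(fit2)), c(fit2$L, 2L))
})

test_that("step 2 requires biomarker-bearing samples", {
  ds <- ab_dataset(id = c("a1", "a2"), type = c("AD", "WT"),
                   age = c(8, 8), y = c(0.4, 0))
  expect_error(step2_train(ds, small_summary()), "biomarker")
})

test_that("fit serialization round trips bit-exactly", {
  fit <- small_fit()
  f <- tempfile(fileext = ".csv")
  write_fit(fit, f)
  back <- read_fit(f)
  expect_identical(back$draws$W, fit$draws$W)
  expect_identical(back$draws$mu, fit$draws$mu)
  expect_identical(back$draws$theta, fit$draws$theta)
  expect_equal(back$C, fit$C)
  expect_equal(back$summary$mu_mean, fit$summary$mu_mean)
  # predictions from the reloaded fit are identical
  x_star <- small_study()$dataset$X[small_study()$dataset$S_XY[1], ]
  p1 <- predict_abeta(x_star, fit, max_draws = 100, seed = 3)
  p2 <- predict_abeta(x_star, back, max_draws = 100, seed = 3)
  expect_identical(p1$yhat, p2$yhat)
  unlink(c(f, paste0(f, ".meta")))
})

test_that("reruns with the same seed reproduce the draws exactly", {
  st <- small_study()
  a <- suppressWarnings(step2_train(st$dataset, small_summary(),
                                    mcmc = mcmc_config(1, 100, 100,
                                                       seed = 7)))
  b <- suppressWarnings(step2_train(st$dataset, small_summary(),
                                    mcmc = mcmc_config(1, 100, 100,
                                                       seed = 7)))
  expect_identical(a$draws$W, b$draws$W)
  expect_identical(a$draws$theta, b$draws$theta)
  c_ <- suppressWarnings(step2_train(st$dataset, small_summary(),
                                     mcmc = mcmc_config(1, 100, 100,
                                                        seed = 8)))
  expect_false(identical(a$draws$W, c_$draws$W))
})

test_that("hyper summaries serialize to CSV and back exactly", {
  s <- small_summary()
  f <- tempfile(fileext = ".csv")
  write_hyper_summary(s, f)
  back <- read_hyper_summary(f)
  expect_identical(back$mu_mean, s$mu_mean)
  expect_identical(back$lam_rate, s$lam_rate)
  unlink(f)
})
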