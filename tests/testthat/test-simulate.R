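test_that("default cohort has the documented composition", {
  st <- acc_study()
  ds <- st$dataset
  expect_equal(ds$N_y, 140L)
  expect_equal(ds$N_X, 200L)
  expect_equal(length(ds$S_XY), 100L)
  expect_equal(ds$L, 11L)
  expect_equal(sum(ds$type == "WT"), 120L)
  expect_equal(sum(ds$type == "AD"), 120L)
  expect_true(all(ds$age %in% seq(4, 16, by = 2)))
})

test_that("cohort generation is seed-deterministic", {
  d <- cohort_design(n_abeta_only = c(WT = 3, AD = 3),
                     n_biomarker_only = c(WT = 3, AD = 3),
                     n_paired = c(WT = 3, AD = 3), L = 3)
  a <- generate_synthetic_study(d, truth_config(), seed = 5)
  b <- generate_synthetic_study(d, truth_config(), seed = 5)
  c_ <- generate_synthetic_study(d, truth_config(), seed = 6)
  expect_identical(a$dataset$y, b$dataset$y)
  expect_identical(a$dataset$X, b$dataset$X)
  expect_identical(a$truth$theta, b$truth$theta)
  expect_false(identical(a$dataset$X, c_$dataset$X))
})

test_that("ground truth is exactly consistent with noiseless emission", {
  st <- small_study()
  tr <- st$truth
  ds <- st$dataset
  # recompute z from stored theta and compare with stored z
  z <- tr$theta[, "alpha"] *
    plogis(tr$theta[, "beta"] * ds$age - tr$theta[, "gamma"])
  expect_equal(unname(z), unname(tr$z), tolerance = 1e-12)
  # zero-noise simulation reproduces z and W zvec exactly
  p <- logistic_params(1, 0.5, 5)
  obs <- obs_params(W = matrix(c(1, -1, 2, 0.5, 0, 3), 2, 3,
                               byrow = TRUE),
                    sigma2_x = c(1, 1), sigma2_w = c(1, 1), C = 4)
  sim <- simulate_observations(p, 8, obs, sigma_y = 0, sigma2_x = c(0, 0))
  expect_equal(sim$y, logistic_accumulation(p, 8), tolerance = 1e-14)
  expect_equal(sim$x, drop(obs$W %*% latent_vector(p, 8, obs)),
               tolerance = 1e-14)
})

test_that("every true weight row loads on the latent process", {
  st <- acc_study()
  W <- st$truth$obs$W
  expect_true(all(apply(abs(W[, 1:2, drop = FALSE]), 1, max) >= 0.5))
})

test_that("fixture cohort mirrors the motivating study composition", {
  st <- memo("fixture_study", generate_fixture_study(seed = 7))
  ds <- st$dataset
  abeta_only <- setdiff(ds$S_y, ds$S_XY)
  marker_only <- setdiff(ds$S_X, ds$S_XY)
  expect_equal(length(abeta_only), 24L)
  expect_equal(length(marker_only), 82L)
  expect_equal(length(ds$S_XY), 18L)
  expect_true(all(ds$type[c(abeta_only, ds$S_XY)] == "AD"))
  expect_equal(sum(ds$type[marker_only] == "WT"), 41L)
  # features are standardized to population mean 0, sd 1
  Xobs <- ds$X[ds$S_X, ]
  expect_equal(unname(colMeans(Xobs)), rep(0, ds$L), tolerance = 1e-10)
  popsd <- sqrt(colMeans(sweep(Xobs, 2, colMeans(Xobs))^2))
  expect_equal(unname(popsd), rep(1, ds$L), tolerance = 1e-10)
  # the co-transformed truth still reproduces the emitted means:
  # residuals x - W zvec should have sd comparable to the scaled noise
  tr <- st$truth
  Z <- cbind(tr$z, tr$obs$C * tr$zp, 1)[ds$S_X, ]
  resid <- Xobs - Z %*% t(tr$obs$W)
  expect_equal(unname(apply(resid, 2, sd)),
               unname(sqrt(tr$obs$sigma2_x)), tolerance = 0.35)
})
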