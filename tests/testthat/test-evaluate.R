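# reduced-cost CV used across these tests
small_cv <- function() memo("small_cv", {
  cross_validate(small_study()$dataset, small_summary(), scheme = 4,
                 mcmc = mcmc_config(1, 150, 150, seed = 3), seed = 3,
                 max_draws = 150)
})

test_that("cross-validation folds partition the paired set", {
  cv <- small_cv()
  ds <- small_study()$dataset
  expect_equal(sort(names(cv$folds)), sort(ds$id[ds$S_XY]))
  expect_equal(sort(unique(cv$folds)), 1:4)
  expect_equal(nrow(cv$samples), length(ds$S_XY))
  expect_equal(cv$mse, mean(cv$samples$sq_err))
  expect_error(cross_validate(ds, small_summary(), scheme = 1), "fold")
  expect_error(cross_validate(ds, small_summary(), scheme = 1000),
               "fold")
})

test_that("the full-label supervised-ratio run reproduces plain CV", {
  sr <- supervised_ratio_experiment(
    small_study()$dataset, small_summary(), fractions = 1, repeats = 3,
    scheme = 4, mcmc = mcmc_config(1, 150, 150, seed = 3), seed = 3,
    max_draws = 150)
  expect_equal(nrow(sr$results), 1L)  # fraction 1 is deterministic
  expect_identical(sr$results$mse, small_cv()$mse)
  expect_identical(sr$cv[[1]]$samples$yhat, small_cv()$samples$yhat)
})

test_that("masking labels changes training but keeps the fold design", {
  sr <- supervised_ratio_experiment(
    small_study()$dataset, small_summary(), fractions = c(1, 0.5),
    repeats = 2, scheme = 4, mcmc = mcmc_config(1, 150, 150, seed = 3),
    seed = 3, max_draws = 150)
  expect_equal(nrow(sr$results), 3L)
  expect_identical(sr$cv[[1]]$folds, sr$cv[[2]]$folds)
  expect_false(identical(sr$cv[[1]]$samples$yhat,
                         sr$cv[[2]]$samples$yhat))
})

test_that("stratified performance aggregates errors coherently", {
  cv <- small_cv()
  by_age <- stratified_performance(cv, "age")
  expect_equal(sum(by_age$n), nrow(cv$samples))
  expect_equal(sum(by_age$n * by_age$mse) / sum(by_age$n), cv$mse,
               tolerance = 1e-12)
  expect_true(all(by_age$presence_accuracy >= 0 &
                    by_age$presence_accuracy <= 1))
  by_type <- stratified_performance(cv, "type")
  expect_true(all(by_type$stratum %in% c("WT", "AD")))
  by_thr <- stratified_performance(cv, "threshold", threshold = 0.66)
  expect_equal(sum(by_thr$n), nrow(cv$samples))
})

test_that("presence calls follow the documented rule exactly", {
  fake <- structure(list(samples = data.frame(
    id = c("a", "b", "c", "d"), type = c("AD", "AD", "WT", "WT"),
    age = c(8, 8, 8, 8), y = c(0.5, 0.2, 0, 0),
    yhat = c(0.4, 0.04, 0.02, 0.3),
    p_AD = c(0.9, 0.4, 0.1, 0.6), fold = 1,
    abs_err = 0, sq_err = 0)), class = "ab_cv")
  fake$samples$abs_err <- abs(fake$samples$yhat - fake$samples$y)
  fake$samples$sq_err <- fake$samples$abs_err^2
  out <- stratified_performance(fake, "age", presence_eps = 0.05)
  # calls: 0.4 -> AD (correct), 0.04 -> WT (wrong), 0.02 -> WT (correct),
  # 0.3 -> AD (wrong) => accuracy 0.5
  expect_equal(out$presence_accuracy, 0.5)
})

test_that("feature importance validates its inputs", {
  ds <- small_study()$dataset
  expect_error(feature_importance(
    ab_dataset(ds$id, ds$type, ds$age, ds$y, ds$X[, 1, drop = FALSE]),
    small_summary()), "L >= 2")
  expect_error(feature_importance(ds, small_summary(),
                                  mode = "random_subsets", R = 1), "R")
})

test_that("the incremental curve ends at the full-feature error", {
  imp <- feature_importance(small_study()$dataset, small_summary(),
                            mode = "incremental", scheme = 4,
                            mcmc = mcmc_config(1, 150, 150, seed = 3),
                            seed = 3, max_draws = 150)
  expect_length(imp$curve, 4L)
  # using all features reproduces the plain CV error exactly
  expect_identical(unname(imp$curve[4]), small_cv()$mse)
  expect_equal(sort(imp$ranking), 1:4)
})

test_that("multiple-testing correction matches the step-down oracle", {
  # Holm on (0.01, 0.04, 0.03): 0.03, 0.06, 0.06
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), method = "holm"),
               c(0.03, 0.06, 0.06))
  imp <- feature_importance(small_study()$dataset, small_summary(),
                            mode = "random_subsets", scheme = 3,
                            mcmc = mcmc_config(1, 100, 100, seed = 3),
                            seed = 3, R = 2, sizes = c(2, 3),
                            max_draws = 100)
  expect_true(all(imp$tests$p_holm >= imp$tests$p, na.rm = TRUE))
  expect_equal(imp$tests$p_holm,
               p.adjust(imp$tests$p, method = "holm"))
})
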