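# Shared helpers for the test suite. Expensive shared objects are built
# lazily and cached for the duration of one test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# a tiny hand-built dataset: 2 paired, 1 abeta-only, 1 biomarker-only
tiny_dataset <- function(L = 2) {
  X <- rbind(c(0.3, -0.1), c(-0.2, 0.5), c(NA, NA), c(1.0, 0.2))[, seq_len(L), drop = FALSE]
  ab_dataset(id = c("p1", "p2", "a1", "b1"),
             type = c("AD", "WT", "AD", "WT"),
             age = c(8, 12, 10, 6),
             y = c(0.4, 0.02, 0.7, NA),
             X = X)
}

# small but real synthetic cohort for fast end-to-end unit tests
small_study <- function() memo("small_study", {
  design <- cohort_design(n_abeta_only = c(WT = 6, AD = 6),
                          n_biomarker_only = c(WT = 6, AD = 6),
                          n_paired = c(WT = 8, AD = 8),
                          age_grid = seq(4, 16, by = 4), L = 4)
  generate_synthetic_study(design, truth_config(), seed = 11)
})

small_summary <- function() memo("small_summary", {
  suppressWarnings(step1_pretrain(small_study()$dataset,
                                  mcmc = mcmc_config(2, 400, 400,
                                                     seed = 11)))$summary
})

small_fit <- function() memo("small_fit", {
  suppressWarnings(step2_train(small_study()$dataset, small_summary(),
                               mcmc = mcmc_config(2, 300, 300,
                                                  seed = 12)))
})

# the acceptance-scale cohort (study conditions) and its step-1 summary
acc_study <- function() memo("acc_study", {
  generate_synthetic_study(cohort_design(), truth_config(), seed = 42)
})

acc_summary <- function() memo("acc_summary", {
  suppressWarnings(step1_pretrain(acc_study()$dataset,
                                  mcmc = mcmc_config(3, 1500, 1000,
                                                     seed = 1)))$summary
})
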