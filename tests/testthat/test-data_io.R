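test_that("sample-table writing is byte-deterministic and round trips", {
  st <- small_study()
  tab <- study_to_table(st)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_samples_table(tab, f1)
  write_samples_table(tab, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_samples_table(f1)
  expect_identical(back$abeta40, tab$abeta40)   # bit-exact doubles
  expect_identical(back$f01, tab$f01)
  unlink(c(f1, f2))
})

test_that("standardization matches the population-sd oracle", {
  tab <- data.frame(sample_id = c("a", "b", "c"),
                    type = "AD", age_months = c(4, 8, 12),
                    f1 = c(1, 2, 3))
  out <- standardize_features(tab)
  # population sd of (1,2,3) is sqrt(2/3); z-scores are +-sqrt(3/2), 0
  expect_equal(out$table$f1, c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  expect_equal(out$report$feature_stats$mean, 2)
  expect_equal(out$report$feature_stats$sd, sqrt(2 / 3))
  # re-application reproduces the transform
  expect_equal(apply_preprocess(tab, out$report)$f1, out$table$f1)
})

test_that("zero-variance features are rejected by name", {
  tab <- data.frame(sample_id = c("a", "b"), type = "AD",
                    age_months = c(4, 8), f_flat = c(2, 2))
  expect_error(standardize_features(tab), "f_flat")
})

test_that("abeta scaling maps the reference-age maximum to one", {
  tab <- data.frame(sample_id = c("a", "b", "c", "d"), type = "AD",
                    age_months = c(12, 12, 8, 16),
                    abeta40 = c(2, 4, 1, 6))
  out <- scale_abeta(tab, reference_age = 12)
  expect_equal(out$table$abeta40, c(0.5, 1, 0.25, 1.5))
  expect_equal(unname(out$report$divisors["abeta40"]), 4)
  expect_error(scale_abeta(tab, reference_age = 20), "reference age")
})

test_that("virtual wild-type augmentation adds zero observations", {
  tab <- data.frame(sample_id = c("w1", "a1"), type = c("WT", "AD"),
                    age_months = c(8, 12), abeta40 = c(NA, 1),
                    f1 = c(0.3, -0.2))
  out <- augment_virtual_wt(tab, ages = c(8, 18), n_per_age = 2)
  added <- out[!out$sample_id %in% tab$sample_id, ]
  expect_equal(nrow(added), 4L)
  expect_true(all(added$type == "WT"))
  expect_true(all(added$abeta40 == 0))
  expect_true(all(is.na(added$f1)))
  expect_equal(sort(unique(added$age_months)), c(8, 18))
  # paired variant attaches zeros to existing WT feature rows
  out2 <- augment_virtual_wt(tab, paired = TRUE)
  expect_equal(out2$abeta40[out2$sample_id == "w1"], 0)
  expect_equal(nrow(out2), nrow(tab))
})

test_that("dataset assembly honours the exclusion semantics", {
  tab <- data.frame(sample_id = c("p1", "p2", "b1"),
                    type = c("AD", "AD", "WT"),
                    age_months = c(8, 12, 8),
                    abeta40 = c(0.5, 0.9, NA),
                    f1 = c(1, 2, 3), f2 = c(0, 1, -1))
  ds <- assemble_dataset(tab)
  expect_equal(length(ds$S_XY), 2L)
  # an excluded paired sample keeps its features but loses its label
  ds2 <- assemble_dataset(tab, exclusions = "p1")
  expect_true(is.na(ds2$y[ds2$id == "p1"]))
  expect_equal(length(ds2$S_XY), 1L)
  expect_equal(ds2$N_X, 3L)
})

test_that("table validation flags structural problems", {
  tab <- data.frame(sample_id = c("a", "a"), type = "AD",
                    age_months = 4, abeta40 = 1)
  f <- tempfile(fileext = ".csv")
  write_samples_table(tab, f)
  expect_error(read_samples_table(f), "duplicate")
  unlink(f)
})
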