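#' Cross-validated prediction of Abeta in paired samples
#'
#' Leave-one-out or k-fold cross-validation over the paired samples.
#' For each fold the held-out samples are removed from training (their
#' `y` always; in the default `"strict"` mode their `x` as well, the
#' strictest leakage control; in `"lenient"` mode their `x` stays in the
#' training set as unpaired data), step-2 training is rerun, and the
#' held-out levels are predicted from their biomarker vectors. Step-1
#' pre-training is not repeated: it involves no biomarker data, so the
#' held-out features cannot leak through it.
#'
#' @param dataset an [ab_dataset] with a nonempty paired set.
#' @param summary the step-1 `"hyper_summary"`.
#' @param scheme `"loocv"` or an integer number of folds.
#' @param prior an [ab_prior].
#' @param mcmc an [mcmc_config] for the per-fold retraining (reduced
#'   settings, e.g. 500 + 500, keep evaluation loops fast).
#' @param seed seed controlling fold assignment and prediction draws.
#' @param mode held-out handling, `"strict"` (default) or `"lenient"`.
#' @param grid,M,max_draws prediction settings, see
#'   [predictive_components()].
#' @param include_derivative passed to [step2_train()].
#' @param mask_ids optional sample ids whose labels are masked in every
#'   training set (they act as unpaired biomarker data); used by the
#'   supervised-ratio experiment.
#' @return An object of class `"ab_cv"`: per-sample predictions
#'   (`samples` data.frame with `id`, `type`, `age`, `y`, `yhat`,
#'   `abs_err`, `sq_err`, `p_AD`, `fold`), the aggregate `mse`, fold
#'   assignments and the seed.
#' @export
cross_validate <- function(dataset, summary, scheme = "loocv",
                           prior = prior_config(),
                           mcmc = mcmc_config(3, 500, 500),
                           seed = 1L, mode = c("strict", "lenient"),
                           grid = 2:18, M = 1, max_draws = 600,
                           include_derivative = TRUE,
                           mask_ids = character(0)) {
  mode <- match.arg(mode)
  paired <- dataset$S_XY
  if (length(paired) == 0) stop("no paired samples", call. = FALSE)
  k <- if (identical(scheme, "loocv")) length(paired)
       else as.integer(scheme)
  if (k < 2 || k > length(paired))
    stop("fold count must be in [2, |S_XY|]", call. = FALSE)
  set.seed(seed)
  fold_of <- stats::setNames(
    sample(rep(seq_len(k), length.out = length(paired))),
    dataset$id[paired])
  rows <- list()
  for (f in seq_len(k)) {
    test_ids <- names(fold_of)[fold_of == f]
    test_idx <- match(test_ids, dataset$id)
    train <- if (mode == "strict") {
      dataset_subset(dataset, setdiff(seq_along(dataset$id), test_idx))
    } else {
      mask_labels(dataset, test_ids)
    }
    if (length(mask_ids))
      train <- mask_labels(train, setdiff(mask_ids, test_ids))
    fit <- step2_train(train, summary, prior,
                       mcmc_config(mcmc$n_chains, mcmc$n_burnin,
                                   mcmc$n_samples, seed = mcmc$seed + f),
                       include_derivative = include_derivative,
                       rhat_warn = Inf)
    comps <- predictive_components(fit, grid, M, seed = seed + f,
                                   max_draws = max_draws)
    for (i in test_idx) {
      p <- predict_abeta(dataset$X[i, ], fit, comps = comps)
      rows[[length(rows) + 1L]] <- data.frame(
        id = dataset$id[i], type = dataset$type[i],
        age = dataset$age[i], y = dataset$y[i], yhat = p$yhat,
        p_AD = unname(p$type_posterior["AD"]), fold = f)
    }
  }
  samples <- do.call(rbind, rows)
  samples$abs_err <- abs(samples$yhat - samples$y)
  samples$sq_err <- (samples$yhat - samples$y)^2
  structure(list(samples = samples, mse = mean(samples$sq_err),
                 folds = fold_of, k = k, mode = mode, seed = seed),
            class = "ab_cv")
}

#' @export
print.ab_cv <- function(x, ...) {
  cat(sprintf(
    "%s cross-validation over %d paired samples (%d folds, %s held-out handling)\n",
    if (x$k == nrow(x$samples)) "Leave-one-out" else sprintf("%d-fold", x$k),
    nrow(x$samples), x$k, x$mode))
  cat(sprintf("  MSE = %.4f (null mean-predictor variance = %.4f)\n",
              x$mse, mean((x$samples$y - mean(x$samples$y))^2)))
  invisible(x)
}

#' Plot cross-validated predictions against observations
#'
#' @param x an `"ab_cv"` object.
#' @param ... passed to [plot()].
#' @export
plot.ab_cv <- function(x, ...) {
  cols <- c(WT = "black", AD = "red")
  lim <- range(c(x$samples$y, x$samples$yhat))
  plot(x$samples$y, x$samples$yhat, col = cols[x$samples$type],
       pch = 16, xlim = lim, ylim = lim,
       xlab = "observed Abeta", ylab = "predicted Abeta", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Prediction error as the supervised (paired) fraction shrinks
#'
#' For each fraction, a random subset of the training paired samples
#' keeps its Abeta label; the remainder's labels are masked so those
#' samples act as unpaired biomarker data. Evaluation uses the same
#' cross-validation harness (the held-out fold itself is never masked,
#' it is held out), so `fraction = 1` reproduces [cross_validate()]
#' exactly on the same seed.
#'
#' @param dataset,summary,scheme,prior,mcmc,seed,mode,grid,M,max_draws
#'   as in [cross_validate()].
#' @param fractions supervised fractions to evaluate.
#' @param repeats random label subsets per fraction (the `fraction = 1`
#'   case is deterministic and run once).
#' @return A list with `results` (data.frame of `fraction`, `rep`,
#'   `mse`) and `cv` (list of the underlying `"ab_cv"` objects).
#' @export
supervised_ratio_experiment <- function(dataset, summary,
                                        fractions = c(1, 1 / 2, 1 / 3),
                                        repeats = 2, scheme = 4,
                                        prior = prior_config(),
                                        mcmc = mcmc_config(3, 500, 500),
                                        seed = 1L, ...) {
  paired_ids <- dataset$id[dataset$S_XY]
  out <- list(); cvs <- list()
  for (f in fractions) {
    n_keep <- round(f * length(paired_ids))
    if (n_keep < 1) stop("fraction ", f, " leaves no supervised samples",
                         call. = FALSE)
    n_rep <- if (f == 1) 1L else repeats
    for (r in seq_len(n_rep)) {
      mask <- if (f == 1) character(0) else {
        set.seed(seed + 1000L * r + round(1e6 * f))
        setdiff(paired_ids, sample(paired_ids, n_keep))
      }
      cv <- cross_validate(dataset, summary, scheme = scheme,
                           prior = prior, mcmc = mcmc, seed = seed,
                           mask_ids = mask, ...)
      out[[length(out) + 1L]] <- data.frame(fraction = f, rep = r,
                                            mse = cv$mse)
      cvs[[length(cvs) + 1L]] <- cv
    }
  }
  list(results = do.call(rbind, out), cv = cvs)
}

#' Feature importance for Abeta prediction
#'
#' Three modes. `"exclusion"`: retrain and cross-validate with each
#' single feature removed; the importance of a feature is the CV error
#' when it is missing. `"incremental"`: rank features by exclusion
#' impact (largest error increase first, ties broken by feature index)
#' and evaluate the top-`j` sets for `j = 1..L`. `"random_subsets"`:
#' evaluate `R` random feature subsets per subset size and compare the
#' size-specific error distributions pairwise by Mann-Whitney U tests
#' with Holm correction.
#'
#' @param dataset,summary,scheme,prior,mcmc,seed as in
#'   [cross_validate()].
#' @param mode one of `"exclusion"`, `"incremental"`,
#'   `"random_subsets"`.
#' @param R random subsets per size (`random_subsets` mode; must be
#'   >= 2).
#' @param sizes subset sizes to evaluate (`random_subsets` mode).
#' @param ... passed to [cross_validate()].
#' @return An object of class `"ab_importance"` whose contents depend on
#'   the mode: per-feature exclusion errors and `ranking`; the
#'   incremental error `curve`; or per-size error distributions with a
#'   Holm-adjusted pairwise p-value matrix.
#' @export
feature_importance <- function(dataset, summary,
                               mode = c("exclusion", "incremental",
                                        "random_subsets"),
                               scheme = 4, prior = prior_config(),
                               mcmc = mcmc_config(2, 300, 300),
                               seed = 1L, R = 5,
                               sizes = seq_len(dataset$L), ...) {
  mode <- match.arg(mode)
  L <- dataset$L
  if (L < 2) stop("feature importance needs L >= 2", call. = FALSE)
  feat_names <- colnames(dataset$X)
  if (is.null(feat_names)) feat_names <- sprintf("f%02d", seq_len(L))
  with_features <- function(keep) {
    ab_dataset(dataset$id, dataset$type, dataset$age, dataset$y,
               dataset$X[, keep, drop = FALSE])
  }
  run_cv <- function(ds) cross_validate(ds, summary, scheme = scheme,
                                        prior = prior, mcmc = mcmc,
                                        seed = seed, ...)$mse
  if (mode %in% c("exclusion", "incremental")) {
    excl_mse <- vapply(seq_len(L),
                       function(l) run_cv(with_features(-l)), 0)
    names(excl_mse) <- feat_names
    ranking <- order(excl_mse, decreasing = TRUE)
    if (mode == "exclusion")
      return(structure(list(mode = mode, exclusion_mse = excl_mse,
                            ranking = ranking, seed = seed),
                       class = "ab_importance"))
    curve <- vapply(seq_len(L), function(j)
      run_cv(with_features(sort(ranking[seq_len(j)]))), 0)
    return(structure(list(mode = mode, exclusion_mse = excl_mse,
                          ranking = ranking, curve = curve, seed = seed),
                     class = "ab_importance"))
  }
  if (R < 2) stop("'R' must be >= 2 for the subset comparison tests",
                  call. = FALSE)
  sizes <- sizes[sizes >= 1 & sizes <= L]
  res <- list()
  for (sz in sizes) {
    n_draws <- if (sz == L) 1L else R
    for (r in seq_len(n_draws)) {
      set.seed(seed + 100L * sz + r)
      keep <- sort(sample(L, sz))
      res[[length(res) + 1L]] <- data.frame(size = sz, rep = r,
                                            mse = run_cv(with_features(keep)))
    }
  }
  res <- do.call(rbind, res)
  by_size <- split(res$mse, res$size)
  pairs <- utils::combn(names(by_size), 2)
  pvals <- apply(pairs, 2, function(pr) {
    a <- by_size[[pr[1]]]; b <- by_size[[pr[2]]]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    stats::wilcox.test(a, b, exact = FALSE)$p.value
  })
  adj <- stats::p.adjust(pvals, method = "holm")
  tests <- data.frame(size_a = pairs[1, ], size_b = pairs[2, ],
                      p = pvals, p_holm = adj)
  structure(list(mode = mode, subsets = res, tests = tests, seed = seed),
            class = "ab_importance")
}

#' @export
print.ab_importance <- function(x, ...) {
  cat("Feature-importance analysis, mode:", x$mode, "\n")
  if (!is.null(x$exclusion_mse)) {
    cat("  CV MSE with each feature excluded (high = important):\n")
    print(round(sort(x$exclusion_mse, decreasing = TRUE), 4))
  }
  if (!is.null(x$curve)) {
    cat("  incremental-inclusion error curve:\n")
    print(round(x$curve, 4))
  }
  if (!is.null(x$tests)) print(x$tests)
  invisible(x)
}

#' Stratified prediction performance
#'
#' Splits cross-validated errors by age, type, or an observed-level
#' threshold, and reports per-age accuracy of presence/absence calls:
#' "presence predicted" means the predicted level exceeds
#' `presence_eps` (predictions are never exactly zero), compared against
#' the true type (AD = presence). Empty strata are simply absent.
#'
#' @param cv an `"ab_cv"` result.
#' @param strata one of `"age"`, `"type"`, `"threshold"`.
#' @param threshold observed-level split point for `"threshold"`.
#' @param presence_eps predicted-level cutoff for a presence call
#'   (default `0.05`, the Abeta noise sd).
#' @return A data.frame with one row per stratum: `n`, `mse`,
#'   `mean_abs_err`, and (for `"age"`) `presence_accuracy`.
#' @export
stratified_performance <- function(cv, strata = c("age", "type",
                                                  "threshold"),
                                   threshold = 0.66,
                                   presence_eps = 0.05) {
  strata <- match.arg(strata)
  s <- cv$samples
  key <- switch(strata,
                age = s$age,
                type = s$type,
                threshold = ifelse(s$y <= threshold,
                                   sprintf("<=%.2f", threshold),
                                   sprintf(">%.2f", threshold)))
  out <- do.call(rbind, lapply(split(seq_len(nrow(s)), key), function(i) {
    d <- s[i, ]
    row <- data.frame(stratum = as.character(key[i[1]]), n = nrow(d),
                      mse = mean(d$sq_err),
                      mean_abs_err = mean(d$abs_err))
    if (strata == "age") {
      pred_presence <- d$yhat > presence_eps
      true_presence <- d$type == "AD"
      row$presence_accuracy <- mean(pred_presence == true_presence)
    }
    row
  }))
  rownames(out) <- NULL
  out
}
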