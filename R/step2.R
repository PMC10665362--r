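#' Step-2 training on biomarker and paired data
#'
#' Learns the joint posterior of the emission weight matrix, the noise
#' and weight-scale variances, the per-animal logistic parameters of all
#' biomarker-bearing samples (`S_X`), and the type hierarchy, given the
#' unpaired biomarker data and the paired data. Each iteration draws the
#' weight rows and the variance precisions from their exact conjugate
#' conditionals and updates the remaining block by adaptive random-walk
#' Metropolis; the step-1 [summarize_hyperposterior()] summary provides
#' the hyper-priors. Abeta likelihood terms enter only for paired
#' samples; Abeta-only samples contribute through the summary.
#'
#' @param dataset an [ab_dataset] with a nonempty `S_X`.
#' @param summary a `"hyper_summary"` from step 1.
#' @param prior an [ab_prior] (supplies `a_w`, `b_w`, `a_x`, `b_x` and
#'   `sigma_y`).
#' @param mcmc an [mcmc_config]; defaults to 3 chains of 5000 + 5000.
#' @param C speed-scaling factor; `NULL` uses
#'   `4 / (mu_beta_AD * mu_alpha_AD)` evaluated at the summary means, so
#'   the prior-typical peak of `C z'` is about 1.
#' @param include_derivative keep the `C z'` component of the latent
#'   state? `FALSE` fits the two-column variant model.
#' @param compat_printed_shape see [variance_conditional_params()].
#' @param rhat_warn warn when any monitored split-R-hat exceeds this.
#' @return An object of class `"abm_fit"` with the posterior draws
#'   (`W`, `sigma2_x`, `sigma2_w`, `theta`, `mu`, `sigma2`), the model
#'   constants, and convergence diagnostics.
#' @seealso [predict.abm_fit()], [cross_validate()]
#' @export
step2_train <- function(dataset, summary, prior = prior_config(),
                        mcmc = mcmc_config(3, 5000, 5000),
                        C = NULL, include_derivative = TRUE,
                        compat_printed_shape = FALSE, rhat_warn = 1.2) {
  stopifnot(inherits(summary, "hyper_summary"))
  if (dataset$N_X == 0)
    stop("step 2 needs biomarker-bearing samples", call. = FALSE)
  if (is.null(C))
    C <- 4 / (summary$mu_mean["beta", "AD"] * summary$mu_mean["alpha", "AD"])
  sel <- dataset$S_X
  k <- type_index(dataset$type[sel])
  theta0 <- t(vapply(k, function(kk) summary$mu_mean[, kk], numeric(3)))
  theta0[, 1:2] <- pmax(theta0[, 1:2], 1e-6)
  L <- dataset$L
  D <- if (include_derivative) 3L else 2L
  emission <- list(W = matrix(0, L, D),
                   sigma2_x = rep(1, L),
                   sigma2_w = rep(prior$b_w / prior$a_w, L),
                   C = C, include_derivative = include_derivative,
                   gibbs = TRUE, a_x = prior$a_x, b_x = prior$b_x,
                   a_w = prior$a_w, b_w = prior$b_w)
  hyper_prior <- list(mu_mean = summary$mu_mean, mu_sd = summary$mu_sd,
                      lam_shape = summary$lam_shape,
                      lam_rate = summary$lam_rate)
  draws <- run_mwg(theta0 = theta0, t = dataset$age[sel], k = k,
                   y = dataset$y[sel], X = dataset$X[sel, , drop = FALSE],
                   pseudo = FALSE, hyper_prior = hyper_prior,
                   sigma_y = prior$sigma_y, emission = emission,
                   mcmc = mcmc,
                   compat_printed_shape = compat_printed_shape)
  colnames(draws$W) <- as.vector(outer(seq_len(L), seq_len(D),
                                       function(l, d) sprintf("W.%d.%d", l, d)))
  colnames(draws$sigma2_x) <- sprintf("sigma2_x.%d", seq_len(L))
  colnames(draws$sigma2_w) <- sprintf("sigma2_w.%d", seq_len(L))
  if (!is.null(draws$theta))
    colnames(draws$theta) <- as.vector(outer(
      seq_along(sel), c("alpha", "beta", "gamma"),
      function(i, p) sprintf("theta.%s.%s", dataset$id[sel][i], p)))
  diag_df <- rbind(hyper_diagnostics(draws),
                   data.frame(param = colnames(draws$W),
                              rhat = apply(draws$W, 2, split_rhat,
                                           chain = draws$chain),
                              ess = apply(draws$W, 2, ess_basic,
                                          chain = draws$chain)))
  if (any(diag_df$rhat > rhat_warn, na.rm = TRUE))
    warning("step 2: split-R-hat above ", rhat_warn, " for: ",
            paste(diag_df$param[diag_df$rhat > rhat_warn],
                  collapse = ", "), call. = FALSE)
  structure(list(draws = draws, ids = dataset$id[sel],
                 type = dataset$type[sel], age = dataset$age[sel],
                 y = dataset$y[sel], L = L, D = D, C = C,
                 include_derivative = include_derivative,
                 sigma_y = prior$sigma_y, summary = summary,
                 mcmc = mcmc, diagnostics = diag_df),
            class = "abm_fit")
}

#' Sample the non-conjugate block at fixed emission parameters
#'
#' Draws the per-animal logistic parameters (for all biomarker-bearing
#' samples) and the type hierarchy from their conditional posterior with
#' the weight matrix and variances held fixed. With no biomarker
#' likelihood (`dataset = NULL`), the hierarchy is sampled from the
#' summary priors alone.
#'
#' @param dataset an [ab_dataset] or `NULL` for prior-only sampling.
#' @param summary a `"hyper_summary"` providing the hyper-priors.
#' @param obs an [obs_params] with the fixed emission parameters.
#' @param mcmc an [mcmc_config].
#' @param sigma_y fixed Abeta noise sd.
#' @return A list of draws (`mu`, `sigma2`, `theta`, `chain`).
#' @export
mcmc_update_theta_hyper <- function(dataset, summary, obs,
                                    mcmc = mcmc_config(1, 1000, 1000),
                                    sigma_y = 0.05) {
  hyper_prior <- list(mu_mean = summary$mu_mean, mu_sd = summary$mu_sd,
                      lam_shape = summary$lam_shape,
                      lam_rate = summary$lam_rate)
  if (is.null(dataset) || dataset$N_X == 0) {
    return(run_mwg(theta0 = matrix(0, 0, 3), t = numeric(0),
                   k = integer(0), y = numeric(0), X = NULL,
                   pseudo = FALSE, hyper_prior = hyper_prior,
                   sigma_y = sigma_y, emission = NULL, mcmc = mcmc))
  }
  sel <- dataset$S_X
  k <- type_index(dataset$type[sel])
  theta0 <- t(vapply(k, function(kk) pmax(summary$mu_mean[, kk], 1e-6),
                     numeric(3)))
  emission <- c(obs[c("W", "sigma2_x", "sigma2_w", "C",
                      "include_derivative")], list(gibbs = FALSE))
  run_mwg(theta0 = theta0, t = dataset$age[sel], k = k,
          y = dataset$y[sel], X = dataset$X[sel, , drop = FALSE],
          pseudo = FALSE, hyper_prior = hyper_prior, sigma_y = sigma_y,
          emission = emission, mcmc = mcmc)
}

#' @export
print.abm_fit <- function(x, ...) {
  I <- nrow(x$draws$mu)
  cat(sprintf(
    "Fitted accumulation-emission model: L = %d features, D = %d latent components\n",
    x$L, x$D))
  cat(sprintf("  %d posterior draws (%d chains), C = %.3f, sigma_y = %.3f\n",
              I, x$mcmc$n_chains, x$C, x$sigma_y))
  cat(sprintf("  max split-R-hat (monitored): %.3f\n",
              max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.abm_fit <- function(object, ...) {
  W <- posterior_mean_W(object)
  cat("Posterior-mean emission weights (rows = features):\n")
  print(round(W, 3))
  cat("\nPosterior-mean feature noise sds:\n")
  print(round(sqrt(colMeans(object$draws$sigma2_x)), 3))
  cat("\nHierarchy posterior means:\n")
  print(round(matrix(colMeans(object$draws$mu), 3, 2,
                     dimnames = dn_phik()), 4))
  invisible(object)
}

#' Posterior mean of the emission weight matrix
#'
#' @param fit an `"abm_fit"`.
#' @return `L x D` matrix of posterior means.
#' @export
posterior_mean_W <- function(fit) {
  matrix(colMeans(fit$draws$W), fit$L, fit$D)
}

#' @export
coef.abm_fit <- function(object, ...) {
  list(W = posterior_mean_W(object),
       sigma2_x = colMeans(object$draws$sigma2_x),
       sigma2_w = colMeans(object$draws$sigma2_w),
       mu = matrix(colMeans(object$draws$mu), 3, 2,
                   dimnames = dn_phik()),
       sigma2 = matrix(colMeans(object$draws$sigma2), 3, 2,
                       dimnames = dn_phik()))
}

# ---- serialization ------------------------------------------------------

#' Write posterior draws to a columnar CSV
#'
#' One row per draw with named parameter columns (plus a `chain`
#' column); a plain-text metadata sidecar `<path>.meta` holds the model
#' constants needed to reload the fit.
#'
#' @param fit an `"abm_fit"`.
#' @param path output CSV path.
#' @export
write_fit <- function(fit, path) {
  d <- fit$draws
  df <- data.frame(chain = d$chain, d$mu, d$sigma2, d$W, d$sigma2_x,
                   d$sigma2_w, d$theta, check.names = FALSE)
  out <- lapply(df, function(col)
    if (is.numeric(col) && !is.integer(col)) sprintf("%.17g", col)
    else col)
  out <- as.data.frame(out, check.names = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- fit[c("ids", "type", "age", "y", "L", "D", "C",
                "include_derivative", "sigma_y")]
  meta$summary <- unclass(fit$summary)
  dput(meta, file = paste0(path, ".meta"))
  invisible(path)
}

#' Read posterior draws written by [write_fit()]
#'
#' @param path CSV path previously written by [write_fit()].
#' @return An `"abm_fit"` object (without diagnostics).
#' @export
read_fit <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- dget(paste0(path, ".meta"))
  grab <- function(prefix) {
    cols <- grep(prefix, names(df))
    m <- as.matrix(df[, cols, drop = FALSE])
    rownames(m) <- NULL
    m
  }
  draws <- list(mu = grab("^mu\\."), sigma2 = grab("^sigma2\\."),
                W = grab("^W\\."), sigma2_x = grab("^sigma2_x\\."),
                sigma2_w = grab("^sigma2_w\\."), theta = grab("^theta\\."),
                chain = df$chain)
  summary <- structure(meta$summary, class = "hyper_summary")
  structure(c(list(draws = draws, summary = summary),
              meta[c("ids", "type", "age", "y", "L", "D", "C",
                     "include_derivative", "sigma_y")]),
            class = "abm_fit")
}
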