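#' Least-squares initialization of the logistic prior means
#'
#' Fits the logistic accumulation curve to the Abeta-vs-age scatter of
#' each animal type by nonlinear least squares (with the zero
#' pseudo-observations at `t = 0` appended), yielding the prior means
#' `m[phi, k]` used by step-1 pre-training. Ten deterministic random
#' restarts are tried and the best-SSE fit kept. A degenerate type (e.g.
#' WT with all-zero observations, where `beta` and `gamma` are not
#' identified) falls back to configured defaults and is flagged.
#'
#' @param dataset an [ab_dataset]; only `S_y` samples are used.
#' @param fallback named vector `c(alpha=, beta=, gamma=)` used for a
#'   degenerate type. `beta` / `gamma` of `NA` mean "copy from the other
#'   type's fit".
#' @param n_starts number of random restarts.
#' @param seed seed for the restart draws.
#' @param degenerate_tol a type counts as degenerate when all its
#'   observations, or its fitted maximum `alpha`, stay below this
#'   fraction of the scaled axis (on which the reference-age maximum is
#'   1): with no measurable accumulation, `beta` and `gamma` are not
#'   identified and fitting them would chase noise.
#' @return A list with `m` (3 x 2 matrix of fitted means), `fallback_used`
#'   (logical per type) and `sse` (per type).
#' @export
least_squares_init <- function(dataset,
                               fallback = c(alpha = 0.05, beta = NA,
                                            gamma = NA),
                               n_starts = 10, seed = 1L,
                               degenerate_tol = 0.1) {
  m <- matrix(NA_real_, 3, 2, dimnames = dn_phik())
  used_fb <- c(WT = FALSE, AD = FALSE)
  sse <- c(WT = NA_real_, AD = NA_real_)
  fits <- list()
  for (kname in c("AD", "WT")) {
    sel <- intersect(dataset$S_y, which(dataset$type == kname))
    t_obs <- c(dataset$age[sel], rep(0, length(sel)))
    y_obs <- c(dataset$y[sel], rep(0, length(sel)))
    degenerate <- length(sel) < 3 ||
      length(unique(dataset$age[sel])) < 2 ||
      all(abs(dataset$y[sel]) < degenerate_tol)
    if (degenerate) {
      used_fb[kname] <- TRUE
      next
    }
    best <- NULL
    set.seed(seed)
    for (s in seq_len(n_starts)) {
      start <- list(alpha = max(y_obs) * stats::runif(1, 0.7, 1.5),
                    beta = stats::runif(1, 0.1, 1),
                    gamma = stats::runif(1, 1, 8))
      fit <- try(minpack.lm::nlsLM(
        y ~ alpha / (1 + exp(-beta * t + gamma)),
        data = data.frame(t = t_obs, y = y_obs),
        start = start,
        lower = c(alpha = 1e-6, beta = 1e-6, gamma = -50),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        silent = TRUE)
      if (inherits(fit, "try-error")) next
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
    if (is.null(best)) {
      # every start failed: typical for near-zero accumulation where the
      # sigmoid is unidentified; treat like the degenerate case
      used_fb[kname] <- TRUE
      next
    }
    cf <- stats::coef(best$fit)
    if (cf["alpha"] < degenerate_tol) {
      # no measurable accumulation: beta/gamma are noise-chasing
      used_fb[kname] <- TRUE
      next
    }
    m[, kname] <- cf[c("alpha", "beta", "gamma")]
    sse[kname] <- best$rss
    fits[[kname]] <- best$fit
  }
  for (kname in names(used_fb)[used_fb]) {
    other <- setdiff(c("WT", "AD"), kname)
    fb <- fallback
    for (phi in c("beta", "gamma"))
      if (is.na(fb[phi])) fb[phi] <- m[phi, other]
    if (any(is.na(fb)))
      stop("insufficient data to initialize type ", kname, call. = FALSE)
    m[, kname] <- fb[c("alpha", "beta", "gamma")]
  }
  list(m = m, fallback_used = used_fb, sse = sse, fits = fits)
}

#' Step-1 pre-training on Abeta-only data
#'
#' Samples the joint posterior of the per-animal logistic parameters and
#' the type-level hierarchy given only the Abeta observations (`S_y`),
#' by adaptive Metropolis-within-Gibbs. Each sample's likelihood
#' includes its observed `(t, y)` and the zero pseudo-observation at
#' `t = 0` with the same noise sd. Prior means `m` that are `NA` in the
#' prior config are filled by [least_squares_init()].
#'
#' @param dataset an [ab_dataset]; both types must be present in `S_y`
#'   (WT may be entirely virtual).
#' @param prior an [ab_prior].
#' @param mcmc an [mcmc_config]; defaults to 3 chains of 3000 + 3000.
#' @param rhat_warn warn when any hyper-parameter's split-R-hat exceeds
#'   this.
#' @return An object of class `"ab_pretrain"`: posterior draws of the
#'   hierarchy (`mu`, `sigma2`) and per-sample `theta`, the resolved
#'   prior, the least-squares initialization, diagnostics, and the
#'   moment-matched [summarize_hyperposterior()] summary.
#' @export
step1_pretrain <- function(dataset, prior = prior_config(),
                           mcmc = mcmc_config(3, 3000, 3000),
                           rhat_warn = 1.2) {
  if (dataset$N_y == 0) stop("no Abeta-observed samples", call. = FALSE)
  sel <- dataset$S_y
  types <- unique(dataset$type[sel])
  if (!all(c("WT", "AD") %in% types))
    stop("step 1 needs Abeta observations for both types ",
         "(add virtual WT samples)", call. = FALSE)
  lsq <- NULL
  if (any(is.na(prior$m))) {
    lsq <- least_squares_init(dataset, seed = mcmc$seed)
    prior$m[is.na(prior$m)] <- lsq$m[is.na(prior$m)]
  }
  k <- type_index(dataset$type[sel])
  theta0 <- t(vapply(k, function(kk) prior$m[, kk], numeric(3)))
  hyper_prior <- list(mu_mean = prior$m, mu_sd = prior$v,
                      lam_shape = prior$a, lam_rate = prior$b)
  draws <- run_mwg(theta0 = theta0, t = dataset$age[sel], k = k,
                   y = dataset$y[sel], X = NULL, pseudo = TRUE,
                   hyper_prior = hyper_prior, sigma_y = prior$sigma_y,
                   emission = NULL, mcmc = mcmc)
  diag_df <- hyper_diagnostics(draws)
  if (any(diag_df$rhat > rhat_warn, na.rm = TRUE))
    warning("step 1: split-R-hat above ", rhat_warn,
            " for: ", paste(diag_df$param[diag_df$rhat > rhat_warn],
                            collapse = ", "),
            "; consider longer chains", call. = FALSE)
  out <- structure(list(draws = draws, prior = prior, lsq = lsq,
                        ids = dataset$id[sel], type = dataset$type[sel],
                        age = dataset$age[sel], y = dataset$y[sel],
                        mcmc = mcmc, diagnostics = diag_df),
                   class = "ab_pretrain")
  out$summary <- summarize_hyperposterior(out)
  out
}

hyper_diagnostics <- function(draws) {
  cols <- cbind(draws$mu, draws$sigma2)
  data.frame(
    param = colnames(cols),
    rhat = apply(cols, 2, split_rhat, chain = draws$chain),
    ess = apply(cols, 2, ess_basic, chain = draws$chain),
    row.names = NULL)
}

#' @export
print.ab_pretrain <- function(x, ...) {
  cat(sprintf(
    "Step-1 pre-training: %d Abeta samples, %d chains x %d draws\n",
    length(x$ids), x$mcmc$n_chains, x$mcmc$n_samples))
  cat(sprintf("  max split-R-hat (hierarchy): %.3f\n",
              max(x$diagnostics$rhat, na.rm = TRUE)))
  cat("  posterior means of the type means:\n")
  print(round(matrix(colMeans(x$draws$mu), 3, 2, dimnames = dn_phik()), 4))
  invisible(x)
}

#' Summarize the step-1 hyper-posterior into step-2 priors
#'
#' Moment-matches a Gaussian to the posterior draws of each type mean
#' `mu[phi,k]` and a Gamma to the draws of each type precision
#' `sigma[phi,k]^-2` (shape `= mean^2/var`, rate `= mean/var`). The
#' resulting distributions serve as the hyper-priors of step-2 training.
#' Degenerate (zero-variance) draw sets get a small floor sd so the
#' summary stays proper.
#'
#' @param x an `"ab_pretrain"` object, or a list with matrices `mu` and
#'   `sigma2` of draws (6 columns each, `phi` x type).
#' @param sd_floor minimum sd for the fitted Gaussians.
#' @return An object of class `"hyper_summary"`: 3 x 2 matrices
#'   `mu_mean`, `mu_sd`, `lam_shape`, `lam_rate`.
#' @export
summarize_hyperposterior <- function(x, sd_floor = 1e-6) {
  draws <- if (inherits(x, "ab_pretrain")) x$draws else x
  if (is.null(draws$mu) || nrow(draws$mu) == 0)
    stop("no draws to summarize", call. = FALSE)
  mu_mean <- matrix(colMeans(draws$mu), 3, 2, dimnames = dn_phik())
  mu_sd <- matrix(pmax(apply(draws$mu, 2, stats::sd), sd_floor), 3, 2,
                  dimnames = dn_phik())
  lam <- 1 / draws$sigma2
  lm_ <- colMeans(lam)
  lv <- apply(lam, 2, stats::var)
  lv <- pmax(lv, (sd_floor * lm_)^2)
  structure(list(mu_mean = mu_mean, mu_sd = mu_sd,
                 lam_shape = matrix(lm_^2 / lv, 3, 2,
                                    dimnames = dn_phik()),
                 lam_rate = matrix(lm_ / lv, 3, 2,
                                   dimnames = dn_phik())),
            class = "hyper_summary")
}

#' @export
print.hyper_summary <- function(x, ...) {
  cat("Hyper-posterior summary (step-2 priors)\n  mu ~ Normal, means:\n")
  print(round(x$mu_mean, 4))
  cat("  precision ~ Gamma, implied sigma^2 means:\n")
  print(round(x$lam_rate / pmax(x$lam_shape - 1, 1e-12), 5))
  invisible(x)
}

#' Plot pre-trained accumulation curves over the Abeta scatter
#'
#' Draws logistic curves with parameters sampled from the learned
#' hierarchy over the observed Abeta-vs-age scatter (red: AD, black: WT).
#'
#' @param x an `"ab_pretrain"` object.
#' @param n_curves curves per type.
#' @param t_grid ages for curve evaluation.
#' @param ... passed to [plot()].
#' @export
plot.ab_pretrain <- function(x, n_curves = 30,
                             t_grid = seq(0, 18, by = 0.25), ...) {
  cols <- c(WT = "black", AD = "red")
  plot(x$age, x$y, col = cols[x$type], pch = 16,
       xlab = "age [months]", ylab = "scaled Abeta", ...)
  idx <- round(seq(1, nrow(x$draws$mu), length.out = n_curves))
  for (kk in 1:2) {
    for (i in idx) {
      mu <- matrix(x$draws$mu[i, ], 3, 2)
      s2 <- matrix(x$draws$sigma2[i, ], 3, 2)
      th <- sample_individual_params(type_hyper(mu, s2),
                                     c("WT", "AD")[kk])
      graphics::lines(t_grid, logistic_accumulation(th, t_grid),
                      col = grDevices::adjustcolor(cols[kk], 0.25))
    }
  }
  invisible(x)
}
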