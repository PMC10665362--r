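#' Prior configuration
#'
#' Hyper-prior constants of the hierarchy and emission model. For each
#' accumulation parameter `phi` in `{alpha, beta, gamma}` and each animal
#' type `k` in `{WT, AD}` the type mean `mu[phi,k]` has a normal prior
#' `N(m[phi,k], v[phi,k]^2)` and the type precision `sigma[phi,k]^-2` a
#' Gamma prior with shape `a[phi,k]` and rate `b[phi,k]`. Emission weight
#' rows have zero-mean normal priors whose scale precisions are
#' `Gamma(a_w, b_w)`; per-feature noise precisions are `Gamma(a_x, b_x)`.
#' The Abeta observation noise `sigma_y` is fixed, not sampled.
#'
#' Defaults are the constants used throughout:
#' `v_alpha = 0.1, a_alpha = 25, b_alpha = 0.5, v_beta = 0.1,
#' a_beta = 100, b_beta = 1, v_gamma = 1, a_gamma = 10, b_gamma = 1,
#' a_w = 100, b_w = 1000, a_x = 0.5, b_x = 1, sigma_y = 0.05`.
#' The prior means `m` default to `NA` and are filled from a least-squares
#' fit of the logistic curve (see [least_squares_init()]).
#'
#' @param m,v 3 x 2 matrices (rows alpha, beta, gamma; columns WT, AD) of
#'   prior means and sds for the type means.
#' @param a,b 3 x 2 matrices of Gamma shape/rate for the type precisions.
#' @param a_w,b_w Gamma shape/rate for weight-scale precisions.
#' @param a_x,b_x Gamma shape/rate for feature-noise precisions.
#' @param sigma_y fixed Abeta observation noise sd.
#' @return An object of class `"ab_prior"`.
#' @export
prior_config <- function(m = matrix(NA_real_, 3, 2, dimnames = dn_phik()),
                         v = phik_matrix(c(0.1, 0.1, 1)),
                         a = phik_matrix(c(25, 100, 10)),
                         b = phik_matrix(c(0.5, 1, 1)),
                         a_w = 100, b_w = 1000,
                         a_x = 0.5, b_x = 1,
                         sigma_y = 0.05) {
  m <- as_phik(m); v <- as_phik(v); a <- as_phik(a); b <- as_phik(b)
  stopifnot(all(v > 0), all(a > 0), all(b > 0),
            a_w > 0, b_w > 0, a_x > 0, b_x > 0, sigma_y > 0)
  structure(list(m = m, v = v, a = a, b = b, a_w = a_w, b_w = b_w,
                 a_x = a_x, b_x = b_x, sigma_y = sigma_y),
            class = "ab_prior")
}

dn_phik <- function() list(c("alpha", "beta", "gamma"), c("WT", "AD"))

phik_matrix <- function(per_phi) {
  matrix(rep(per_phi, 2L), nrow = 3, ncol = 2, dimnames = dn_phik())
}

as_phik <- function(x) {
  if (is.matrix(x) && all(dim(x) == c(3L, 2L))) {
    dimnames(x) <- dn_phik()
    return(x)
  }
  stop("expected a 3 x 2 matrix (rows alpha/beta/gamma, columns WT/AD)",
       call. = FALSE)
}

#' Type-level hierarchy parameters
#'
#' Means and variances of the per-animal parameter hierarchy: for each of
#' alpha, beta, gamma and each type (WT, AD) a mean and a variance.
#' alpha and beta follow truncated normals restricted to positive values;
#' gamma an ordinary normal.
#'
#' @param mu 3 x 2 matrix of means (rows alpha, beta, gamma; columns WT,
#'   AD).
#' @param sigma2 3 x 2 matrix of positive variances.
#' @return An object of class `"type_hyper"`.
#' @export
type_hyper <- function(mu, sigma2) {
  mu <- as_phik(mu); sigma2 <- as_phik(sigma2)
  if (any(sigma2 <= 0)) stop("all variances must be > 0", call. = FALSE)
  structure(list(mu = mu, sigma2 = sigma2), class = "type_hyper")
}

#' @export
print.type_hyper <- function(x, ...) {
  cat("Type-level hierarchy parameters\n  means:\n")
  print(round(x$mu, 4))
  cat("  variances:\n")
  print(round(x$sigma2, 4))
  invisible(x)
}

#' Emission (observation) parameters
#'
#' The linear emission of the `L` biomarker candidates from the latent
#' state `(z, C z', 1)`: `x = W zvec + noise`, with independent per-feature
#' Gaussian noise variances `sigma2_x` and per-row weight-scale variances
#' `sigma2_w`. With `include_derivative = FALSE` the latent state is
#' `(z, 1)` and `W` has two columns.
#'
#' @param W numeric matrix, `L` rows by 3 columns (2 when
#'   `include_derivative = FALSE`).
#' @param sigma2_x length-`L` vector of positive noise variances.
#' @param sigma2_w length-`L` vector of positive weight-scale variances.
#' @param C positive scaling factor for the speed term.
#' @param include_derivative logical, keep the `C z'` component?
#' @return An object of class `"obs_params"`.
#' @export
obs_params <- function(W, sigma2_x, sigma2_w, C = 1,
                       include_derivative = TRUE) {
  W <- as.matrix(W)
  D <- if (include_derivative) 3L else 2L
  if (ncol(W) != D)
    stop(sprintf("'W' must have %d columns for include_derivative = %s",
                 D, include_derivative), call. = FALSE)
  L <- nrow(W)
  stopifnot(length(sigma2_x) == L, length(sigma2_w) == L)
  if (any(sigma2_x <= 0) || any(sigma2_w <= 0))
    stop("all variances must be > 0", call. = FALSE)
  if (!is.finite(C) || C <= 0) stop("'C' must be > 0", call. = FALSE)
  structure(list(W = W, sigma2_x = as.numeric(sigma2_x),
                 sigma2_w = as.numeric(sigma2_w), C = C,
                 include_derivative = isTRUE(include_derivative),
                 L = L, D = D),
            class = "obs_params")
}

#' MCMC settings
#'
#' @param n_chains number of independent chains.
#' @param n_burnin iterations discarded as burn-in (adaptation happens
#'   here).
#' @param n_samples retained iterations per chain.
#' @param seed integer seed; chain `c` uses stream `seed + c - 1`.
#' @param target_accept target acceptance rate for the random-walk blocks.
#' @return An object of class `"mcmc_config"`.
#' @details Step-1 pre-training defaults to 3 chains with 3000 burn-in and
#'   3000 retained draws; step-2 training to 3 chains with 5000 + 5000.
#'   Evaluation loops typically use reduced settings.
#' @export
mcmc_config <- function(n_chains = 3, n_burnin = 3000, n_samples = 3000,
                        seed = 1L, target_accept = 0.3) {
  stopifnot(n_chains >= 1, n_burnin >= 1, n_samples >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed),
                 target_accept = target_accept),
            class = "mcmc_config")
}
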