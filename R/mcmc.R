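# Metropolis-within-Gibbs engine shared by the two learning steps.
#
# Non-conjugate blocks (per-animal logistic parameters and the type-level
# hierarchy) are updated by adaptive random-walk Metropolis on transformed
# coordinates: alpha and beta are sampled on the log scale with the
# Jacobian correction so their positive-truncated-normal priors are
# honoured exactly; the type precisions are sampled as log-precisions.
# Proposal scales adapt by Robbins-Monro during burn-in only, so the
# retained draws come from a fixed, valid Markov kernel. Conjugate blocks
# (emission weight rows, feature-noise precisions, weight-scale
# precisions) are drawn from their exact conditionals.

# conditional parameters of the weight-row updates:
# precision_l = Z'Z / sigma2_x_l + I / sigma2_w_l,
# mean_l = precision_l^{-1} Z' x_l / sigma2_x_l

#' Conditional parameters of the weight-matrix Gibbs update
#'
#' @param X `N x L` matrix of biomarker observations (samples in `S_X`).
#' @param Z `N x D` matrix of latent vectors `(z, C z', 1)`.
#' @param sigma2_x length-`L` feature noise variances.
#' @param sigma2_w length-`L` weight-scale variances.
#' @return A list with `mean` (`L x D`) and `precision` (list of `D x D`
#'   matrices, one per feature row).
#' @export
weight_conditional_params <- function(X, Z, sigma2_x, sigma2_w) {
  D <- ncol(Z)
  L <- length(sigma2_x)
  if (nrow(X) != nrow(Z)) stop("X and Z must have matching rows")
  ZtZ <- crossprod(Z)
  ZtX <- crossprod(Z, X)
  mean_mat <- matrix(0, L, D)
  prec <- vector("list", L)
  for (l in seq_len(L)) {
    Lam <- ZtZ / sigma2_x[l] + diag(1 / sigma2_w[l], D)
    prec[[l]] <- Lam
    mean_mat[l, ] <- solve(Lam, ZtX[, l] / sigma2_x[l])
  }
  list(mean = mean_mat, precision = prec)
}

#' Gibbs draw of the emission weight matrix
#'
#' Draws each weight row from its exact multivariate-normal conditional
#' given the latent vectors, noise variances and weight-scale variances.
#' With zero samples the rows are drawn from their prior
#' `N(0, sigma2_w_l I)`.
#'
#' @inheritParams weight_conditional_params
#' @return A new `L x D` weight matrix.
#' @export
gibbs_update_weights <- function(X, Z, sigma2_x, sigma2_w) {
  D <- ncol(Z)
  L <- length(sigma2_x)
  cp <- weight_conditional_params(X, Z, sigma2_x, sigma2_w)
  W <- matrix(0, L, D)
  for (l in seq_len(L)) {
    R <- chol(cp$precision[[l]])
    W[l, ] <- cp$mean[l, ] + backsolve(R, stats::rnorm(D))
  }
  W
}

#' Conditional parameters of the variance Gibbs updates
#'
#' Shape/rate of the Gamma conditionals for the feature-noise precisions
#' (`sigma_x^-2`) and the weight-scale precisions (`sigma_w^-2`):
#' shape `a_x + N_X/2` and rate `b_x + sum(residual^2)/2` for the noise,
#' shape `a_w + D/2` and rate `b_w + w_l'w_l / 2` for the scales.
#' `compat_printed_shape = TRUE` switches the noise shape to
#' `a_x + 2/N_X` for audit of an alternative published form; the standard
#' conjugate shape is the default.
#'
#' @param X,Z as in [weight_conditional_params()].
#' @param W current `L x D` weight matrix.
#' @param a_x,b_x,a_w,b_w Gamma prior shapes/rates.
#' @param compat_printed_shape use the non-conjugate printed shape
#'   `a_x + 2/N_X`?
#' @return A list with vectors `shape_x`, `rate_x`, `shape_w`, `rate_w`.
#' @export
variance_conditional_params <- function(X, Z, W, a_x, b_x, a_w, b_w,
                                        compat_printed_shape = FALSE) {
  N <- nrow(X)
  D <- ncol(Z)
  resid <- X - Z %*% t(W)
  rss <- colSums(resid^2)
  shape_x <- if (compat_printed_shape) a_x + 2 / N else a_x + N / 2
  list(shape_x = rep(shape_x, length.out = ncol(X)),
       rate_x = b_x + rss / 2,
       shape_w = rep(a_w + D / 2, nrow(W)),
       rate_w = b_w + rowSums(W^2) / 2)
}

#' Gibbs draw of the variance parameters
#'
#' @inheritParams variance_conditional_params
#' @return A list with `sigma2_x` and `sigma2_w` (variances, i.e.
#'   reciprocals of the drawn precisions).
#' @export
gibbs_update_variances <- function(X, Z, W, a_x, b_x, a_w, b_w,
                                   compat_printed_shape = FALSE) {
  cp <- variance_conditional_params(X, Z, W, a_x, b_x, a_w, b_w,
                                    compat_printed_shape)
  lam_x <- stats::rgamma(length(cp$rate_x), cp$shape_x, rate = cp$rate_x)
  lam_w <- stats::rgamma(length(cp$rate_w), cp$shape_w, rate = cp$rate_w)
  list(sigma2_x = 1 / lam_x, sigma2_w = 1 / lam_w)
}

# ---- shared MH machinery -------------------------------------------------

# per-sample log target over transformed coordinates u = (log a, log b, g)
theta_log_target <- function(u, t, k, y, X, pseudo, mu, sigma2, sigma_y,
                             emission) {
  alpha <- exp(u[, 1L]); beta <- exp(u[, 2L]); gamma <- u[, 3L]
  sdm <- sqrt(sigma2)
  muA <- mu[1L, ][k]; sdA <- sdm[1L, ][k]
  muB <- mu[2L, ][k]; sdB <- sdm[2L, ][k]
  muG <- mu[3L, ][k]; sdG <- sdm[3L, ][k]
  ll <- u[, 1L] + u[, 2L] +
    stats::dnorm(alpha, muA, sdA, log = TRUE) -
    stats::pnorm(muA / sdA, log.p = TRUE) +
    stats::dnorm(beta, muB, sdB, log = TRUE) -
    stats::pnorm(muB / sdB, log.p = TRUE) +
    stats::dnorm(gamma, muG, sdG, log = TRUE)
  have_y <- !is.na(y)
  if (any(have_y)) {
    z <- alpha * stats::plogis(beta * t - gamma)
    lly <- stats::dnorm(y[have_y], z[have_y], sigma_y, log = TRUE)
    if (pseudo) {
      z0 <- alpha * stats::plogis(-gamma)
      lly <- lly + stats::dnorm(0, z0[have_y], sigma_y, log = TRUE)
    }
    ll[have_y] <- ll[have_y] + lly
  }
  if (!is.null(X)) {
    Z <- latent_vector_matrix(cbind(alpha, beta, gamma), t, emission$C,
                              emission$include_derivative)
    M <- Z %*% t(emission$W)
    ll <- ll - 0.5 * drop((X - M)^2 %*% (1 / emission$sigma2_x)) -
      0.5 * sum(log(2 * pi * emission$sigma2_x))
  }
  ll
}

# log target of one hyper cell (phi, k) as a function of mu and
# eta = log precision, given sufficient statistics of the active thetas
hyper_log_target <- function(mu_v, eta_v, n_k, S1, S2, trunc_adj,
                             mu_mean, mu_sd, lam_shape, lam_rate) {
  lam <- exp(eta_v)
  sd_v <- exp(-eta_v / 2)
  ll <- n_k * eta_v / 2 - lam * (S2 - 2 * mu_v * S1 + n_k * mu_v^2) / 2 +
    stats::dnorm(mu_v, mu_mean, mu_sd, log = TRUE) +
    lam_shape * eta_v - lam_rate * lam
  adj <- trunc_adj * n_k * stats::pnorm(mu_v / sd_v, log.p = TRUE)
  ll - adj
}

# sufficient statistics per (phi, k) cell from the active thetas
theta_suffstats <- function(theta, k) {
  S1 <- matrix(0, 3, 2); S2 <- matrix(0, 3, 2); nk <- c(0, 0)
  for (kk in 1:2) {
    sel <- k == kk
    nk[kk] <- sum(sel)
    if (nk[kk] > 0) {
      th <- theta[sel, , drop = FALSE]
      S1[, kk] <- colSums(th)
      S2[, kk] <- colSums(th^2)
    }
  }
  list(S1 = S1, S2 = S2, nk = nk)
}

# The engine. `y` may contain NAs (no Abeta likelihood for that sample);
# `X` is NULL (step 1 / prior-only) or a complete N x L matrix; `emission`
# carries the current emission state, with `gibbs = TRUE` to resample
# W / sigma2_x / sigma2_w and FALSE to hold them fixed.
run_mwg <- function(theta0, t, k, y, X, pseudo, hyper_prior, sigma_y,
                    emission = NULL, mcmc, store_theta = TRUE,
                    compat_printed_shape = FALSE) {
  n <- nrow(theta0)
  L <- if (!is.null(X)) ncol(X) else 0L
  D <- if (!is.null(emission)) {
    if (emission$include_derivative) 3L else 2L
  } else 0L
  nkeep <- mcmc$n_samples
  trunc_adj <- c(1, 1, 0)  # alpha, beta truncated; gamma not

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + ch - 1L)
    u <- cbind(log(theta0[, 1L]), log(theta0[, 2L]), theta0[, 3L])
    # small chain-specific jitter to overdisperse starting points
    u <- u + 0.05 * matrix(stats::rnorm(3L * n), n, 3L)
    mu <- hyper_prior$mu_mean
    eta <- log(hyper_prior$lam_shape / hyper_prior$lam_rate)
    em <- emission
    ls_theta <- rep(log(0.1), n)
    ls_mu <- matrix(log(0.1), 3, 2)
    ls_eta <- matrix(log(0.5), 3, 2)
    ls_shift <- matrix(log(0.1), 3, 2)
    ls_shift2 <- rep(log(0.1), 2)

    keep_mu <- matrix(NA_real_, nkeep, 6L)
    keep_s2 <- matrix(NA_real_, nkeep, 6L)
    keep_th <- if (store_theta) matrix(NA_real_, nkeep, 3L * n) else NULL
    keep_W <- if (!is.null(em) && em$gibbs)
      matrix(NA_real_, nkeep, L * D) else NULL
    keep_sx <- if (!is.null(em) && em$gibbs)
      matrix(NA_real_, nkeep, L) else NULL
    keep_sw <- if (!is.null(em) && em$gibbs)
      matrix(NA_real_, nkeep, L) else NULL

    total <- mcmc$n_burnin + nkeep
    for (it in seq_len(total)) {
      adapting <- it <= mcmc$n_burnin
      theta <- cbind(exp(u[, 1L]), exp(u[, 2L]), u[, 3L])

      # conjugate emission blocks
      if (!is.null(em) && em$gibbs) {
        Z <- latent_vector_matrix(theta, t, em$C, em$include_derivative)
        em$W <- gibbs_update_weights(X, Z, em$sigma2_x, em$sigma2_w)
        v <- gibbs_update_variances(X, Z, em$W, em$a_x, em$b_x, em$a_w,
                                    em$b_w, compat_printed_shape)
        em$sigma2_x <- v$sigma2_x
        em$sigma2_w <- v$sigma2_w
      }

      # per-animal parameters, one joint 3-d proposal per animal
      if (n > 0) {
        cur <- theta_log_target(u, t, k, y, X, pseudo, mu, exp(-eta),
                                sigma_y, em)
        up <- u + exp(ls_theta) * matrix(stats::rnorm(3L * n), n, 3L)
        prop <- theta_log_target(up, t, k, y, X, pseudo, mu, exp(-eta),
                                 sigma_y, em)
        dl <- prop - cur
        acc <- log(stats::runif(n)) < dl
        u[acc, ] <- up[acc, ]
        if (adapting)
          ls_theta <- ls_theta +
            (pmin(1, exp(pmin(dl, 0))) - mcmc$target_accept) / it^0.6
        theta <- cbind(exp(u[, 1L]), exp(u[, 2L]), u[, 3L])
      }

      # hierarchy means and log-precisions, scalar proposals per cell
      ss <- theta_suffstats(theta, k)
      for (par in c("mu", "eta")) {
        cur <- hyper_log_target(mu, eta, rep(ss$nk, each = 3), ss$S1,
                                ss$S2, trunc_adj, hyper_prior$mu_mean,
                                hyper_prior$mu_sd, hyper_prior$lam_shape,
                                hyper_prior$lam_rate)
        if (par == "mu") {
          cand <- mu + exp(ls_mu) * matrix(stats::rnorm(6), 3, 2)
          prop <- hyper_log_target(cand, eta, rep(ss$nk, each = 3), ss$S1,
                                   ss$S2, trunc_adj, hyper_prior$mu_mean,
                                   hyper_prior$mu_sd,
                                   hyper_prior$lam_shape,
                                   hyper_prior$lam_rate)
          dl <- prop - cur
          acc <- matrix(log(stats::runif(6)), 3, 2) < dl
          mu[acc] <- cand[acc]
          if (adapting)
            ls_mu <- ls_mu + (pmin(1, exp(pmin(dl, 0))) - 0.44) / it^0.6
        } else {
          cand <- eta + exp(ls_eta) * matrix(stats::rnorm(6), 3, 2)
          prop <- hyper_log_target(mu, cand, rep(ss$nk, each = 3), ss$S1,
                                   ss$S2, trunc_adj, hyper_prior$mu_mean,
                                   hyper_prior$mu_sd,
                                   hyper_prior$lam_shape,
                                   hyper_prior$lam_rate)
          dl <- prop - cur
          acc <- matrix(log(stats::runif(6)), 3, 2) < dl
          eta[acc] <- cand[acc]
          if (adapting)
            ls_eta <- ls_eta + (pmin(1, exp(pmin(dl, 0))) - 0.44) / it^0.6
        }
      }

      # group-shift moves: translate a type mean together with all that
      # type's per-animal values. These break the slow random walk the
      # centered hierarchy otherwise forces on the type means when the
      # data constrain a parameter only weakly.
      if (n > 0) {
        for (kk in 1:2) {
          sel <- which(k == kk)
          if (!length(sel)) next
          for (phi in 1:3) {
            delta <- exp(ls_shift[phi, kk]) * stats::rnorm(1L)
            mu_p <- mu; mu_p[phi, kk] <- mu[phi, kk] + delta
            u_p <- u[sel, , drop = FALSE]
            ok <- TRUE
            if (phi <= 2L) {
              th_new <- exp(u_p[, phi]) + delta
              if (any(th_new <= 0)) ok <- FALSE else
                u_p[, phi] <- log(th_new)
            } else u_p[, phi] <- u_p[, phi] + delta
            if (ok) {
              cur <- theta_log_target(u[sel, , drop = FALSE], t[sel],
                                      k[sel], y[sel],
                                      if (is.null(X)) NULL
                                      else X[sel, , drop = FALSE],
                                      pseudo, mu, exp(-eta), sigma_y, em)
              prop <- theta_log_target(u_p, t[sel], k[sel], y[sel],
                                       if (is.null(X)) NULL
                                       else X[sel, , drop = FALSE],
                                       pseudo, mu_p, exp(-eta), sigma_y,
                                       em)
              dl <- sum(prop) - sum(cur) +
                stats::dnorm(mu_p[phi, kk], hyper_prior$mu_mean[phi, kk],
                             hyper_prior$mu_sd[phi, kk], log = TRUE) -
                stats::dnorm(mu[phi, kk], hyper_prior$mu_mean[phi, kk],
                             hyper_prior$mu_sd[phi, kk], log = TRUE)
              # the shift acts in natural coordinates; remove the log
              # transform's Jacobian contribution from the target ratio
              if (phi <= 2L)
                dl <- dl - sum(u_p[, phi] - u[sel, phi])
            } else dl <- -Inf
            if (is.finite(dl) && log(stats::runif(1L)) < dl) {
              mu <- mu_p
              u[sel, ] <- u_p
            }
            if (adapting)
              ls_shift[phi, kk] <- ls_shift[phi, kk] +
                (min(1, exp(min(dl, 0))) - 0.3) / it^0.6
          }
          # joint (beta, gamma) shift along the fixed direction
          # (1, gamma/beta of the prior means), i.e. approximately
          # onset-time-preserving: the data identify gamma/beta much
          # more sharply than beta and gamma separately, so this is
          # the remaining slow ridge.
          r_dir <- hyper_prior$mu_mean[3L, kk] / hyper_prior$mu_mean[2L, kk]
          delta <- exp(ls_shift2[kk]) * stats::rnorm(1L)
          mu_p <- mu
          mu_p[2L, kk] <- mu[2L, kk] + delta
          mu_p[3L, kk] <- mu[3L, kk] + r_dir * delta
          u_p <- u[sel, , drop = FALSE]
          th_new <- exp(u_p[, 2L]) + delta
          if (any(th_new <= 0)) dl <- -Inf else {
            u_p[, 2L] <- log(th_new)
            u_p[, 3L] <- u_p[, 3L] + r_dir * delta
            cur <- theta_log_target(u[sel, , drop = FALSE], t[sel],
                                    k[sel], y[sel],
                                    if (is.null(X)) NULL
                                    else X[sel, , drop = FALSE],
                                    pseudo, mu, exp(-eta), sigma_y, em)
            prop <- theta_log_target(u_p, t[sel], k[sel], y[sel],
                                     if (is.null(X)) NULL
                                     else X[sel, , drop = FALSE],
                                     pseudo, mu_p, exp(-eta), sigma_y,
                                     em)
            dl <- sum(prop) - sum(cur) -
              sum(u_p[, 2L] - u[sel, 2L]) +
              sum(stats::dnorm(mu_p[2:3, kk], hyper_prior$mu_mean[2:3, kk],
                               hyper_prior$mu_sd[2:3, kk], log = TRUE)) -
              sum(stats::dnorm(mu[2:3, kk], hyper_prior$mu_mean[2:3, kk],
                               hyper_prior$mu_sd[2:3, kk], log = TRUE))
          }
          if (is.finite(dl) && log(stats::runif(1L)) < dl) {
            mu <- mu_p
            u[sel, ] <- u_p
          }
          if (adapting)
            ls_shift2[kk] <- ls_shift2[kk] +
              (min(1, exp(min(dl, 0))) - 0.3) / it^0.6
        }
        theta <- cbind(exp(u[, 1L]), exp(u[, 2L]), u[, 3L])
      }

      if (!adapting) {
        j <- it - mcmc$n_burnin
        keep_mu[j, ] <- as.vector(mu)
        keep_s2[j, ] <- as.vector(exp(-eta))
        if (store_theta && n > 0)
          keep_th[j, ] <- as.vector(theta)
        if (!is.null(keep_W)) {
          keep_W[j, ] <- as.vector(em$W)
          keep_sx[j, ] <- em$sigma2_x
          keep_sw[j, ] <- em$sigma2_w
        }
      }
    }
    chains[[ch]] <- list(mu = keep_mu, sigma2 = keep_s2, theta = keep_th,
                         W = keep_W, sigma2_x = keep_sx,
                         sigma2_w = keep_sw)
  }

  bind <- function(name) {
    mats <- lapply(chains, `[[`, name)
    if (is.null(mats[[1L]])) return(NULL)
    do.call(rbind, mats)
  }
  phik_names <- as.vector(outer(c("alpha", "beta", "gamma"),
                                c("WT", "AD"), paste, sep = "."))
  mu_d <- bind("mu"); colnames(mu_d) <- paste0("mu.", phik_names)
  s2_d <- bind("sigma2"); colnames(s2_d) <- paste0("sigma2.", phik_names)
  out <- list(mu = mu_d, sigma2 = s2_d, theta = bind("theta"),
              W = bind("W"), sigma2_x = bind("sigma2_x"),
              sigma2_w = bind("sigma2_w"),
              chain = rep(seq_len(mcmc$n_chains), each = nkeep),
              n_active = n)
  out
}

# ---- convergence diagnostics --------------------------------------------

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed on chains split in half.
#'
#' @param draws numeric vector of draws, chains stacked.
#' @param chain integer chain label per draw.
#' @return The split-R-hat value (1 = perfect mixing).
#' @export
split_rhat <- function(draws, chain) {
  pieces <- list()
  for (ch in unique(chain)) {
    v <- draws[chain == ch]
    h <- floor(length(v) / 2)
    pieces <- c(pieces, list(v[seq_len(h)], v[h + seq_len(h)]))
  }
  m <- length(pieces); nn <- length(pieces[[1L]])
  means <- vapply(pieces, mean, 0)
  vars <- vapply(pieces, stats::var, 0)
  B <- nn * stats::var(means)
  Wv <- mean(vars)
  if (Wv == 0) return(1)
  sqrt(((nn - 1) / nn * Wv + B / nn) / Wv)
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size using Geyer's initial
#' positive sequence, summed over chains.
#'
#' @inheritParams split_rhat
#' @return Estimated effective number of independent draws.
#' @export
ess_basic <- function(draws, chain) {
  total <- 0
  for (ch in unique(chain)) {
    v <- draws[chain == ch]
    nn <- length(v)
    if (stats::var(v) == 0) { total <- total + 1; next }
    ac <- stats::acf(v, lag.max = min(nn - 1L, 200L), plot = FALSE,
                     demean = TRUE)$acf[-1L]
    s <- 0
    for (j in seq(1L, length(ac) - 1L, by = 2L)) {
      pair <- ac[j] + ac[j + 1L]
      if (is.na(pair) || pair < 0) break
      s <- s + pair
    }
    total <- total + nn / (1 + 2 * s)
  }
  total
}
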