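#' Joint log density of the full model
#'
#' Sum of every log prior and log likelihood factor of the generative
#' model: the hyper-priors of the type means and precisions, the
#' hierarchy densities of the per-animal parameters, the weight-matrix
#' and variance priors, the Abeta likelihood over `S_y` and the
#' biomarker likelihood over `S_X`. Precisions (`1/sigma2`) carry the
#' Gamma priors, matching the sampler's parameterization. Adding an
#' independent sample adds exactly its own terms.
#'
#' @param dataset an [ab_dataset].
#' @param thetas `n x 3` matrix (`alpha`, `beta`, `gamma`), one row per
#'   dataset sample; rows may be `NA` only for samples contributing no
#'   likelihood term.
#' @param hyper a [type_hyper].
#' @param obs an [obs_params].
#' @param prior an [ab_prior] with resolved (non-`NA`) means `m`.
#' @param include_pseudo add the step-1 zero pseudo-observations at
#'   `t = 0` for `S_y` samples?
#' @return Scalar log density.
#' @export
log_joint_density <- function(dataset, thetas, hyper, obs, prior,
                              include_pseudo = FALSE) {
  thetas <- as.matrix(thetas)
  stopifnot(nrow(thetas) == length(dataset$id), ncol(thetas) == 3)
  contributing <- sort(union(dataset$S_y, dataset$S_X))
  if (any(is.na(thetas[contributing, ])))
    stop("missing theta for a contributing sample", call. = FALSE)
  if (any(is.na(prior$m)))
    stop("prior means 'm' must be resolved", call. = FALSE)
  ld <- 0
  # hyper-priors
  ld <- ld + sum(stats::dnorm(hyper$mu, prior$m, prior$v, log = TRUE)) +
    sum(stats::dgamma(1 / hyper$sigma2, prior$a, rate = prior$b,
                      log = TRUE))
  # emission priors
  ld <- ld + sum(stats::dnorm(obs$W, 0, sqrt(obs$sigma2_w), log = TRUE)) +
    sum(stats::dgamma(1 / obs$sigma2_w, prior$a_w, rate = prior$b_w,
                      log = TRUE)) +
    sum(stats::dgamma(1 / obs$sigma2_x, prior$a_x, rate = prior$b_x,
                      log = TRUE))
  # hierarchy over contributing samples
  k <- type_index(dataset$type)
  sdm <- sqrt(hyper$sigma2)
  for (n in contributing) {
    kk <- k[n]
    ld <- ld +
      dtnorm_pos(thetas[n, 1], hyper$mu[1, kk], sdm[1, kk], log = TRUE) +
      dtnorm_pos(thetas[n, 2], hyper$mu[2, kk], sdm[2, kk], log = TRUE) +
      stats::dnorm(thetas[n, 3], hyper$mu[3, kk], sdm[3, kk], log = TRUE)
  }
  # Abeta likelihood
  for (n in dataset$S_y) {
    p <- logistic_params(thetas[n, 1], thetas[n, 2], thetas[n, 3])
    z <- logistic_accumulation(p, dataset$age[n])
    ld <- ld + stats::dnorm(dataset$y[n], z, prior$sigma_y, log = TRUE)
    if (include_pseudo)
      ld <- ld + stats::dnorm(0, logistic_accumulation(p, 0),
                              prior$sigma_y, log = TRUE)
  }
  # biomarker likelihood
  for (n in dataset$S_X) {
    p <- logistic_params(thetas[n, 1], thetas[n, 2], thetas[n, 3])
    zv <- latent_vector(p, dataset$age[n], obs)
    m <- drop(obs$W %*% zv)
    ld <- ld + sum(stats::dnorm(dataset$X[n, ], m, sqrt(obs$sigma2_x),
                                log = TRUE))
  }
  ld
}

# sum over components in log space
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
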