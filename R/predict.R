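# Posterior-predictive prediction of Abeta level and animal type.
#
# For a new biomarker vector x*, the predictive distribution is a
# mixture over posterior draws i, candidate ages t on a grid, animal
# types s, and M auxiliary parameter draws theta* from draw i's type-s
# hierarchy (a test animal has no inferred theta of its own). Each
# component is weighted by the Gaussian likelihood of x* under that
# component's emission; the predicted level is the component's noiseless
# accumulation z(theta*, t). All mixture arithmetic is in log space.

#' Precompute predictive mixture components
#'
#' Draws the mixture components shared by all test samples: per
#' (posterior draw, grid age, type, auxiliary draw) a latent level and
#' the implied emission mean. Build once per fit and reuse across test
#' samples.
#'
#' @param fit an `"abm_fit"`.
#' @param grid candidate ages in months (default integer months 2..18).
#' @param M auxiliary parameter draws per (draw, age, type) component.
#' @param seed seed for the auxiliary draws.
#' @param max_draws cap on posterior draws used (evenly thinned);
#'   `NULL` = all.
#' @return An object of class `"ab_pred_components"`.
#' @export
predictive_components <- function(fit, grid = 2:18, M = 1, seed = 1L,
                                  max_draws = NULL) {
  set.seed(seed)
  d <- fit$draws
  I_all <- nrow(d$mu)
  use <- if (!is.null(max_draws) && max_draws < I_all)
    round(seq(1, I_all, length.out = max_draws)) else seq_len(I_all)
  I <- length(use)
  L <- fit$L; D <- fit$D
  Nt <- length(grid)
  # component index: draw varies slowest, then type, then age, then m
  i_idx <- rep(seq_len(I), each = 2L * Nt * M)
  s_idx <- rep(rep(1:2, each = Nt * M), times = I)
  t_val <- rep(rep(grid, each = M), times = 2L * I)
  K <- length(i_idx)

  mu <- d$mu[use, , drop = FALSE]
  s2 <- d$sigma2[use, , drop = FALSE]
  off <- (s_idx - 1L) * 3L
  pick <- function(m, j) m[cbind(i_idx, off + j)]
  alpha <- rtnorm_pos(K, pick(mu, 1L), sqrt(pick(s2, 1L)))
  beta <- rtnorm_pos(K, pick(mu, 2L), sqrt(pick(s2, 2L)))
  gamma <- stats::rnorm(K, pick(mu, 3L), sqrt(pick(s2, 3L)))
  z <- alpha * stats::plogis(beta * t_val - gamma)
  zv <- if (fit$include_derivative) {
    zp <- beta * z * (1 - z / alpha)
    cbind(z, fit$C * zp, 1)
  } else cbind(z, 1)

  Wd <- d$W[use, , drop = FALSE]
  Mean <- matrix(0, K, L)
  for (dd in seq_len(D))
    Mean <- Mean + Wd[i_idx, (dd - 1L) * L + seq_len(L), drop = FALSE] *
      zv[, dd]
  s2x <- d$sigma2_x[use, , drop = FALSE]
  inv_s2x <- 1 / s2x
  log_const <- -0.5 * rowSums(log(2 * pi * s2x))

  structure(list(level = z, mean = Mean, i_idx = i_idx, s_idx = s_idx,
                 t_val = t_val, inv_s2x = inv_s2x,
                 log_const = log_const, L = L, K = K),
            class = "ab_pred_components")
}

component_loglik <- function(comps, x_star) {
  if (length(x_star) != comps$L)
    stop("feature vector has length ", length(x_star), ", expected ",
         comps$L, call. = FALSE)
  resid2 <- (comps$mean - rep(x_star, each = comps$K))^2
  ll <- -0.5 * rowSums(resid2 * comps$inv_s2x[comps$i_idx, , drop = FALSE]) +
    comps$log_const[comps$i_idx]
  if (all(!is.finite(ll)))
    stop("all predictive weights vanished; check the feature scale",
         call. = FALSE)
  ll
}

#' Predict the Abeta accumulation level for a new biomarker vector
#'
#' Posterior-predictive mixture over posterior draws, grid ages and
#' types: component weights are proportional to the likelihood of
#' `x_star` under each component's emission distribution, evaluated in
#' log space; the point estimate is the weight-averaged noiseless level.
#'
#' @param x_star length-`L` feature vector on the training scale.
#' @param fit an `"abm_fit"`.
#' @param grid,M,seed,max_draws see [predictive_components()].
#' @param comps optional precomputed [predictive_components()]
#'   (overrides `grid`, `M`, `seed`).
#' @param level central credible level for the reported interval.
#' @param point point estimator, weighted `"mean"` (default) or
#'   `"median"`.
#' @return A list of class `"ab_prediction"`: `yhat`, `lwr`, `upr`,
#'   `type_posterior` (named WT/AD, sums to 1), and the normalized
#'   component `weights` and `levels`.
#' @export
predict_abeta <- function(x_star, fit, grid = 2:18, M = 1, seed = 1L,
                          max_draws = NULL, comps = NULL, level = 0.9,
                          point = c("mean", "median")) {
  point <- match.arg(point)
  if (is.null(comps))
    comps <- predictive_components(fit, grid, M, seed, max_draws)
  ll <- component_loglik(comps, x_star)
  w <- exp(ll - logsumexp(ll))
  w <- w / sum(w)
  ord <- order(comps$level)
  cw <- cumsum(w[ord])
  qz <- function(p) comps$level[ord][which.max(cw >= p)]
  yhat <- if (point == "mean") sum(w * comps$level) else qz(0.5)
  tp <- vapply(1:2, function(s) logsumexp(ll[comps$s_idx == s]), 0)
  tp <- exp(tp - logsumexp(tp))
  structure(list(yhat = yhat,
                 lwr = qz((1 - level) / 2), upr = qz(1 - (1 - level) / 2),
                 type_posterior = stats::setNames(tp / sum(tp),
                                                  c("WT", "AD")),
                 weights = w, levels = comps$level),
            class = "ab_prediction")
}

#' Predict the animal type for a new biomarker vector
#'
#' Marginalizes the same predictive mixture over draws and grid ages
#' separately per type (uniform implicit type prior).
#'
#' @inheritParams predict_abeta
#' @return Named probability pair `(WT, AD)` summing to 1.
#' @export
predict_type <- function(x_star, fit, grid = 2:18, M = 1, seed = 1L,
                         max_draws = NULL, comps = NULL) {
  if (is.null(comps))
    comps <- predictive_components(fit, grid, M, seed, max_draws)
  ll <- component_loglik(comps, x_star)
  tp <- vapply(1:2, function(s) logsumexp(ll[comps$s_idx == s]), 0)
  tp <- exp(tp - logsumexp(tp))
  stats::setNames(tp / sum(tp), c("WT", "AD"))
}

#' @export
print.ab_prediction <- function(x, ...) {
  cat(sprintf(
    "Predicted Abeta level: %.3f [%.3f, %.3f]; P(AD | x) = %.3f\n",
    x$yhat, x$lwr, x$upr, x$type_posterior["AD"]))
  invisible(x)
}

#' Predict Abeta levels and types for new biomarker vectors
#'
#' @param object an `"abm_fit"`.
#' @param newdata matrix or data.frame of feature vectors (one row per
#'   sample, training scale and column order).
#' @param grid,M,seed,max_draws see [predictive_components()].
#' @param level central credible level.
#' @param ... unused.
#' @return A data.frame with columns `yhat`, `lwr`, `upr`, `p_WT`,
#'   `p_AD`.
#' @export
predict.abm_fit <- function(object, newdata, grid = 2:18, M = 1,
                            seed = 1L, max_draws = NULL, level = 0.9,
                            ...) {
  X <- as.matrix(newdata)
  comps <- predictive_components(object, grid, M, seed, max_draws)
  res <- lapply(seq_len(nrow(X)), function(i) {
    p <- predict_abeta(X[i, ], object, comps = comps, level = level)
    c(yhat = p$yhat, lwr = p$lwr, upr = p$upr,
      p_WT = unname(p$type_posterior["WT"]),
      p_AD = unname(p$type_posterior["AD"]))
  })
  out <- as.data.frame(do.call(rbind, res))
  rownames(out) <- rownames(X)
  out
}
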