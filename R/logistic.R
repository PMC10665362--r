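#' Per-animal logistic accumulation parameters
#'
#' Bundles the three parameters of the logistic amyloid-beta accumulation
#' curve for one animal: `alpha` (maximum accumulation, scaled units),
#' `beta` (steepness, per month) and `gamma` (offset). The critical period
#' `tau = gamma / beta`, the age at which accumulation reaches half its
#' maximum, is derived and exposed read-only.
#'
#' @param alpha positive scalar, maximum accumulation level.
#' @param beta positive scalar, steepness of accumulation (1/month).
#' @param gamma real scalar, offset; `gamma = beta * tau`.
#' @return An object of class `"logistic_params"`: a list with elements
#'   `alpha`, `beta`, `gamma` and the derived `tau`.
#' @examples
#' p <- logistic_params(alpha = 1, beta = 0.5, gamma = 5)
#' p$tau  # half-maximum age, 10 months
#' @export
logistic_params <- function(alpha, beta, gamma) {
  stopifnot(length(alpha) == 1L, length(beta) == 1L, length(gamma) == 1L)
  if (!is.finite(alpha) || !is.finite(beta) || !is.finite(gamma))
    stop("logistic parameters must be finite", call. = FALSE)
  if (alpha <= 0) stop("'alpha' must be > 0", call. = FALSE)
  if (beta <= 0) stop("'beta' must be > 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 tau = gamma / beta),
            class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf(
    "Logistic accumulation parameters: alpha = %.4g, beta = %.4g, gamma = %.4g (tau = %.4g months)\n",
    x$alpha, x$beta, x$gamma, x$tau))
  invisible(x)
}

as_logistic_params <- function(p) {
  if (inherits(p, "logistic_params")) return(p)
  logistic_params(p[["alpha"]], p[["beta"]], p[["gamma"]])
}

#' Logistic accumulation level
#'
#' Amyloid-beta accumulation at age `t`:
#' `z(t) = alpha / (1 + exp(-beta * t + gamma))`. Strictly increasing in
#' `t` and bounded in `(0, alpha)`.
#'
#' @param params a [logistic_params] object (or list with `alpha`, `beta`,
#'   `gamma`).
#' @param t age in months; may be a vector.
#' @return Accumulation level(s), same length as `t`.
#' @examples
#' logistic_accumulation(logistic_params(1, 1, 0), 0)  # 0.5 at tau
#' @export
logistic_accumulation <- function(params, t) {
  params <- as_logistic_params(params)
  if (any(!is.finite(t))) stop("'t' must be finite", call. = FALSE)
  params$alpha * stats::plogis(params$beta * t - params$gamma)
}

#' Instantaneous accumulation speed
#'
#' Temporal derivative of the logistic accumulation curve,
#' `z'(t) = beta * z * (1 - z / alpha)`; nonnegative, peaking at
#' `beta * alpha / 4` when `t = tau`.
#'
#' @inheritParams logistic_accumulation
#' @return Speed value(s), same length as `t`.
#' @export
accumulation_speed <- function(params, t) {
  params <- as_logistic_params(params)
  z <- logistic_accumulation(params, t)
  params$beta * z * (1 - z / params$alpha)
}

#' Latent emission vector
#'
#' Assembles the hidden state that drives biomarker emission:
#' `(z, C * z', 1)` when the derivative term is included, `(z, 1)`
#' otherwise. `C` is a scaling factor shared across samples that
#' calibrates the range of the speed term.
#'
#' @inheritParams logistic_accumulation
#' @param obs an [obs_params] object (only `C` and `include_derivative`
#'   are used).
#' @return For scalar `t`, a numeric vector of length 3 (or 2); for
#'   vector `t`, a matrix with one row per time point.
#' @export
latent_vector <- function(params, t, obs) {
  if (obs$C <= 0) stop("'C' must be > 0", call. = FALSE)
  z <- logistic_accumulation(params, t)
  if (obs$include_derivative) {
    zp <- accumulation_speed(params, t)
    out <- cbind(z, obs$C * zp, 1)
  } else {
    out <- cbind(z, 1)
  }
  colnames(out) <- NULL
  if (length(t) == 1L) drop(out) else out
}

# latent vectors for many (theta, t) rows at once; theta is an n x 3 matrix
# with columns alpha, beta, gamma.
latent_vector_matrix <- function(theta, t, C, include_derivative = TRUE) {
  z <- theta[, 1L] * stats::plogis(theta[, 2L] * t - theta[, 3L])
  if (include_derivative) {
    zp <- theta[, 2L] * z * (1 - z / theta[, 1L])
    cbind(z, C * zp, 1, deparse.level = 0)
  } else {
    cbind(z, 1, deparse.level = 0)
  }
}
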