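# Truncated normal (lower-truncated at 0) by stabilized inverse-CDF.
#
# Sampling works in the upper tail in log space so that means far below
# zero (many sds) still give exact, finite draws: if Z ~ N(0,1) and
# a = -mu/sd, then  P(Z > q | Z > a) = Phi_c(q) / Phi_c(a), so
# q = Phi_c^{-1}(u * Phi_c(a)) with u ~ U(0,1).

#' Positive truncated normal draws
#'
#' Draws from a normal distribution with mean `mu` and sd `sd` restricted
#' to `(0, Inf)`, via the inverse-CDF method evaluated in the upper tail
#' in log space (stable even when `mu` is many sds below zero). Uses the
#' current R RNG stream, so draws are reproducible under `set.seed()`.
#'
#' @param n number of draws.
#' @param mu,sd mean and sd of the untruncated normal (recycled).
#' @return `n` positive draws.
#' @export
rtnorm_pos <- function(n, mu, sd) {
  stopifnot(all(sd > 0))
  a <- (0 - mu) / sd
  u <- stats::runif(n)
  # log Phi_c(a), then log Phi_c(q) = log(u) + log Phi_c(a)
  log_tail <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
  q <- stats::qnorm(log(u) + log_tail, lower.tail = FALSE, log.p = TRUE)
  mu + sd * q
}

#' Positive truncated normal density
#'
#' @param x evaluation points.
#' @param mu,sd parameters of the untruncated normal.
#' @param log return the log density?
#' @return Density values; zero (or `-Inf`) for `x <= 0`.
#' @export
dtnorm_pos <- function(x, mu, sd, log = FALSE) {
  ld <- stats::dnorm(x, mu, sd, log = TRUE) -
    stats::pnorm(mu / sd, log.p = TRUE)
  ld[x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

# mean of N(mu, sd^2) truncated to (0, Inf)
tnorm_pos_mean <- function(mu, sd) {
  a <- -mu / sd
  # hazard-ratio form, stable in the far tail
  lambda <- exp(stats::dnorm(a, log = TRUE) -
                  stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  mu + sd * lambda
}
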