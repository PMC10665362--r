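#' Draw per-animal parameters from the type hierarchy
#'
#' `alpha` and `beta` are drawn from normals truncated to positive values
#' with the type-specific mean and variance; `gamma` from an untruncated
#' normal.
#'
#' @param hyper a [type_hyper] object.
#' @param type `"WT"` or `"AD"`.
#' @param n number of draws.
#' @return For `n = 1` a [logistic_params] object; otherwise an `n` x 3
#'   matrix with columns `alpha`, `beta`, `gamma`.
#' @export
sample_individual_params <- function(hyper, type = c("WT", "AD"), n = 1) {
  type <- match.arg(type)
  k <- type_index(type)
  mu <- hyper$mu[, k]; sd <- sqrt(hyper$sigma2[, k])
  alpha <- rtnorm_pos(n, mu["alpha"], sd["alpha"])
  beta <- rtnorm_pos(n, mu["beta"], sd["beta"])
  gamma <- stats::rnorm(n, mu["gamma"], sd["gamma"])
  if (n == 1L) return(logistic_params(alpha, beta, gamma))
  cbind(alpha = alpha, beta = beta, gamma = gamma)
}

#' Simulate one animal's observations
#'
#' Generates the scaled Abeta observation `y = z + sigma_y * xi` and the
#' biomarker vector `x = W zvec + diag(sigma_x) eps` with standard-normal
#' `xi`, `eps`.
#'
#' @param params [logistic_params] of the animal.
#' @param t age in months (scalar).
#' @param obs [obs_params] with the emission weights and noise.
#' @param sigma_y Abeta noise sd (may be 0 for noiseless simulation).
#' @param sigma2_x noise variances used for `x`; defaults to
#'   `obs$sigma2_x`, may contain zeros for noiseless simulation.
#' @return A list with elements `y` and `x`.
#' @export
simulate_observations <- function(params, t, obs, sigma_y = 0.05,
                                  sigma2_x = obs$sigma2_x) {
  stopifnot(length(t) == 1L, sigma_y >= 0, all(sigma2_x >= 0),
            length(sigma2_x) == obs$L)
  z <- logistic_accumulation(params, t)
  zvec <- latent_vector(params, t, obs)
  y <- z + sigma_y * stats::rnorm(1L)
  x <- drop(obs$W %*% zvec) + sqrt(sigma2_x) * stats::rnorm(obs$L)
  list(y = y, x = x)
}

#' Cohort design for synthetic studies
#'
#' Per-type sample counts for the three observation roles, the age grid,
#' the feature dimension, and pairing constraints (which types/ages may
#' carry paired observations).
#'
#' @param n_abeta_only,n_biomarker_only,n_paired named length-2 vectors
#'   (`WT`, `AD`) of nonnegative counts.
#' @param age_grid ages (months) sampled uniformly with replacement.
#' @param L number of biomarker features.
#' @param paired_types types allowed to carry paired samples.
#' @param paired_ages age grid for paired samples (defaults to
#'   `age_grid`).
#' @param abeta_ages age grid for Abeta-only samples (defaults to
#'   `age_grid`).
#' @return An object of class `"cohort_design"`.
#' @export
cohort_design <- function(n_abeta_only = c(WT = 20, AD = 20),
                          n_biomarker_only = c(WT = 50, AD = 50),
                          n_paired = c(WT = 50, AD = 50),
                          age_grid = seq(4, 16, by = 2),
                          L = 11,
                          paired_types = c("WT", "AD"),
                          paired_ages = age_grid,
                          abeta_ages = age_grid) {
  chk <- function(v) {
    stopifnot(length(v) == 2L, all(v >= 0))
    if (is.null(names(v))) names(v) <- c("WT", "AD")
    v[c("WT", "AD")]
  }
  stopifnot(length(age_grid) >= 1, L >= 0)
  structure(list(n_abeta_only = chk(n_abeta_only),
                 n_biomarker_only = chk(n_biomarker_only),
                 n_paired = chk(n_paired),
                 age_grid = age_grid, L = as.integer(L),
                 paired_types = paired_types,
                 paired_ages = paired_ages,
                 abeta_ages = abeta_ages),
            class = "cohort_design")
}

#' Ground-truth configuration for synthetic cohorts
#'
#' Defaults give a clearly separated two-type cohort on the scaled Abeta
#' axis: AD animals saturate near 1 with half-maximum around 10 months;
#' WT animals have a tiny maximum (`alpha = 0.01`) so their accumulation
#' stays near zero over the lifespan while all densities remain proper.
#' The speed-scaling factor `C` defaults to
#' `4 / (mu_beta_AD * mu_alpha_AD)` so that the typical peak of `C z'`
#' is about 1, matching the scaled range of `z`.
#'
#' @param hyper a [type_hyper] with the true hierarchy.
#' @param sigma_x per-feature emission noise sd (scalar recycled).
#' @param sigma_y Abeta observation noise sd.
#' @param C speed scaling factor; `NULL` for the default above.
#' @param w_sd sd of the zero-mean normal the true weight rows are drawn
#'   from when no `W` is supplied.
#' @param signal_floor rows of a drawn `W` are redrawn until the larger
#'   of |w_z|, |w_z'| exceeds this, so every feature loads on the latent
#'   process.
#' @param W optional fixed true weight matrix.
#' @param include_derivative keep the speed term in the emission?
#' @return A list of class `"truth_config"`.
#' @export
truth_config <- function(hyper = type_hyper(
                           mu = matrix(c(0.01, 0.45, 4.5,
                                         1.00, 0.45, 4.5), 3, 2,
                                       dimnames = dn_phik()),
                           sigma2 = matrix(c(3e-3, 0.05, 0.5,
                                             0.10, 0.05, 0.5)^2, 3, 2,
                                           dimnames = dn_phik())),
                         sigma_x = 0.5, sigma_y = 0.05, C = NULL,
                         w_sd = 1.5, signal_floor = 0.5, W = NULL,
                         include_derivative = TRUE) {
  if (is.null(C)) C <- 4 / (hyper$mu["beta", "AD"] * hyper$mu["alpha", "AD"])
  structure(list(hyper = hyper, sigma_x = sigma_x, sigma_y = sigma_y,
                 C = C, w_sd = w_sd, signal_floor = signal_floor, W = W,
                 include_derivative = isTRUE(include_derivative)),
            class = "truth_config")
}

draw_true_W <- function(L, D, w_sd, signal_floor) {
  W <- matrix(stats::rnorm(L * D, 0, w_sd), L, D)
  if (D >= 2) {
    for (l in seq_len(L)) {
      while (max(abs(W[l, seq_len(D - 1L)])) < signal_floor)
        W[l, ] <- stats::rnorm(D, 0, w_sd)
    }
  }
  W
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-animal logistic parameters from the true hierarchy, ages
#' uniformly from the design's age grid, and observations from the
#' emission model, partitioning the cohort into Abeta-only,
#' biomarker-only, and paired samples according to the design. The
#' default design yields 140 Abeta-observed, 200 biomarker-observed and
#' 100 paired samples (20/50/50 per type).
#'
#' @param design a [cohort_design].
#' @param truth a [truth_config].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param standardize_features if `TRUE`, affinely rescale each feature
#'   column to population mean 0, sd 1 and apply the same transform to
#'   the true weights and noise sds, so the ground truth stays exactly
#'   consistent with the emitted data.
#' @return A list with elements `dataset` (an [ab_dataset]) and `truth`
#'   (class `"ab_truth"`: per-sample `theta`, latent `z`, `zp`, the true
#'   [type_hyper], the true [obs_params], `sigma_y` and the seed).
#' @export
generate_synthetic_study <- function(design = cohort_design(),
                                     truth = truth_config(),
                                     seed = 1L,
                                     standardize_features = FALSE) {
  set.seed(seed)
  L <- design$L
  D <- if (truth$include_derivative) 3L else 2L
  roles <- c("abeta", "marker", "paired")
  n_mat <- rbind(abeta = design$n_abeta_only,
                 marker = design$n_biomarker_only,
                 paired = design$n_paired)
  if (L == 0 && any(n_mat[c("marker", "paired"), ] > 0))
    stop("biomarker samples requested but L = 0", call. = FALSE)
  bad <- setdiff(names(which(design$n_paired > 0)), design$paired_types)
  if (length(bad))
    stop("paired samples requested for disallowed type(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  W <- truth$W
  if (is.null(W) && L > 0)
    W <- draw_true_W(L, D, truth$w_sd, truth$signal_floor)
  if (L == 0) W <- matrix(numeric(0), 0, D)
  sigma_x <- rep_len(truth$sigma_x, L)
  obs <- obs_params(W, pmax(sigma_x^2, 1e-12),
                    rep(truth$w_sd^2, max(L, 1L))[seq_len(L)],
                    C = truth$C,
                    include_derivative = truth$include_derivative)

  id <- character(0); type <- character(0); age <- numeric(0)
  role <- character(0)
  for (k in c("WT", "AD")) for (r in roles) {
    n_kr <- n_mat[r, k]
    if (n_kr == 0) next
    grid <- switch(r, abeta = design$abeta_ages,
                   paired = design$paired_ages, design$age_grid)
    id <- c(id, sprintf("%s_%s_%03d", k, r, seq_len(n_kr)))
    type <- c(type, rep(k, n_kr))
    age <- c(age, sample(rep(grid, 2L), n_kr, replace = TRUE))
    role <- c(role, rep(r, n_kr))
  }
  n <- length(id)
  theta <- matrix(NA_real_, n, 3,
                  dimnames = list(id, c("alpha", "beta", "gamma")))
  for (k in c("WT", "AD")) {
    sel <- type == k
    if (any(sel))
      theta[sel, ] <- sample_individual_params(truth$hyper, k, sum(sel))
  }
  z <- theta[, 1] * stats::plogis(theta[, 2] * age - theta[, 3])
  zp <- theta[, 2] * z * (1 - z / theta[, 1])

  y <- rep(NA_real_, n)
  want_y <- role %in% c("abeta", "paired")
  y[want_y] <- z[want_y] + truth$sigma_y * stats::rnorm(sum(want_y))
  X <- matrix(NA_real_, n, L)
  want_x <- role %in% c("marker", "paired")
  if (L > 0 && any(want_x)) {
    Zv <- latent_vector_matrix(theta[want_x, , drop = FALSE], age[want_x],
                               truth$C, truth$include_derivative)
    noise <- matrix(stats::rnorm(sum(want_x) * L), ncol = L) *
      rep(sigma_x, each = sum(want_x))
    X[want_x, ] <- Zv %*% t(W) + noise
  }
  if (L > 0) colnames(X) <- sprintf("f%02d", seq_len(L))

  if (standardize_features && L > 0 && any(want_x)) {
    for (l in seq_len(L)) {
      v <- X[want_x, l]
      mu_l <- mean(v); sd_l <- sqrt(mean((v - mu_l)^2))
      if (sd_l <= 0) stop("degenerate feature in standardization")
      X[, l] <- (X[, l] - mu_l) / sd_l
      Wl <- obs$W[l, ]
      Wl <- Wl / sd_l
      Wl[length(Wl)] <- Wl[length(Wl)] - mu_l / sd_l
      obs$W[l, ] <- Wl
      obs$sigma2_x[l] <- obs$sigma2_x[l] / sd_l^2
    }
  }

  dataset <- ab_dataset(id, type, age, y, X)
  truth_out <- structure(list(theta = theta, z = z, zp = zp,
                              hyper = truth$hyper, obs = obs,
                              sigma_y = truth$sigma_y, seed = seed,
                              role = stats::setNames(role, id)),
                         class = "ab_truth")
  list(dataset = dataset, truth = truth_out)
}

#' Generate the small real-study-like fixture cohort
#'
#' Emulates the composition of the motivating 5xFAD behavioural study:
#' 24 Abeta-only AD samples (ages 4, 8, 12, 18), 82 biomarker-only
#' samples (41 WT, 41 AD at ages 4, 8, 12), and 18 paired samples, all
#' AD at ages 8 and 12, with 11 features. WT animals carry no Abeta
#' observation (virtual WT samples are added downstream by
#' [augment_virtual_wt()]). Features are on a standardized scale by
#' construction.
#'
#' @param seed integer seed.
#' @param truth a [truth_config].
#' @return As [generate_synthetic_study()].
#' @export
generate_fixture_study <- function(seed = 1L, truth = truth_config()) {
  design <- cohort_design(
    n_abeta_only = c(WT = 0, AD = 24),
    n_biomarker_only = c(WT = 41, AD = 41),
    n_paired = c(WT = 0, AD = 18),
    age_grid = c(4, 8, 12), L = 11,
    paired_types = "AD", paired_ages = c(8, 12),
    abeta_ages = c(4, 8, 12, 18))
  generate_synthetic_study(design, truth, seed,
                           standardize_features = TRUE)
}
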