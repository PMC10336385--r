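#' Simulation-based randomized quantile residuals
#'
#' Simulates `n_sim` response vectors from the fitted model (conditional on
#' the estimated latent effects) and scores each observation by its
#' randomized rank among its simulations, scaled to (0, 1). Under a correctly
#' specified model the residuals are uniform; a Kolmogorov-Smirnov uniformity
#' test and a simulated dispersion test (observed Pearson statistic against
#' its simulated distribution) are reported.
#'
#' @param fit A `bycatch_glmm` fit.
#' @param n_sim Number of simulated response vectors (>= 100).
#' @param seed Integer seed (rank tie-randomization and simulations).
#' @return List with `residuals` (vector in (0, 1)), `ks` (the
#'   [stats::ks.test()] result), `dispersion` (observed statistic, simulated
#'   mean, and p-value), `n_sim`.
#' @export
quantile_residuals <- function(fit, n_sim = 250L, seed = 1L) {
  stopifnot(inherits(fit, "bycatch_glmm"), n_sim >= 100)
  set.seed(seed)
  design <- fit$design
  y <- design$y
  eta <- fitted_eta(fit)
  fam <- design$family
  n <- length(y)
  sims <- matrix(fam$simulate(rep(eta, n_sim), fit$theta), nrow = n)
  below <- rowSums(sims < y)
  ties <- rowSums(sims == y)
  resid <- (below + runif(n) * (ties + 1)) / (n_sim + 1)
  ks <- suppressWarnings(ks.test(resid, "punif"))
  # dispersion: Pearson statistic vs its simulated reference distribution
  mu <- exp(eta)
  vfun <- if (fam$name == "nb2") mu + mu^2 / fit$theta else fit$theta^2
  pearson <- function(v) sum((v - mu)^2 / vfun)
  d_obs <- pearson(y)
  d_sim <- apply(sims, 2, pearson)
  p_disp <- min(1, 2 * min(mean(d_sim >= d_obs), mean(d_sim <= d_obs)) +
    1 / n_sim)
  list(
    residuals = resid, ks = ks,
    dispersion = list(
      observed = d_obs, simulated_mean = mean(d_sim),
      ratio = d_obs / mean(d_sim), p_value = p_disp
    ),
    n_sim = n_sim
  )
}

#' Linear predictor of a fitted model at the data (conditional on latents)
#' @param fit A `bycatch_glmm` fit.
#' @return Numeric vector, link scale.
#' @export
fitted_eta <- function(fit) {
  stopifnot(inherits(fit, "bycatch_glmm"))
  fit$state$eta %||% drop(fit$design$X %*% fit$beta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
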