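#' Negative-binomial (NB2) log-likelihood
#'
#' Sum of log NB2 probabilities with mean `mu` and dispersion `theta`
#' (variance `mu + mu^2/theta`). This is the response distribution of the
#' bycatch model: counts of porpoises per vessel-day-rectangle.
#'
#' @param y Non-negative integer counts.
#' @param mu Means, > 0 (recycled against `y`).
#' @param theta Dispersion, > 0.
#' @return Scalar log-likelihood.
#' @export
#' @examples
#' nb2_loglik(0, 1, 1) # log(1/2)
nb2_loglik <- function(y, mu, theta) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  if (length(theta) != 1 || !is.finite(theta) || theta <= 0) {
    stop("theta must be a single value > 0", call. = FALSE)
  }
  if (any(y < 0) || any(y != round(y))) {
    stop("y must be non-negative integers", call. = FALSE)
  }
  sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
}

# family objects: log-density plus first/second derivatives w.r.t. the
# linear predictor eta, as needed by the inner Newton solver.
# For NB2 with log link (mu = exp(eta)):
#   dl/deta   = y - (y + theta) * mu / (mu + theta)
#   -d2l/deta2 = (y + theta) * theta * mu / (mu + theta)^2  (always > 0)
.family_nb2 <- function() {
  list(
    name = "nb2",
    loglik = function(y, eta, disp) {
      sum(dnbinom(y, size = disp, mu = exp(eta), log = TRUE))
    },
    d1 = function(y, eta, disp) {
      mu <- exp(eta)
      y - (y + disp) * mu / (mu + disp)
    },
    weight = function(y, eta, disp) {
      mu <- exp(eta)
      (y + disp) * disp * mu / (mu + disp)^2
    },
    simulate = function(eta, disp) {
      rnbinom(length(eta), size = disp, mu = exp(eta))
    },
    disp_name = "theta"
  )
}

# Gaussian response with identity link; disp is the residual SD. The Laplace
# approximation is exact for this family, which makes it the validation case
# against the closed-form linear-mixed-model marginal likelihood.
.family_gaussian <- function() {
  list(
    name = "gaussian",
    loglik = function(y, eta, disp) sum(dnorm(y, eta, disp, log = TRUE)),
    d1 = function(y, eta, disp) (y - eta) / disp^2,
    weight = function(y, eta, disp) rep(1 / disp^2, length(eta)),
    simulate = function(eta, disp) rnorm(length(eta), eta, disp),
    disp_name = "sd"
  )
}

.get_family <- function(name) {
  switch(name,
    nb2 = .family_nb2(),
    gaussian = .family_gaussian(),
    stop("unknown family: ", name, call. = FALSE)
  )
}
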